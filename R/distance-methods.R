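#' Pairwise distance matrix
#'
#' Euclidean distance (the metric used on clr-transformed data) or
#' Bray-Curtis dissimilarity (for non-negative relative abundances;
#' `d = sum |x - y| / sum (x + y)`).
#'
#' @param X samples x OTUs matrix.
#' @param metric `"euclidean"` or `"bray"`.
#' @return a square symmetric matrix of class `distance_matrix` with zero
#'   diagonal and attribute `metric`.
#' @export
distance_matrix <- function(X, metric = c("euclidean", "bray")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (metric == "bray" && any(X < 0)) {
    stop("Bray-Curtis requires non-negative input", call. = FALSE)
  }
  d <- if (metric == "euclidean") stats::dist(X) else vegan::vegdist(X, "bray")
  m <- as.matrix(d)
  dimnames(m) <- list(rownames(X), rownames(X))
  structure(m, metric = metric, class = c("distance_matrix", "matrix", "array"))
}

#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' Gower-centres the squared distances and partitions the resulting total
#' sum of squares by the model terms (sequential, Type I), giving per-term
#' explained variances (R-squared), pseudo-F statistics and permutation
#' p-values by free permutation of the samples. With Euclidean distances on
#' centred data the partition is algebraically identical to the direct
#' multivariate ANOVA partition of the data matrix.
#'
#' @param dist a [distance_matrix()] (or any square symmetric matrix).
#' @param design a [build_design()] object over the same samples.
#' @param n_perm permutations (999 by convention).
#' @param seed integer seed.
#' @param exact enumerate all row permutations (small n only).
#' @return a `permanova_result` / `effect_decomposition` tibble with
#'   additional column `pseudo_f`.
#' @export
permanova <- function(dist, design, n_perm = 999, seed = 0, exact = FALSE) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n != design$n) stop("distance matrix does not match design", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric", call. = FALSE)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    warning("distance matrix is not Euclidean-embeddable (negative eigenvalues); proceeding",
            call. = FALSE)
  }
  total_ss <- sum(diag(G))

  bases <- .cumulative_bases(design)
  Q_full <- bases[[length(bases)]]
  df_res <- n - ncol(Q_full)
  K <- length(design$terms)

  term_ss <- function(Gm) {
    # tr(P_k G) - tr(P_{k-1} G) per term, plus residual trace
    tr <- vapply(bases, function(Q) sum(Q * (Gm %*% Q)), 0)  # tr(Q'GQ)
    ss <- diff(tr)
    res <- sum(diag(Gm)) - tr[length(tr)]
    list(ss = ss, res = res)
  }
  obs <- term_ss(G)
  pseudo_f <- (obs$ss / design$df) / (obs$res / df_res)

  perms <- .make_permutations(n, n_perm, seed, exact)
  is_exact <- isTRUE(attr(perms, "exact"))
  perm_f <- matrix(0, nrow(perms), K)
  for (b in seq_len(nrow(perms))) {
    idx <- perms[b, ]
    Gp <- G[idx, idx]
    s <- term_ss(Gp)
    perm_f[b, ] <- (s$ss / design$df) / (s$res / df_res)
  }
  pvals <- vapply(seq_len(K), function(k) {
    .perm_pvalue(pseudo_f[k], perm_f[, k], is_exact)
  }, 0)

  tab <- tibble::tibble(
    term = c(design$terms, "residuals"),
    df = c(design$df, df_res),
    ss = c(obs$ss, obs$res),
    explained_variance_pct = 100 * c(obs$ss, obs$res) / total_ss,
    pseudo_f = c(pseudo_f, NA_real_),
    p_value = c(pvals, NA_real_)
  )
  structure(tab, total_ss = total_ss, ss_type = "sequential", design = design,
            metric = attr(dist, "metric"),
            class = c("permanova_result", "effect_decomposition", class(tab)))
}

#' Analysis of similarities (ANOSIM)
#'
#' One-way rank-based comparison of between- versus within-group distances:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`. R near 1 means complete separation, near 0 no structure.
#' Multi-factor designs are handled by passing the combined design cells as
#' the single grouping factor (see [combine_factors()]).
#'
#' @param dist a [distance_matrix()].
#' @param group factor with at least two groups of two or more samples.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param exact enumerate all permutations (small n only).
#' @return tibble of class `anosim_result` with `r_statistic`, `p_value`,
#'   `n_perm`.
#' @export
anosim <- function(dist, group, n_perm = 999, seed = 0, exact = FALSE) {
  D <- as.matrix(dist)
  group <- as.factor(group)
  n <- nrow(D)
  if (length(group) != n) stop("group labels must match samples", call. = FALSE)
  if (nlevels(droplevels(group)) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) stop("every group needs at least 2 samples", call. = FALSE)

  lower <- lower.tri(D)
  r <- rank(D[lower])
  M <- n * (n - 1) / 2
  stat <- function(g) {
    same <- outer(g, g, "==")[lower]
    (mean(r[!same]) - mean(r[same])) / (M / 2)
  }
  r_obs <- stat(group)
  perms <- .make_permutations(n, n_perm, seed, exact)
  perm_r <- apply(perms, 1L, function(idx) stat(group[idx]))
  p <- .perm_pvalue(r_obs, perm_r, isTRUE(attr(perms, "exact")))
  structure(tibble::tibble(r_statistic = r_obs, p_value = p,
                           n_perm = nrow(perms)),
            class = c("anosim_result", class(tibble::tibble())))
}

#' Similarity percentage analysis (SIMPER)
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity into per-OTU
#' contributions: for a between-group sample pair (k, l) OTU j contributes
#' `|x_jk - x_jl| / sum_i (x_ik + x_il)`, averaged over all between-group
#' pairs (so the contributions sum exactly to the mean dissimilarity). The
#' p-value of each OTU is the probability of a larger average contribution
#' under random permutation of the group factor.
#'
#' @param rel non-negative relative-abundance matrix (filtered, zeros
#'   allowed).
#' @param group factor; only the two levels in `levels_pair` are used.
#' @param levels_pair character vector of the two group levels to compare
#'   (defaults to the first two levels).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param exact enumerate all permutations of the retained samples.
#' @return a [ranking_table()] (statistic = permutation p, lower = more
#'   evidence) with extra columns `contribution` and `p_value`.
#' @export
simper <- function(rel, group, levels_pair = NULL, n_perm = 999, seed = 0,
                   exact = FALSE) {
  X <- as.matrix(rel)
  group <- as.factor(group)
  if (is.null(levels_pair)) levels_pair <- levels(group)[1:2]
  keep <- group %in% levels_pair
  X <- X[keep, , drop = FALSE]
  g <- droplevels(group[keep])
  if (any(table(g) < 2L)) stop("both levels need at least 2 samples", call. = FALSE)

  S <- rowSums(X)
  n <- nrow(X)
  # precompute every unordered pair's per-OTU contribution once; a
  # permutation only changes which pairs are between-group
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  P <- abs(X[pair_idx[, 1L], , drop = FALSE] - X[pair_idx[, 2L], , drop = FALSE]) /
    (S[pair_idx[, 1L]] + S[pair_idx[, 2L]])
  contrib <- function(gg) {
    between <- gg[pair_idx[, 1L]] != gg[pair_idx[, 2L]]
    colSums(P[between, , drop = FALSE]) / sum(between)
  }
  obs <- contrib(g)
  perms <- .make_permutations(n, n_perm, seed, exact)
  is_exact <- isTRUE(attr(perms, "exact"))
  hits <- numeric(ncol(X))
  for (b in seq_len(nrow(perms))) {
    cb <- contrib(g[perms[b, ]])
    hits <- hits + (cb >= obs - 1e-12)
  }
  p <- if (is_exact) hits / nrow(perms) else (1 + hits) / (1 + nrow(perms))

  ranking_table(
    otu_id = colnames(X),
    statistic = p,
    polarity = "lower",
    significant = p < 0.01,
    method = "simper",
    contrast = paste(levels_pair, collapse = " vs "),
    mean_rel_abundance = colMeans(X),
    extra = tibble::tibble(contribution = unname(obs), p_value = unname(p))
  )
}
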