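#' 50-50 MANOVA community test
#'
#' A MANOVA variant for many collinear responses. Explained variances per
#' term are partial (adjusted) sums of squares of the autoscaled clr matrix.
#' The community p-value of each term comes from an F-like statistic
#' computed in a reduced principal-component space: the data are projected
#' onto the principal components that carry at least a given fraction
#' (default 50%) of the total variance, and the ratio of hypothesis to
#' residual mean squares over that test space is compared against its
#' permutation distribution (free permutation of the sample rows). For a
#' single response the statistic collapses to the classical univariate
#' ANOVA F.
#'
#' @param X clr matrix (samples x OTUs); autoscaled internally by default.
#' @param design a [build_design()] object.
#' @param n_perm permutations for the p-value (999 by convention).
#' @param seed integer seed.
#' @param pc_fraction fraction of variance the retained PCs must reach
#'   (default 0.5, the "fifty-fifty" split).
#' @param scale `"autoscale"` (default) or `"center"`; applied before the
#'   analysis.
#' @param exact enumerate all row permutations (small n only).
#' @return an `ffmanova_result` / `effect_decomposition` tibble with partial
#'   explained variances and permutation p-values; the observed 50-50 F
#'   statistics are attached as attribute `f5050`.
#' @export
ffmanova_community <- function(X, design, n_perm = 999, seed = 0,
                               pc_fraction = 0.5,
                               scale = c("autoscale", "center"),
                               exact = FALSE) {
  scale <- match.arg(scale)
  X <- scale_columns(as.matrix(X), scale)
  decomp <- anova_partition(X, design, "partial")
  df_res <- decomp$df[decomp$term == "residuals"]
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)

  # PCs of the (fitted + residual) data = X itself; row permutation leaves
  # X'X, and therefore the PC directions, unchanged, so the permuted
  # statistic can be computed by permuting the fixed PC scores.
  sv <- svd(X)
  var_frac <- cumsum(sv$d^2) / sum(sv$d^2)
  n_pc <- max(1L, which(var_frac >= pc_fraction)[1L])
  Tm <- X %*% sv$v[, seq_len(n_pc), drop = FALSE]   # test-space scores

  Q_full <- .basis(design$full)
  loo <- .leave_one_out_bases(design)
  K <- length(design$terms)

  stat_term <- function(Tp, k) {
    fit_full <- Q_full %*% crossprod(Q_full, Tp)
    fit_red <- loo[[k]] %*% crossprod(loo[[k]], Tp)
    ssh <- sum((fit_full - fit_red)^2)
    sse <- sum((Tp - fit_full)^2)
    (ssh / decomp$df[k]) / (sse / df_res)
  }

  perms <- .make_permutations(design$n, n_perm, seed, exact)
  f_obs <- vapply(seq_len(K), function(k) stat_term(Tm, k), 0)
  pvals <- numeric(K)
  for (k in seq_len(K)) {
    perm_f <- apply(perms, 1L, function(idx) stat_term(Tm[idx, , drop = FALSE], k))
    pvals[k] <- .perm_pvalue(f_obs[k], perm_f, isTRUE(attr(perms, "exact")))
  }
  decomp$p_value[seq_len(K)] <- pvals
  attr(decomp, "f5050") <- stats::setNames(f_obs, design$terms)
  attr(decomp, "n_pc") <- n_pc
  class(decomp) <- c("ffmanova_result", class(decomp))
  decomp
}

#' Per-OTU F tests with rotation-based familywise adjustment
#'
#' Classical per-OTU F statistics for one model term (partial sums of
#' squares), with raw parametric p-values and familywise-adjusted p-values
#' obtained by a max-statistic rotation test: the data's coordinates in the
#' hypothesis-plus-residual subspace are randomly rotated, all OTU F
#' statistics recomputed, and each OTU's adjusted p-value is the fraction
#' of rotations whose maximal F exceeds its observed F. Under Gaussian
#' errors the rotation null is exact. Ranking uses the raw p-value.
#'
#' @param X clr matrix; autoscaled internally by default.
#' @param design a [build_design()] object.
#' @param term term label to test.
#' @param n_rot number of random rotations; `0` skips the adjustment
#'   (adjusted p reported as `NA`).
#' @param seed integer seed.
#' @param scale `"autoscale"` (default) or `"center"`.
#' @return a [ranking_table()] with columns `otu_id`, `statistic` (raw p),
#'   `f`, `p_raw`, `p_adjusted`, `rank`, `significant` (raw p < 0.01).
#' @export
rotation_pvalues <- function(X, design, term, n_rot = 999, seed = 0,
                             scale = c("autoscale", "center")) {
  scale <- match.arg(scale)
  X <- scale_columns(as.matrix(X), scale)
  if (!term %in% design$terms) stop("unknown term: ", term, call. = FALSE)
  k <- match(term, design$terms)
  Q_full <- .basis(design$full)
  df_res <- design$n - ncol(Q_full)
  if (df_res < 2) stop("need residual df >= 2", call. = FALSE)
  Q_red <- .leave_one_out_bases(design)[[k]]
  df_h <- ncol(Q_full) - ncol(Q_red)
  if (df_h < 1) stop("term '", term, "' aliased with the rest of the model",
                     call. = FALSE)

  fit_full <- Q_full %*% crossprod(Q_full, X)
  fit_red <- Q_red %*% crossprod(Q_red, X)
  ssh <- colSums((fit_full - fit_red)^2)
  sse <- colSums((X - fit_full)^2)
  f_obs <- (ssh / df_h) / (sse / df_res)
  p_raw <- stats::pf(f_obs, df_h, df_res, lower.tail = FALSE)

  p_adj <- rep(NA_real_, ncol(X))
  if (n_rot > 0) {
    if (!is.null(seed)) set.seed(seed)
    # basis of hypothesis (+) residual space; coordinates there are
    # rotation-invariant under the null for the tested term
    G_h <- .basis_complement(cbind(Q_red, .basis_complement(Q_full)))
    # G_h spans hypothesis space; residual basis:
    G_e <- .basis_complement(Q_full)
    B <- cbind(G_h, G_e)
    d <- ncol(B)
    C <- crossprod(B, X)                       # d x p coordinates
    hyp_idx <- seq_len(ncol(G_h))
    max_f <- numeric(n_rot)
    for (b in seq_len(n_rot)) {
      O <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
      Cr <- O %*% C
      ssh_r <- colSums(Cr[hyp_idx, , drop = FALSE]^2)
      sse_r <- colSums(Cr[-hyp_idx, , drop = FALSE]^2)
      max_f[b] <- max((ssh_r / df_h) / (sse_r / df_res))
    }
    p_adj <- vapply(f_obs, function(f) {
      (1 + sum(max_f >= f - 1e-12)) / (1 + n_rot)
    }, 0)
    p_adj <- pmax(p_adj, p_raw)   # familywise adjustment never below raw
  }

  ranking_table(
    otu_id = colnames(X),
    statistic = p_raw,
    polarity = "lower",
    significant = p_raw < 0.01,
    method = "rotation",
    contrast = term,
    extra = tibble::tibble(f = unname(f_obs), p_raw = unname(p_raw),
                           p_adjusted = unname(p_adj))
  )
}
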