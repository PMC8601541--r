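# PLS1 (single response) via NIPALS, the engine behind the PLS-DA/VIP/UVE
# OTU selection. Kept internal; the user-facing entry points are
# plsda_vip(), uve_select() and asca_otu_ranking().

.pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  ncomp <- min(ncomp, qr(Xc)$rank)
  if (ncomp < 1L) stop("X has rank 0", call. = FALSE)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- tt <- numeric(ncomp)
  Xd <- Xc
  yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_a <- Xd %*% w
    tt[a] <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt[a]
    q[a] <- sum(yd * t_a) / tt[a]
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q[a] * t_a
  }
  if (ncomp < 1L) stop("response uncorrelated with all predictors", call. = FALSE)
  idx <- seq_len(ncomp)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]; q <- q[idx]; tt <- tt[idx]
  B <- W %*% solve(crossprod(P, W), q)          # coefficients on centred X
  ss <- q^2 * tt                                 # response variance per comp
  vip <- sqrt(p * as.vector(W^2 %*% ss) / sum(ss))
  list(coefficients = as.vector(B), vip = vip, ncomp = ncomp,
       scores = Tm, weights = W, x_mean = x_mean, y_mean = y_mean)
}

.pls1_predict <- function(fit, Xnew) {
  sweep(as.matrix(Xnew), 2L, fit$x_mean) %*% fit$coefficients + fit$y_mean
}

# 10-fold cross-validated classification error to pick the component count
.choose_ncomp <- function(X, y, max_comp = 5L, seed = 0) {
  n <- nrow(X)
  max_comp <- min(max_comp, n - 2L, ncol(X))
  if (max_comp <= 1L) return(1L)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(min(10L, n)), n))
  err <- numeric(max_comp)
  for (nc in seq_len(max_comp)) {
    bad <- 0L
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      fit <- tryCatch(.pls1(X[tr, , drop = FALSE], y[tr], nc),
                      error = function(e) NULL)
      if (is.null(fit)) { bad <- bad + sum(!tr); next }
      pred <- .pls1_predict(fit, X[!tr, , drop = FALSE])
      bad <- bad + sum((pred > mean(unique(y))) != (y[!tr] > mean(unique(y))))
    }
    err[nc] <- bad
  }
  which.min(err)
}

#' PLS-DA variable importance (VIP)
#'
#' Partial least squares regression of a two-class dummy response on a
#' predictor matrix (for the ASCA pipeline: the diet effect matrix plus
#' residuals), returning per-OTU VIP scores and regression coefficients.
#' VIP scores satisfy `mean(VIP^2) = 1`, so 1 is the conventional
#' "average importance" reference.
#'
#' @param X predictor matrix (samples x OTUs).
#' @param response factor (two levels) or numeric dummy vector.
#' @param n_components number of PLS components; truncated to the rank of
#'   `X` with a warning if too large.
#' @return tibble with `otu_id`, `vip`, `coefficient`; the fitted ncomp is
#'   attached as attribute.
#' @export
plsda_vip <- function(X, response, n_components = 2L) {
  X <- as.matrix(X)
  y <- .dummy_response(response)
  rk <- qr(sweep(X, 2L, colMeans(X)))$rank
  if (n_components > rk) {
    warning(sprintf("n_components reduced from %d to rank %d", n_components, rk),
            call. = FALSE)
    n_components <- rk
  }
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  fit <- .pls1(X, y, n_components)
  out <- tibble::tibble(
    otu_id = colnames(X) %||% paste0("V", seq_len(ncol(X))),
    vip = fit$vip,
    coefficient = fit$coefficients
  )
  attr(out, "ncomp") <- fit$ncomp
  out
}

.dummy_response <- function(response) {
  if (is.numeric(response)) {
    if (length(unique(response)) != 2L) stop("response must have two classes",
                                             call. = FALSE)
    return(as.numeric(response))
  }
  f <- droplevels(as.factor(response))
  if (nlevels(f) != 2L) stop("response must have exactly two levels", call. = FALSE)
  as.numeric(f == levels(f)[2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uninformative variable elimination (UVE) for PLS-DA
#'
#' Sets a data-driven VIP significance threshold by appending one noise
#' variable per real OTU (an independent random permutation of that OTU's
#' column, preserving its marginal distribution), fitting the PLS-DA model
#' on the augmented matrix, and flagging real OTUs whose VIP exceeds the
#' largest noise VIP. The procedure is repeated `n_rep` times; OTUs above
#' the threshold in at least `keep_rate` of the repetitions are significant.
#'
#' @param X predictor matrix (samples x OTUs).
#' @param response two-class factor or dummy.
#' @param n_rep repetitions (100 by convention).
#' @param keep_rate selection-frequency cut-off (0.95 by convention).
#' @param seed integer seed.
#' @param n_components PLS components; `NULL` picks by 10-fold
#'   cross-validated classification error, capped at 5.
#' @param statistic optional per-OTU ranking statistic
#'   (higher-is-more-evidence); defaults to the absolute PLS-DA regression
#'   coefficient from the full-data fit.
#' @return a [ranking_table()] with extra columns `selection_freq` and
#'   `vip` (full-data VIP).
#' @export
uve_select <- function(X, response, n_rep = 100, keep_rate = 0.95, seed = 0,
                       n_components = NULL, statistic = NULL) {
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  y <- .dummy_response(response)
  m <- ncol(X)
  if (is.null(n_components)) n_components <- .choose_ncomp(X, y, seed = seed)
  full <- .pls1(X, y, n_components)
  if (is.null(statistic)) statistic <- abs(full$coefficients)

  set.seed(seed)
  marks <- numeric(m)
  for (r in seq_len(n_rep)) {
    noise <- apply(X, 2L, sample)
    fit <- .pls1(cbind(X, noise), y, n_components)
    thr <- max(fit$vip[(m + 1L):(2L * m)])
    marks <- marks + (fit$vip[seq_len(m)] > thr)
  }
  freq <- marks / n_rep
  ranking_table(
    otu_id = colnames(X) %||% paste0("V", seq_len(m)),
    statistic = statistic,
    polarity = "higher",
    significant = freq >= keep_rate,
    method = "uve",
    contrast = "",
    extra = tibble::tibble(selection_freq = freq, vip = full$vip)
  )
}

#' ASCA OTU-level ranking via PLS-DA/VIP/UVE
#'
#' The OTU-level arm of the ASCA pipeline: the predictor is the tested
#' factor's effect matrix plus the residual matrix, restricted to the
#' samples of one pairwise level comparison; significance comes from
#' [uve_select()]. For a two-level factor the ranking statistic is the
#' absolute first-component ASCA loading of the effect matrix, for
#' multilevel factors the absolute PLS-DA regression coefficient.
#'
#' @param fit an [asca()] result.
#' @param term factor (term label) whose effect is examined.
#' @param group factor of that term's levels, one per sample.
#' @param levels_pair two levels to compare (defaults to the first two).
#' @inheritParams uve_select
#' @return a [ranking_table()].
#' @export
asca_otu_ranking <- function(fit, term, group, levels_pair = NULL,
                             n_rep = 100, keep_rate = 0.95, seed = 0,
                             n_components = NULL) {
  stopifnot(inherits(fit, "asca_result"))
  group <- as.factor(group)
  if (is.null(levels_pair)) levels_pair <- levels(group)[1:2]
  E <- effect_matrix(fit, term) + attr(fit, "residuals")
  keep <- group %in% levels_pair
  Xp <- E[keep, , drop = FALSE]
  y <- droplevels(group[keep])
  stat <- if (nlevels(group) == 2L) {
    abs(attr(fit, "loadings")[[term]][, 1L])
  } else NULL
  out <- uve_select(Xp, y, n_rep = n_rep, keep_rate = keep_rate, seed = seed,
                    n_components = n_components, statistic = stat)
  attr(out, "method") <- "asca_uve"
  attr(out, "contrast") <- paste(levels_pair, collapse = " vs ")
  out
}
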