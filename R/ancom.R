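#' ANCOM W statistic
#'
#' For every ordered pair of OTUs (i, j != i) the log-ratio
#' `log(x_i / x_j)` is regressed on the main factor (plus optional additive
#' covariate terms) and the omnibus F-test p-value recorded. Within each
#' OTU i the m-1 p-values are Benjamini-Hochberg adjusted and
#' `W_i = #\{adjusted p <= alpha\}` counts the rejections. Because
#' log-ratios cancel any per-sample scaling, W is invariant to sequencing
#' depth. All pairwise tests are computed in closed form from two p x p
#' cross-product matrices, so the full scan is a few matrix products.
#'
#' @param rel strictly positive relative abundances (zero-replaced),
#'   samples x OTUs.
#' @param metadata data frame of per-sample factors.
#' @param factor_name name of the main factor tested.
#' @param covariates optional character vector of additional additive model
#'   terms.
#' @param alpha per-pair significance level after BH adjustment (0.05).
#' @param w_rule how the W significance threshold is set:
#'   `"fraction_max"` (default) flags OTUs with
#'   `W >= w_threshold * (m - 1)`; `"quantile"` flags OTUs at or above the
#'   `w_threshold` empirical quantile of the W distribution.
#' @param w_threshold threshold parameter for `w_rule` (0.6).
#' @return a [ranking_table()] (statistic = W, higher = more evidence) with
#'   extra column `w`.
#' @export
ancom_w <- function(rel, metadata, factor_name, covariates = NULL,
                    alpha = 0.05, w_rule = c("fraction_max", "quantile"),
                    w_threshold = 0.6) {
  w_rule <- match.arg(w_rule)
  X <- as.matrix(rel)
  if (any(X <= 0)) {
    stop("ancom_w requires strictly positive abundances; zero-replace first",
         call. = FALSE)
  }
  m <- ncol(X)
  if (m < 3L) stop("need at least 3 OTUs for the pairwise log-ratio scheme",
                   call. = FALSE)
  metadata <- as.data.frame(metadata)
  rhs_red <- if (is.null(covariates)) "1" else paste(covariates, collapse = " + ")
  rhs_full <- paste(c(factor_name, covariates), collapse = " + ")
  mm_full <- stats::model.matrix(stats::as.formula(paste("~", rhs_full)), metadata)
  mm_red <- stats::model.matrix(stats::as.formula(paste("~", rhs_red)), metadata)
  Qf <- .basis(mm_full)
  Qr <- .basis(mm_red)
  n <- nrow(X)
  df1 <- ncol(Qf) - ncol(Qr)
  df2 <- n - ncol(Qf)
  if (df1 < 1L || df2 < 1L) stop("degenerate design for the log-ratio model",
                                 call. = FALSE)

  L <- log(X)
  # For response y = L_i - L_j:  SSH = a_ii + a_jj - 2 a_ij with
  # A = L' (P_full - P_red) L, and likewise SSE from B = L'(I - P_full)L.
  Hf <- crossprod(Qf, L)
  Hr <- crossprod(Qr, L)
  A <- crossprod(Hf) - crossprod(Hr)
  B <- crossprod(L) - crossprod(Hf)
  da <- diag(A); db <- diag(B)
  SSH <- outer(da, da, "+") - 2 * A
  SSE <- outer(db, db, "+") - 2 * B
  SSE[SSE < 1e-12] <- 1e-12
  Fm <- (SSH / df1) / (SSE / df2)
  Pm <- stats::pf(Fm, df1, df2, lower.tail = FALSE)
  diag(Pm) <- NA

  W <- integer(m)
  for (i in seq_len(m)) {
    padj <- stats::p.adjust(Pm[i, -i], method = "BH")
    W[i] <- sum(padj <= alpha)
  }
  thr <- if (w_rule == "fraction_max") {
    w_threshold * (m - 1)
  } else {
    stats::quantile(W, w_threshold, names = FALSE)
  }
  ranking_table(
    otu_id = colnames(X),
    statistic = as.numeric(W),
    polarity = "higher",
    significant = W >= thr,
    method = "ancom",
    contrast = factor_name,
    mean_rel_abundance = colMeans(X),
    extra = tibble::tibble(w = W)
  )
}
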