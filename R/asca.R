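#' ANOVA-simultaneous component analysis (ASCA)
#'
#' Sequential ANOVA partition of the column-centred clr matrix, a
#' permutation test of each term's sum of squares (free permutation of the
#' sample rows), and a PCA of every effect matrix providing per-term scores
#' and loadings.
#'
#' @param X clr matrix (samples x OTUs); column-centred internally.
#' @param design a [build_design()] object.
#' @param n_perm number of random permutations (999 by convention).
#' @param seed integer seed for the permutation stream.
#' @param exact if `TRUE`, enumerate all `n!` row permutations instead of
#'   sampling (small n only); the p-value is then the exact enumeration
#'   probability.
#' @param n_components number of principal components retained per effect
#'   matrix.
#' @return an object of class `asca_result` (also `effect_decomposition`):
#'   the sequential decomposition tibble with permutation p-values filled
#'   in, plus `scores` and `loadings` lists (one entry per term) attached.
#' @export
asca <- function(X, design, n_perm = 999, seed = 0, exact = FALSE,
                 n_components = 2L) {
  if (!exact && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  X <- scale_columns(as.matrix(X), "center")
  decomp <- anova_partition(X, design, "sequential")

  bases <- .cumulative_bases(design)
  perms <- .make_permutations(design$n, n_perm, seed, exact)
  K <- length(design$terms)
  obs_ss <- decomp$ss[seq_len(K)]
  pvals <- numeric(K)
  for (k in seq_len(K)) {
    Q_cur <- bases[[k + 1L]]
    Q_prev <- bases[[k]]
    perm_ss <- apply(perms, 1L, function(idx) {
      Xp <- X[idx, , drop = FALSE]
      sum(crossprod(Q_cur, Xp)^2) - sum(crossprod(Q_prev, Xp)^2)
    })
    pvals[k] <- .perm_pvalue(obs_ss[k], perm_ss, isTRUE(attr(perms, "exact")))
  }
  decomp$p_value[seq_len(K)] <- pvals

  scores <- loadings <- vector("list", K)
  for (k in seq_len(K)) {
    sv <- svd(attr(decomp, "effects")[[k]])
    r <- min(n_components, sum(sv$d > 1e-9 * sv$d[1]))
    r <- max(r, 1L)
    scores[[k]] <- sv$u[, seq_len(r), drop = FALSE] %*%
      diag(sv$d[seq_len(r)], r, r)
    loadings[[k]] <- sv$v[, seq_len(r), drop = FALSE]
    rownames(loadings[[k]]) <- colnames(X)
  }
  names(scores) <- names(loadings) <- design$terms
  attr(decomp, "scores") <- scores
  attr(decomp, "loadings") <- loadings
  attr(decomp, "n_perm") <- if (exact) nrow(perms) else n_perm
  class(decomp) <- c("asca_result", class(decomp))
  decomp
}

#' Per-term scores and loadings of an ASCA fit
#' @param fit an [asca()] result.
#' @param term term label.
#' @return list with `scores` (samples x components) and `loadings`
#'   (OTUs x components).
#' @export
asca_components <- function(fit, term) {
  stopifnot(inherits(fit, "asca_result"))
  list(scores = attr(fit, "scores")[[term]],
       loadings = attr(fit, "loadings")[[term]])
}
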