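# Permutation bookkeeping shared by all permutation tests.
#
# A permutation set is a matrix with one permutation of 1:n per row. Random
# sets get the add-one p-value convention p = (1 + #{perm >= obs})/(1 + B)
# so p can never be 0; exact (exhaustively enumerated) sets include the
# identity and use p = #{perm >= obs}/n!, which equals the enumeration
# probability itself.

.all_permutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to n <= 8", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

.make_permutations <- function(n, n_perm, seed = NULL, exact = FALSE) {
  if (exact) {
    perms <- .all_permutations(n)
    attr(perms, "exact") <- TRUE
    return(perms)
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(n)))
  attr(perms, "exact") <- FALSE
  perms
}

.perm_pvalue <- function(obs, perm_stats, exact) {
  hits <- sum(perm_stats >= obs - 1e-12)
  if (exact) hits / length(perm_stats) else (1 + hits) / (1 + length(perm_stats))
}
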