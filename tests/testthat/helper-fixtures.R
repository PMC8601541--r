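# Shared fixtures, all built in code.

# Small deterministic count table
toy_counts <- function() {
  m <- matrix(c(10, 5, 0, 25,
                8, 0, 2, 30,
                12, 6, 1, 21), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("OTU", 1:4)))
  count_matrix(m)
}

# Two groups of 3 samples with a clear shift in the first block of OTUs
toy_shifted_matrix <- function(n_per_group = 3, p = 8, shift = 3, sd = 0.3,
                               seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * p, sd = sd), n, p)
  X[seq_len(n_per_group), 1:2] <- X[seq_len(n_per_group), 1:2] + shift
  dimnames(X) <- list(paste0("s", seq_len(n)), paste0("OTU", seq_len(p)))
  X
}

toy_group6 <- function() factor(rep(c("a", "b"), each = 3))

# A small synthetic simulation template (fast to sample from)
small_template <- function(n_otus = 40, n_per_cell = 3, depth = 3000, seed = 7) {
  make_default_template(n_otus = n_otus, n_per_cell = n_per_cell,
                        depth_mean = depth, seed = seed)
}

# Independent brute-force enumeration of a permutation p-value: applies
# `stat_fun(labels)` to every distinct reordering of the labels and returns
# the fraction of reorderings with a statistic >= the observed one.
enumeration_pvalue <- function(labels, stat_fun) {
  n <- length(labels)
  perms <- make_all_orders(n)
  obs <- stat_fun(labels)
  stats <- apply(perms, 1L, function(idx) stat_fun(labels[idx]))
  mean(stats >= obs - 1e-12)
}

# All n! orderings, built by simple recursion (independent of the package)
make_all_orders <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- make_all_orders(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
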