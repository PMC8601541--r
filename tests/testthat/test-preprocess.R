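test_that("closure to relative abundances", {
  cm <- count_matrix(matrix(c(2, 3, 5,
                              10, 0, 0), 2, 3, byrow = TRUE,
                            dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  rel <- to_relative(cm)
  expect_equal(unname(unclass(rel)[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(unclass(rel)[2, ]), c(1, 0, 0))
  bad <- matrix(c(1, 2, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  expect_error(to_relative(count_matrix(bad)), "zero total")
})

test_that("abundance/prevalence filter follows the stated rule", {
  # 2 groups of 4; OTU1 present at 1% in exactly 2/4 of group a (prevalence
  # boundary 0.5, inclusive) and absent in b -> retained. OTU2 everywhere
  # zero -> removed. OTU3 abundant everywhere -> retained. OTU4 above zero
  # everywhere but never above the abundance threshold -> removed.
  x <- matrix(0, 8, 4, dimnames = list(paste0("s", 1:8), paste0("OTU", 1:4)))
  x[1:2, 1] <- 0.01
  x[, 3] <- 0.9
  x[, 4] <- 4e-5                      # below min_rel = 5e-5 (strict >)
  rel <- count_matrix(x, relative = TRUE)
  grp <- rep(c("a", "b"), each = 4)
  kept <- filter_otus(rel, grp)
  expect_equal(colnames(kept), c("OTU1", "OTU3"))
  expect_equal(attr(kept, "removed"), c("OTU2", "OTU4"))

  # exactly at min_rel is not enough; just above is
  x2 <- x
  x2[, 4] <- 5e-5
  expect_equal(colnames(filter_otus(count_matrix(x2, relative = TRUE), grp)),
               c("OTU1", "OTU3"))
  x2[1, 4] <- 5.1e-5
  expect_equal(colnames(filter_otus(count_matrix(x2, relative = TRUE), grp)),
               c("OTU1", "OTU3", "OTU4"))
})

test_that("filter is monotone in the abundance threshold", {
  set.seed(11)
  x <- matrix(rexp(20 * 30), 20, 30)
  x[sample(length(x), 200)] <- 0
  x <- x / rowSums(x)
  rel <- count_matrix(x, relative = TRUE)
  grp <- rep(c("a", "b"), each = 10)
  kept_sets <- lapply(c(1e-5, 1e-3, 1e-2, 5e-2),
                      function(th) tryCatch(
                        colnames(filter_otus(rel, grp, min_rel = th)),
                        error = function(e) character()))
  for (i in seq_len(length(kept_sets) - 1L)) {
    expect_true(all(kept_sets[[i + 1L]] %in% kept_sets[[i]]))
  }
})

test_that("multiplicative zero replacement matches the closed form", {
  x <- matrix(c(0.5, 0.5, 0,
                0.2, 0.3, 0.5), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  rel <- count_matrix(x, relative = TRUE)
  out <- replace_zeros_czm(rel, library_sizes = c(100, 100))
  # delta = 0.65 * 1/100 = 0.0065; non-zeros x (1 - 0.0065)
  expect_equal(unname(unclass(out)[1, ]), c(0.496750, 0.496750, 0.0065),
               tolerance = 1e-12)
  # row without zeros is untouched
  expect_equal(unname(unclass(out)[2, ]), c(0.2, 0.3, 0.5))
})

test_that("zero replacement preserves closure and non-zero ratios", {
  set.seed(3)
  x <- matrix(rexp(6 * 10), 6, 10)
  x[sample(length(x), 12)] <- 0
  x[1, ] <- abs(x[1, ]) + 0.1          # one row with no zeros
  x <- x / rowSums(x)
  rel <- count_matrix(x, relative = TRUE)
  out <- suppressWarnings(replace_zeros_czm(rel, library_sizes = rep(5000, 6)))
  expect_true(all(unclass(out) > 0))
  expect_equal(unname(rowSums(out)), rep(1, 6), tolerance = 1e-9)
  for (i in 2:6) {
    nz <- which(x[i, ] > 0)
    expect_equal(unclass(out)[i, nz] / x[i, nz],
                 rep(unclass(out)[i, nz[1]] / x[i, nz[1]], length(nz)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # replacement bigger than an observed value warns
  y <- matrix(c(1e-4, 0.4, 0.5999, 0), 1, 4)
  y <- rbind(y, c(0.25, 0.25, 0.25, 0.25))
  expect_warning(replace_zeros_czm(count_matrix(y, relative = TRUE),
                                   library_sizes = c(100, 100)),
                 "exceeds an observed value")
})

test_that("clr transform has the closed form and its invariances", {
  u <- matrix(0.25, 2, 4)
  expect_equal(clr_transform(count_matrix(u, relative = TRUE)),
               matrix(0, 2, 4), ignore_attr = TRUE)

  x <- matrix(c(1, 2, 4, 8) / 15, 1, 4)
  x <- rbind(x, x)
  out <- clr_transform(x)
  expect_equal(out[1, ], log(2) * c(-1.5, -0.5, 0.5, 1.5), ignore_attr = TRUE)
  expect_equal(rowSums(out), c(0, 0), tolerance = 1e-12)

  # scale invariance: clr(c * x) = clr(x)
  expect_equal(clr_transform(3.7 * x), out, ignore_attr = TRUE)
  expect_error(clr_transform(matrix(c(1, 0, 2, 3), 2, 2)), "positive")
})

test_that("clr of closed counts is invariant to sequencing depth", {
  set.seed(5)
  base <- matrix(rpois(4 * 6, 40) + 1, 4, 6)
  deep <- base * c(10L, 1L, 5L, 2L)     # per-sample depth scaling
  f <- function(m) clr_transform(unclass(to_relative(count_matrix(m))))
  expect_equal(f(deep), f(base), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("column centering and autoscaling", {
  set.seed(8)
  X <- matrix(rnorm(30, sd = 3), 6, 5)
  X[, 5] <- 2                           # constant column
  c1 <- scale_columns(X, "center")
  expect_equal(colMeans(c1), rep(0, 5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_warning(c2 <- scale_columns(X, "autoscale"), "constant")
  expect_equal(apply(c2[, 1:4], 2, sd), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(c2[, 5], rep(0, 6), ignore_attr = TRUE)
})
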