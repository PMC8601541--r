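test_that("sum-to-zero codings and orthogonality in balanced designs", {
  md <- expand.grid(diet = c("A", "B", "C"), dose = c("lo", "hi"),
                    rep = 1:2)[, 1:2]
  d <- build_design(md, "diet*dose")
  expect_equal(d$terms, c("diet", "dose", "diet:dose"))
  expect_equal(unname(d$df), c(2L, 1L, 2L))
  expect_equal(colSums(d$matrices$diet), c(0, 0), ignore_attr = TRUE)
  # balanced 2x2 (subset): main effects and interaction mutually orthogonal
  md2 <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)[, 1:2]
  d2 <- build_design(md2, "a*b")
  M <- do.call(cbind, d2$matrices)
  G <- crossprod(M)
  expect_equal(G[upper.tri(G)], rep(0, 3), tolerance = 1e-12)
  expect_true(d2$balanced)
})

test_that("interaction-only models with a subject blocking factor build", {
  md <- expand.grid(subject = paste0("p", 1:4), day = c("d0", "d28"))
  md$treatment <- ifelse(md$subject %in% c("p1", "p2"), "placebo", "fibre")
  d <- suppressMessages(build_design(md, "treatment:day + subject"))
  expect_setequal(d$terms, c("subject", "treatment:day"))
  expect_true(all(d$df >= 1L))
  expect_error(build_design(data.frame(g = rep("only", 4)), "g"), "single level")
})

test_that("sequential partition reproduces a hand-computed 2x2 ANOVA", {
  # cell means with 2 replicates per cell, one response, no noise
  md <- expand.grid(a = c("m", "p"), b = c("u", "v"), rep = 1:2)[, 1:2]
  mu <- c(m.u = 10, p.u = 14, m.v = 20, p.v = 30)
  y <- mu[paste(md$a, md$b, sep = ".")]
  X <- cbind(y = y + c(0.5, -0.5)[rep(1:2, 4)])  # within-cell deviations
  d <- build_design(md, "a*b")
  dec <- anova_partition(scale_columns(X, "center"), d, "sequential")

  # independent oracle: classical ANOVA sums of squares from aov()
  fit <- summary(stats::aov(X[, 1] ~ a * b, data = md))[[1]]
  expect_equal(dec$ss[1:3], fit[["Sum Sq"]][1:3], tolerance = 1e-9)
  expect_equal(dec$ss[4], fit[["Sum Sq"]][4], tolerance = 1e-9)

  # effect matrices are the cell-mean deviations
  ab <- effect_matrix(dec, "a")
  ga <- tapply(X[, 1], md$a, mean) - mean(X[, 1])
  expect_equal(unname(ab[, 1]), as.vector(ga[as.character(md$a)]),
               tolerance = 1e-9)
  expect_equal(sum(dec$explained_variance_pct), 100, tolerance = 1e-6)
})

test_that("partial and sequential partitions agree on balanced designs", {
  set.seed(21)
  md <- expand.grid(a = c("x", "y", "z"), b = c("u", "v"), rep = 1:3)[, 1:2]
  X <- matrix(rnorm(18 * 7), 18, 7)
  d <- build_design(md, "a*b")
  s1 <- anova_partition(X, d, "sequential")
  s2 <- anova_partition(X, d, "partial")
  expect_equal(s1$ss, s2$ss, tolerance = 1e-9)
})

test_that("pure-noise explained variance matches its degrees of freedom", {
  # under the null each term's expected SS fraction is df_term/(n-1)
  set.seed(22)
  md <- expand.grid(a = c("x", "y", "z"), b = c("u", "v"), rep = 1:4)[, 1:2]
  d <- build_design(md, "a*b")
  n <- nrow(md)
  fracs <- replicate(400, {
    X <- matrix(rnorm(n * 3), n, 3)
    dec <- anova_partition(X, d, "sequential")
    dec$ss[1:3] / sum(dec$ss)
  })
  expect_equal(rowMeans(fracs), d$df / (n - 1), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("PERMANOVA on Euclidean distances equals the direct ANOVA partition", {
  set.seed(31)
  md <- expand.grid(diet = c("A", "B", "C"), dose = c("lo", "hi"),
                    rep = 1:3)[, 1:2]
  X <- matrix(rnorm(18 * 25), 18, 25,
              dimnames = list(paste0("s", 1:18), paste0("OTU", 1:25)))
  d <- build_design(md, "diet*dose")
  dec <- anova_partition(scale_columns(X, "center"), d, "sequential")
  pm <- permanova(distance_matrix(X, "euclidean"), d, n_perm = 19, seed = 1)
  expect_equal(pm$ss, dec$ss, tolerance = 1e-6)
  expect_equal(pm$explained_variance_pct, dec$explained_variance_pct,
               tolerance = 1e-6)
})

test_that("PERMANOVA agrees with vegan::adonis2 on a one-factor design", {
  set.seed(32)
  X <- toy_shifted_matrix(n_per_group = 4, p = 6)
  g <- factor(rep(c("a", "b"), each = 4))
  d <- build_design(data.frame(g = g), "g")
  pm <- permanova(distance_matrix(X, "euclidean"), d, n_perm = 999, seed = 9)
  ref <- vegan::adonis2(dist(X) ~ g, permutations = 999)
  expect_equal(unname(pm$ss[1]), ref$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(unname(pm$pseudo_f[1]), ref$F[1], tolerance = 1e-8)
  expect_equal(unname(pm$p_value[1]), ref$`Pr(>F)`[1], tolerance = 0.05)
})
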