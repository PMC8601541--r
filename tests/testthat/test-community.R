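test_that("ASCA permutation p equals exhaustive enumeration on a 6-sample toy", {
  X <- toy_shifted_matrix(shift = 1.2, seed = 4)
  g <- toy_group6()
  d <- build_design(data.frame(g = g), "g")
  fit <- asca(X, d, exact = TRUE)

  # independent oracle: between-group sum of squares over all label orders
  Xc <- scale_columns(X, "center")
  ss_between <- function(labels) {
    m1 <- colMeans(Xc[labels == "a", , drop = FALSE])
    m2 <- colMeans(Xc[labels == "b", , drop = FALSE])
    gm <- colMeans(Xc)
    3 * sum((m1 - gm)^2) + 3 * sum((m2 - gm)^2)
  }
  p_oracle <- enumeration_pvalue(g, ss_between)
  expect_equal(fit$p_value[1], p_oracle, tolerance = 1e-12)
})

test_that("ASCA on a null term gives small explained variance and flat p", {
  set.seed(12)
  md <- expand.grid(a = c("x", "y"), rep = 1:6)[, 1, drop = FALSE]
  pv <- replicate(40, {
    X <- matrix(rnorm(12 * 5), 12, 5)
    asca(X, build_design(md, "a"), n_perm = 59, seed = sample.int(1e6, 1))$p_value[1]
  })
  expect_gt(mean(pv), 0.3)       # roughly uniform, not concentrated at 0
  expect_lt(mean(pv < 0.05), 0.2)
})

test_that("ASCA scores and loadings reconstruct the effect matrix", {
  X <- toy_shifted_matrix(n_per_group = 4, p = 5, shift = 2)
  g <- factor(rep(c("a", "b"), each = 4))
  d <- build_design(data.frame(g = g), "g")
  fit <- asca(X, d, n_perm = 19, seed = 0, n_components = 1)
  comp <- asca_components(fit, "g")
  E <- effect_matrix(fit, "g")
  expect_equal(tcrossprod(comp$scores, comp$loadings), E, tolerance = 1e-8,
               ignore_attr = TRUE)  # rank-1 effect matrix: exact reconstruction
  expect_equal(crossprod(comp$loadings), diag(1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PERMANOVA exact p on duplicated shifted samples is 1/10", {
  base <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4)   # three identical rows
  X <- rbind(base, base + 5)
  rownames(X) <- paste0("s", 1:6)
  g <- toy_group6()
  d <- build_design(data.frame(g = g), "g")
  pm <- permanova(distance_matrix(X, "euclidean"), d, exact = TRUE)
  expect_gt(pm$explained_variance_pct[1], 99.9)
  expect_equal(pm$p_value[1], 0.1, tolerance = 1e-12)
})

test_that("50-50 MANOVA reduces to the classical F test for one response", {
  set.seed(41)
  y <- c(rnorm(4, 0), rnorm(4, 1.5))
  g <- factor(rep(c("a", "b"), each = 4))
  d <- build_design(data.frame(g = g), "g")
  X <- matrix(y, ncol = 1)
  ff <- ffmanova_community(X, d, n_perm = 999, seed = 2, scale = "center")
  f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(unname(attr(ff, "f5050")["g"]), f_classic, tolerance = 1e-9)
  p_classic <- summary(stats::aov(y ~ g))[[1]]$`Pr(>F)`[1]
  expect_lt(abs(ff$p_value[1] - p_classic), 0.05)
})

test_that("50-50 MANOVA permutation p matches enumeration on a 6-sample toy", {
  X <- toy_shifted_matrix(shift = 1, seed = 6)
  g <- toy_group6()
  d <- build_design(data.frame(g = g), "g")
  ff <- ffmanova_community(X, d, exact = TRUE)
  # oracle: recompute the same statistic definition from scratch per order
  Xs <- scale_columns(X, "autoscale")
  sv <- svd(Xs)
  npc <- which(cumsum(sv$d^2) / sum(sv$d^2) >= 0.5)[1]
  Tm <- Xs %*% sv$v[, 1:npc, drop = FALSE]
  f_stat <- function(labels) {
    a <- labels == "a"
    m1 <- colMeans(Tm[a, , drop = FALSE]); m2 <- colMeans(Tm[!a, , drop = FALSE])
    gm <- colMeans(Tm)
    ssh <- 3 * sum((m1 - gm)^2) + 3 * sum((m2 - gm)^2)
    res <- rbind(sweep(Tm[a, , drop = FALSE], 2, m1),
                 sweep(Tm[!a, , drop = FALSE], 2, m2))
    sse <- sum(res^2)
    (ssh / 1) / (sse / 4)
  }
  p_oracle <- enumeration_pvalue(g, f_stat)
  expect_equal(ff$p_value[1], p_oracle, tolerance = 1e-12)
})

test_that("ANOSIM statistic and p-value match vegan and enumeration", {
  X <- toy_shifted_matrix(shift = 2.5, seed = 9)
  g <- toy_group6()
  D <- distance_matrix(X, "euclidean")
  an <- anosim(D, g, exact = TRUE)
  ref <- vegan::anosim(stats::dist(X), g, permutations = 99)
  expect_equal(an$r_statistic, unname(ref$statistic), tolerance = 1e-12)

  # enumeration oracle for the p-value
  lower <- lower.tri(D)
  r <- rank(as.matrix(D)[lower])
  M <- 6 * 5 / 2
  stat <- function(labels) {
    same <- outer(labels, labels, "==")[lower]
    (mean(r[!same]) - mean(r[same])) / (M / 2)
  }
  expect_equal(an$p_value, enumeration_pvalue(g, stat), tolerance = 1e-12)
})

test_that("ANOSIM hits the boundary values", {
  # perfectly separated groups: all between > all within -> R = 1
  X <- rbind(matrix(rnorm(8, 0, 0.01), 4, 2), matrix(rnorm(8, 50, 0.01), 4, 2))
  g <- factor(rep(c("a", "b"), each = 4))
  an <- anosim(distance_matrix(X, "euclidean"), g, n_perm = 19, seed = 1)
  expect_equal(an$r_statistic, 1)
  # exchangeable data: R near 0 on average
  set.seed(10)
  rs <- replicate(60, {
    X0 <- matrix(rnorm(16), 8, 2)
    anosim(distance_matrix(X0, "euclidean"), g, n_perm = 1, seed = 1)$r_statistic
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(anosim(distance_matrix(X, "euclidean"),
                      factor(c("a", rep("b", 7))), n_perm = 9), "at least 2")
})

test_that("distance metrics match hand arithmetic", {
  X <- rbind(c(1, 0), c(0, 1))
  expect_equal(distance_matrix(X, "bray")[1, 2], 1)
  X2 <- rbind(c(1, 2, 3), c(2, 2, 3))
  expect_equal(distance_matrix(X2, "euclidean")[1, 2], 1)
  expect_equal(distance_matrix(X2, "bray")[1, 2], 1 / 13)
  expect_equal(distance_matrix(X2, "euclidean")[2, 2], 0)
  expect_error(distance_matrix(rbind(c(-1, 2), c(1, 1)), "bray"), "non-negative")
})
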