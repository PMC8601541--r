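test_that("moment matching recovers hand-computed Gamma parameters", {
  # group abundances (0.1, 0.2, 0.3): m = 0.2, v = 0.01 -> shape 4, rate 20
  counts <- rbind(c(100, 900), c(200, 800), c(300, 700),
                  c(500, 500), c(500, 500))
  dimnames(counts) <- list(paste0("s", 1:5), c("OTU1", "OTU2"))
  g <- factor(c("a", "a", "a", "b", "b"))
  par <- estimate_params(counts, g)
  expect_equal(par$shape["OTU1", "a"], 4, tolerance = 1e-9)
  expect_equal(par$rate["OTU1", "a"], 20, tolerance = 1e-9)
  # constant group: variance floor -> shape = 1e4, rate = 1e4 / m
  expect_equal(par$shape["OTU1", "b"], 1e4, tolerance = 1e-9)
  expect_equal(par$rate["OTU1", "b"], 1e4 / 0.5, tolerance = 1e-9)
  # moment identity: shape/rate = group mean
  expect_equal(par$shape["OTU2", "a"] / par$rate["OTU2", "a"], 0.8,
               tolerance = 1e-9)
  expect_error(estimate_params(counts, factor(c("a", "a", "a", "b", "c"))),
               ">= 2 samples")
})

test_that("the default template is deterministic, closed and long-tailed", {
  t1 <- make_default_template(n_otus = 507, seed = 3)
  t2 <- make_default_template(n_otus = 507, seed = 3)
  expect_identical(t1$shape, t2$shape)
  expect_identical(t1$rate, t2$rate)
  mu <- t1$shape / t1$rate
  expect_equal(colSums(mu), rep(1, 6), tolerance = 1e-9, ignore_attr = TRUE)
  # a few dominant OTUs above 1%, but fewer than 10% of all OTUs
  frac_dominant <- mean(mu[, 1] > 0.01)
  expect_gt(frac_dominant, 0)
  expect_lt(frac_dominant, 0.10)
})

test_that("scenario injection places the right effects in the right cells", {
  tpl <- make_default_template(n_otus = 507, seed = 5)
  inj0 <- apply_scenario(tpl, scenario_spec(0, 0, 1))
  expect_identical(inj0$params$rate, tpl$rate)
  expect_false(any(inj0$truth))

  for (nm in c("few_low", "many_high")) {
    inj <- apply_scenario(tpl, scenario_preset(nm, seed = 9))
    expect_equal(sum(inj$truth), if (nm == "few_low") 10 else 254)
    lfc <- inj$log2fc[inj$truth]
    rng <- if (nm == "few_low") c(3, 4) else c(8, 9)
    expect_true(all(lfc >= rng[1] & lfc <= rng[2]))
    expect_true(all(inj$log2fc[!inj$truth] == 0))
    # no dose effect: within each diet, parameters identical across doses
    for (dl in unique(inj$params$groups$diet)) {
      cells <- which(inj$params$groups$diet == dl)
      expect_equal(inj$params$rate[, cells[1]], inj$params$rate[, cells[2]])
    }
    # relative to a non-affected OTU, spiked OTUs change by exactly 2^lfc
    # between the affected and a reference diet (renormalisation cancels)
    aff <- which(inj$params$groups$diet == "A")[1]
    other <- which(inj$params$groups$diet == "B")[1]
    mu <- inj$params$shape / inj$params$rate
    null_otu <- which(!inj$truth)[1]
    rr <- (mu[inj$truth, aff] / mu[inj$truth, other]) /
      (mu[null_otu, aff] / mu[null_otu, other])
    expect_equal(unname(log2(rr)), unname(lfc), tolerance = 1e-9)
  }
  expect_error(apply_scenario(small_template(n_otus = 20),
                              scenario_spec(30, 3, 4)), "exceeds")
})

test_that("simulated counts close exactly to the drawn depth", {
  tpl <- small_template()
  ds <- sample_counts(tpl, seed = 2)
  expect_true(all(rowSums(ds$counts) == library_sizes(ds$counts)))
  expect_equal(nrow(ds$counts), 6 * 3)
  # degenerate urn: one OTU with all the mass gets every count
  par1 <- sim_params(shape = cbind(c(5, 0)), rate = cbind(c(5, 1)),
                     groups = tibble::tibble(diet = "A"), n_per_cell = 3,
                     depths = c(1000L))
  ds1 <- sample_counts(par1, seed = 4)
  expect_true(all(unclass(ds1$counts)[, 1] == 1000L))
  expect_true(all(unclass(ds1$counts)[, 2] == 0L))
})

test_that("sampling moments match the Gamma intensity means", {
  # 200 replicate samples of one group: observed mean relative abundances
  # within 3 Monte-Carlo standard errors of the normalised Gamma means
  set.seed(12)
  p <- 20
  shp <- runif(p, 1, 4)
  mu <- rexp(p); mu <- mu / sum(mu)
  par <- sim_params(shape = cbind(shp), rate = cbind(shp / mu),
                    groups = tibble::tibble(diet = "A"), n_per_cell = 200,
                    depths = list(meanlog = log(5e4), sdlog = 0.01))
  ds <- sample_counts(par, seed = 13)
  rel <- unclass(ds$counts) / rowSums(ds$counts)
  obs <- colMeans(rel)
  mc_se <- apply(rel, 2, sd) / sqrt(200)
  expect_true(all(abs(obs - mu) <= 3 * mc_se + 1e-6))
})

test_that("parameter estimation recovers the generating group means", {
  set.seed(14)
  p <- 15
  shp <- runif(p, 1, 4)
  mu <- rexp(p); mu <- mu / sum(mu)
  par <- sim_params(shape = cbind(shp), rate = cbind(shp / mu),
                    groups = tibble::tibble(diet = "A"), n_per_cell = 150,
                    depths = list(meanlog = log(5e4), sdlog = 0.01))
  ds <- sample_counts(par, seed = 15)
  est <- estimate_params(unclass(ds$counts), rep("A", nrow(ds$counts)))
  mu_hat <- est$shape[, 1] / est$rate[, 1]
  expect_equal(unname(mu_hat), mu, tolerance = 0.15)
})

test_that("scenario batches are reproducible and correctly labelled", {
  tpl <- small_template(n_otus = 30)
  b1 <- generate_scenario_batch(tpl, "few_low", n_datasets = 3, seed = 42)
  b2 <- generate_scenario_batch(tpl, "few_low", n_datasets = 3, seed = 42)
  expect_identical(lapply(b1, function(d) unclass(d$counts)),
                   lapply(b2, function(d) unclass(d$counts)))
  for (d in b1) expect_equal(sum(d$truth), 10)
  # distinct data sets get distinct draws
  expect_false(identical(unclass(b1[[1]]$counts), unclass(b1[[2]]$counts)))
  expect_error(generate_scenario_batch(tpl, "nope", 2, 1), "unknown scenario")
})
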