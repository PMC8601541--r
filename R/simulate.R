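#' Simulation parameters for the Gamma / multivariate-hypergeometric model
#'
#' Counts are simulated in two steps: each OTU's expected relative
#' intensity in a sample is drawn from a per-OTU, per-group Gamma
#' distribution, and the observed counts are then a multivariate
#' hypergeometric draw of the sample's sequencing depth from an urn built
#' from those intensities — so each sample's counts sum exactly to its
#' depth.
#'
#' @param shape,rate OTU x group matrices of Gamma parameters (shape 0
#'   marks an OTU absent from a group).
#' @param groups tibble describing the design cells (one row per group,
#'   factor columns such as `diet`, `dose`).
#' @param n_per_cell samples per design cell.
#' @param depths either a numeric vector of observed depths (resampled) or
#'   a list `list(meanlog=, sdlog=)` for a log-normal depth sampler.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(shape, rate, groups, n_per_cell, depths) {
  shape <- as.matrix(shape); rate <- as.matrix(rate)
  stopifnot(all(dim(shape) == dim(rate)), nrow(groups) == ncol(shape))
  if (any(shape < 0) || any(rate < 0)) stop("negative Gamma parameters", call. = FALSE)
  if (is.null(rownames(shape))) {
    rownames(shape) <- rownames(rate) <- paste0("OTU", seq_len(nrow(shape)))
  }
  structure(list(shape = shape, rate = rate, groups = tibble::as_tibble(groups),
                 n_per_cell = n_per_cell, depths = depths),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d OTUs x %d groups, %d sample(s)/cell\n",
              nrow(x$shape), ncol(x$shape), x$n_per_cell))
  invisible(x)
}

# Mean intensities (shape/rate), zeros where the OTU is absent
.sim_means <- function(params) {
  mu <- params$shape / params$rate
  mu[params$shape == 0] <- 0
  mu
}

#' Estimate Gamma intensity parameters from a template count matrix
#'
#' Moment-matching per OTU and group on relative abundances: with group
#' mean m and variance v, shape = m^2/v and rate = m/v. The variance is
#' floored at m^2 * `var_floor` so OTUs with (nearly) constant abundance do
#' not produce unbounded shapes. Observed sequencing depths are kept as the
#' empirical depth sampler.
#'
#' @param counts samples x OTUs count matrix.
#' @param groups data frame (or factor) of design-cell labels per sample;
#'   a data frame may carry several factor columns (e.g. diet, dose).
#' @param n_per_cell samples per cell for later simulation; defaults to the
#'   smallest observed group size.
#' @param var_floor relative variance floor (default 1e-4, i.e. maximal
#'   shape 1/1e-4 = 1e4).
#' @return a [sim_params()] object.
#' @export
estimate_params <- function(counts, groups, n_per_cell = NULL, var_floor = 1e-4) {
  X <- as.matrix(counts)
  if (is.factor(groups) || is.character(groups)) {
    groups <- data.frame(group = as.factor(groups))
  }
  groups <- as.data.frame(groups)
  cell <- interaction(groups, drop = TRUE, sep = "_")
  if (any(table(cell) < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  rel <- X / rowSums(X)
  G <- nlevels(cell)
  p <- ncol(X)
  shape <- rate <- matrix(0, p, G,
                          dimnames = list(colnames(X), levels(cell)))
  for (g in seq_len(G)) {
    idx <- which(cell == levels(cell)[g])
    m <- colMeans(rel[idx, , drop = FALSE])
    v <- apply(rel[idx, , drop = FALSE], 2L, stats::var)
    v <- pmax(v, m^2 * var_floor)
    pos <- m > 0
    shape[pos, g] <- m[pos]^2 / v[pos]
    rate[pos, g] <- m[pos] / v[pos]
  }
  gtab <- dplyr::distinct(dplyr::bind_cols(groups, .cell = cell))
  gtab <- gtab[match(levels(cell), gtab$.cell), , drop = FALSE]
  gtab$.cell <- NULL
  sim_params(shape, rate, gtab,
             n_per_cell = n_per_cell %||% min(table(cell)),
             depths = rowSums(X))
}

#' Fully synthetic template parameters
#'
#' A no-download stand-in for a real template: log-normal mean intensities
#' give a realistic abundance profile (a few dominant OTUs above 1%
#' relative abundance and a long tail of rare ones), per-OTU Gamma shapes
#' drawn uniformly give overdispersed counts, and all groups share the same
#' parameters (a global null; effects are injected with
#' [apply_scenario()]). Deterministic in `seed`.
#'
#' @param n_otus number of OTUs (default 507, a typical filtered 16S table).
#' @param n_per_cell samples per design cell (default 8; 48 samples over a
#'   3 x 2 design, the scale of a typical rodent feeding trial).
#' @param diet_levels,dose_levels level names of the two crossed factors.
#' @param depth_mean,depth_cv mean and coefficient of variation of the
#'   log-normal sequencing-depth sampler (default 5e4, 0.25).
#' @param intensity_sdlog spread of the log-normal mean intensities
#'   (default 2).
#' @param shape_range range of per-OTU Gamma shapes (default c(0.1, 1.5);
#'   biological CVs of roughly 80-320%, which reproduces the community
#'   effect sizes reported for the benchmark scenarios, about 5% explained
#'   variance with 10 weakly changed OTUs and 30-35% with 254 strongly
#'   changed ones).
#' @param seed integer seed.
#' @return a [sim_params()] object.
#' @export
make_default_template <- function(n_otus = 507, n_per_cell = 8,
                                  diet_levels = c("A", "B", "C"),
                                  dose_levels = c("low", "high"),
                                  depth_mean = 5e4, depth_cv = 0.25,
                                  intensity_sdlog = 2,
                                  shape_range = c(0.1, 1.5), seed = 0) {
  if (n_otus < 10) stop("need at least 10 OTUs", call. = FALSE)
  set.seed(seed)
  mu <- stats::rlnorm(n_otus, meanlog = 0, sdlog = intensity_sdlog)
  mu <- mu / sum(mu)
  shp <- stats::runif(n_otus, shape_range[1L], shape_range[2L])
  groups <- tidyr::expand_grid(diet = diet_levels, dose = dose_levels)
  G <- nrow(groups)
  shape <- matrix(shp, n_otus, G)
  rate <- matrix(shp / mu, n_otus, G)
  rownames(shape) <- rownames(rate) <- sprintf("OTU%03d", seq_len(n_otus))
  sdlog <- sqrt(log(1 + depth_cv^2))
  sim_params(shape, rate, groups, n_per_cell,
             depths = list(meanlog = log(depth_mean) - sdlog^2 / 2, sdlog = sdlog))
}

#' Scenario specification for injected differential abundance
#'
#' @param n_da number of differentially abundant OTUs.
#' @param log2fc_low,log2fc_high bounds of the uniform log2 fold-change
#'   distribution.
#' @param affected_level diet level whose intensities are multiplied.
#' @param seed integer seed for OTU selection and fold-change draws.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_da, log2fc_low, log2fc_high,
                          affected_level = NULL, seed = 0) {
  if (n_da < 0) stop("n_da must be >= 0", call. = FALSE)
  if (n_da > 0 && log2fc_low >= log2fc_high) {
    stop("log2fc_low must be < log2fc_high", call. = FALSE)
  }
  structure(list(n_da = n_da, log2fc_low = log2fc_low,
                 log2fc_high = log2fc_high, affected_level = affected_level,
                 seed = seed),
            class = "scenario_spec")
}

#' Named scenario presets
#'
#' `few_low`: 10 OTUs, log2 fold changes U\[3,4\]; `few_high`: 10, U\[8,9\];
#' `many_low`: 254, U\[3,4\]; `many_high`: 254, U\[8,9\].
#'
#' @param name one of `"few_low"`, `"few_high"`, `"many_low"`, `"many_high"`.
#' @param seed integer seed.
#' @param affected_level diet level receiving the effect (default: first).
#' @return a [scenario_spec()].
#' @export
scenario_preset <- function(name = c("few_low", "few_high", "many_low", "many_high"),
                            seed = 0, affected_level = NULL) {
  name <- match.arg(name)
  n_da <- if (startsWith(name, "few")) 10L else 254L
  bounds <- if (endsWith(name, "low")) c(3, 4) else c(8, 9)
  scenario_spec(n_da, bounds[1L], bounds[2L], affected_level, seed)
}

#' Inject a fold-change scenario into simulation parameters
#'
#' Chooses `n_da` OTUs uniformly without replacement, draws each a log2
#' fold change from U\[low, high\], and multiplies those OTUs' intensity
#' means (rates divided, keeping the Gamma CV) in every design cell whose
#' diet equals the affected level. The second factor (dose) is untouched.
#' Group intensities are then re-normalised, so the compositional knock-on
#' effect of the spiked OTUs on the others is present (disable with
#' `renormalize = FALSE`).
#'
#' @param params a [sim_params()] object with a `diet` column in `$groups`.
#' @param scenario a [scenario_spec()] or preset name.
#' @param renormalize re-close group mean intensities to 1 (default TRUE).
#' @return list with `params` (modified), `truth` (named logical), and
#'   `log2fc` (named numeric, 0 for non-affected OTUs).
#' @export
apply_scenario <- function(params, scenario, renormalize = TRUE) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(params, "sim_params"), inherits(scenario, "scenario_spec"))
  p <- nrow(params$shape)
  if (scenario$n_da > p) stop("n_da exceeds the number of OTUs", call. = FALSE)
  diet <- params$groups$diet %||% params$groups[[1L]]
  affected <- scenario$affected_level %||% diet[1L]
  if (!affected %in% diet) stop("affected_level not a diet level", call. = FALSE)

  truth <- stats::setNames(rep(FALSE, p), rownames(params$shape))
  lfc <- stats::setNames(rep(0, p), rownames(params$shape))
  if (scenario$n_da > 0) {
    set.seed(scenario$seed)
    da <- sample.int(p, scenario$n_da)
    truth[da] <- TRUE
    lfc[da] <- stats::runif(scenario$n_da, scenario$log2fc_low, scenario$log2fc_high)
    cells <- which(diet == affected)
    for (g in cells) {
      params$rate[da, g] <- params$rate[da, g] / 2^lfc[da]
    }
  }
  if (renormalize) {
    mu <- .sim_means(params)
    for (g in seq_len(ncol(params$shape))) {
      params$rate[, g] <- params$rate[, g] * sum(mu[, g])
    }
  }
  list(params = params, truth = truth, log2fc = lfc)
}

# Multivariate hypergeometric draw of N items from urn K (integer counts),
# via sequential conditional univariate hypergeometric draws.
.rmhg <- function(K, N) {
  x <- integer(length(K))
  rem <- sum(K)
  for (j in seq_along(K)) {
    if (N <= 0L) break
    rem <- rem - K[j]
    if (rem <= 0L) { x[j] <- N; N <- 0L; break }
    x[j] <- stats::rhyper(1L, K[j], rem, N)
    N <- N - x[j]
  }
  x
}

#' Draw one simulated data set
#'
#' For each sample: per-OTU intensities from their Gamma distributions, an
#' urn of `round(intensity / sum(intensity) * urn_scale)` items, a depth
#' from the depth sampler, and a multivariate hypergeometric draw of that
#' depth from the urn, so counts sum exactly to the depth. The urn scale is
#' doubled automatically (with a message) if a drawn depth exceeds the urn.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param truth,log2fc optional ground-truth labels from [apply_scenario()]
#'   to carry on the result.
#' @param urn_scale urn size (default 1e6 items).
#' @return object of class `sim_dataset`: list with `counts`
#'   ([count_matrix()]), `metadata` (tibble with `sample_id` + factor
#'   columns), `truth`, `log2fc`.
#' @export
sample_counts <- function(params, seed = 0, truth = NULL, log2fc = NULL,
                          urn_scale = 1e6) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  G <- ncol(params$shape)
  p <- nrow(params$shape)
  n <- G * params$n_per_cell
  counts <- matrix(0L, n, p)
  meta <- params$groups[rep(seq_len(G), each = params$n_per_cell), , drop = FALSE]
  r <- 0L
  for (g in seq_len(G)) {
    for (s in seq_len(params$n_per_cell)) {
      r <- r + 1L
      lam <- numeric(p)
      pos <- params$shape[, g] > 0
      lam[pos] <- stats::rgamma(sum(pos), shape = params$shape[pos, g],
                                rate = params$rate[pos, g])
      if (sum(lam) <= 0) stop("degenerate sample: all intensities zero", call. = FALSE)
      N <- if (is.list(params$depths)) {
        as.integer(round(stats::rlnorm(1L, params$depths$meanlog, params$depths$sdlog)))
      } else {
        as.integer(params$depths[sample.int(length(params$depths), 1L)])
      }
      N <- max(N, 1L)
      scale <- urn_scale
      repeat {
        K <- round(lam / sum(lam) * scale)
        if (sum(K) >= N) break
        scale <- scale * 2
        message("urn scale doubled to ", scale)
      }
      counts[r, ] <- .rmhg(K, N)
    }
  }
  rownames(counts) <- sprintf("S%03d", seq_len(n))
  colnames(counts) <- rownames(params$shape)
  meta <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(counts)), meta)
  structure(list(counts = count_matrix(counts), metadata = meta,
                 truth = truth, log2fc = log2fc),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d samples x %d OTUs%s\n",
              nrow(x$counts), ncol(x$counts),
              if (!is.null(x$truth)) sprintf(", %d true positives", sum(x$truth)) else ""))
  invisible(x)
}

# Deterministic per-dataset seed derivation (counter-based, < 2^31)
.derive_seed <- function(master, scenario_idx, dataset_idx) {
  as.integer((as.numeric(master) + 99991 * scenario_idx + 7919 * dataset_idx) %%
               2147483647)
}

#' Generate a batch of simulated data sets for one scenario
#'
#' @param template a [sim_params()] object (the null template).
#' @param scenario_name preset name (see [scenario_preset()]).
#' @param n_datasets number of data sets (100 in the full design).
#' @param seed master seed; each data set gets an independent derived seed.
#' @param urn_scale passed to [sample_counts()].
#' @return list of `sim_dataset` objects.
#' @export
generate_scenario_batch <- function(template, scenario_name, n_datasets = 100,
                                    seed = 0, urn_scale = 1e6) {
  sc_idx <- match(scenario_name, c("few_low", "few_high", "many_low", "many_high"))
  if (is.na(sc_idx)) stop("unknown scenario: ", scenario_name, call. = FALSE)
  lapply(seq_len(n_datasets), function(i) {
    ds_seed <- .derive_seed(seed, sc_idx, i)
    sc <- scenario_preset(scenario_name, seed = ds_seed)
    inj <- apply_scenario(template, sc)
    sample_counts(inj$params, seed = ds_seed + 1L, truth = inj$truth,
                  log2fc = inj$log2fc, urn_scale = urn_scale)
  })
}
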