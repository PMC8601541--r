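#' Run the simulation benchmark across scenarios and methods
#'
#' For each scenario and each simulated data set: simulate counts from the
#' template, preprocess exactly as experimental data (closure, abundance/
#' prevalence filter, multiplicative zero replacement, clr), run the
#' requested community-level tests and OTU-level procedures, and collect
#' community detection (term p-value < `alpha`), explained variances,
#' TPR/TNR at each method's own significance rule, pairwise Spearman rank
#' agreement and abundance-dependence correlations. OTUs removed by the
#' filter count as "not called" in TPR/TNR. Method failures on individual
#' data sets are recorded and the run continues.
#'
#' @param template a [sim_params()] object (see [make_default_template()] or
#'   [estimate_params()]).
#' @param scenarios character vector of preset names.
#' @param community_methods subset of `c("asca", "ffmanova", "permanova",
#'   "anosim")`.
#' @param otu_methods subset of `c("rotation", "simper", "asca_uve",
#'   "ancom", "dirichlet_clr", "nbglm")`.
#' @param n_datasets data sets per scenario (100 in the full design).
#' @param alpha community detection level (0.05).
#' @param n_perm permutations for the permutation tests (999 by
#'   convention).
#' @param n_mc Monte-Carlo instances for the Dirichlet clr test.
#' @param uve_rep UVE repetitions for the ASCA OTU ranking.
#' @param seed master seed; every stochastic step uses a seed derived from
#'   it, so reruns are identical.
#' @param term the tested factor (default `"diet"`; its first level is the
#'   affected one and the pairwise contrast is first vs second level).
#' @return object of class `benchmark_result`: list of tibbles `community`,
#'   `otu`, `agreement`, `failures` plus the run settings.
#' @export
run_benchmark <- function(template,
                          scenarios = c("few_low", "few_high", "many_low", "many_high"),
                          community_methods = c("asca", "ffmanova", "permanova", "anosim"),
                          otu_methods = c("rotation", "simper", "asca_uve",
                                          "ancom", "dirichlet_clr", "nbglm"),
                          n_datasets = 100, alpha = 0.05, n_perm = 999,
                          n_mc = 128, uve_rep = 100, seed = 0, term = "diet") {
  stopifnot(inherits(template, "sim_params"))
  community <- otu <- agreement <- failures <- list()
  for (sc in scenarios) {
    sc_idx <- match(sc, c("few_low", "few_high", "many_low", "many_high"))
    for (i in seq_len(n_datasets)) {
      ds_seed <- .derive_seed(seed, sc_idx, i)
      inj <- apply_scenario(template, scenario_preset(sc, seed = ds_seed))
      ds <- sample_counts(inj$params, seed = ds_seed + 1L, truth = inj$truth,
                          log2fc = inj$log2fc)
      res <- .analyse_dataset(ds, term = term,
                              community_methods = community_methods,
                              otu_methods = otu_methods, alpha = alpha,
                              n_perm = n_perm, n_mc = n_mc, uve_rep = uve_rep,
                              seed = ds_seed)
      if (nrow(res$community)) {
        community[[length(community) + 1L]] <-
          dplyr::mutate(res$community, scenario = sc, dataset = i, .before = 1L)
      }
      if (nrow(res$otu)) {
        otu[[length(otu) + 1L]] <-
          dplyr::mutate(res$otu, scenario = sc, dataset = i, .before = 1L)
      }
      if (nrow(res$agreement)) {
        agreement[[length(agreement) + 1L]] <-
          dplyr::mutate(res$agreement, scenario = sc, dataset = i, .before = 1L)
      }
      if (nrow(res$failures)) {
        failures[[length(failures) + 1L]] <-
          dplyr::mutate(res$failures, scenario = sc, dataset = i, .before = 1L)
      }
    }
  }
  structure(list(
    community = dplyr::bind_rows(community),
    otu = dplyr::bind_rows(otu),
    agreement = dplyr::bind_rows(agreement),
    failures = dplyr::bind_rows(failures),
    n_datasets = n_datasets, alpha = alpha, seed = seed,
    scenarios = scenarios, community_methods = community_methods,
    otu_methods = otu_methods
  ), class = "benchmark_result")
}

# All methods on one simulated data set. Returns tibbles; never throws for
# an individual method failure.
.analyse_dataset <- function(ds, term, community_methods, otu_methods,
                             alpha, n_perm, n_mc, uve_rep, seed) {
  md <- as.data.frame(ds$metadata)
  factors <- setdiff(names(md), "sample_id")
  cells <- combine_factors(md, factors)
  fail <- list()
  note_failure <- function(method, e) {
    fail[[length(fail) + 1L]] <<- tibble::tibble(method = method,
                                                 error = conditionMessage(e))
    NULL
  }
  prep <- tryCatch(suppressWarnings(preprocess_counts(ds$counts, cells)),
                   error = function(e) note_failure("preprocess", e))
  empty <- list(community = tibble::tibble(), otu = tibble::tibble(),
                agreement = tibble::tibble(),
                failures = dplyr::bind_rows(fail))
  if (is.null(prep)) return(empty)

  other_factors <- setdiff(factors, term)
  form <- if (length(other_factors)) paste0(term, "*", other_factors[1L]) else term
  design <- build_design(md, form)
  lv <- levels(droplevels(as.factor(md[[term]])))
  pair <- lv[1:2]

  comm <- list()
  asca_fit <- NULL
  if ("asca" %in% community_methods || "asca_uve" %in% otu_methods) {
    asca_fit <- tryCatch(
      asca(prep$clr, design, n_perm = n_perm, seed = seed + 11L),
      error = function(e) note_failure("asca", e))
  }
  if ("asca" %in% community_methods && !is.null(asca_fit)) {
    comm$asca <- tibble::tibble(
      method = "asca", term = term,
      p_value = asca_fit$p_value[asca_fit$term == term],
      explained_pct = asca_fit$explained_variance_pct[asca_fit$term == term])
  }
  if ("ffmanova" %in% community_methods) {
    ff <- tryCatch(
      ffmanova_community(prep$clr, design, n_perm = n_perm, seed = seed + 12L),
      error = function(e) note_failure("ffmanova", e))
    if (!is.null(ff)) {
      comm$ffmanova <- tibble::tibble(
        method = "ffmanova", term = term,
        p_value = ff$p_value[ff$term == term],
        explained_pct = ff$explained_variance_pct[ff$term == term])
    }
  }
  if ("permanova" %in% community_methods) {
    pm <- tryCatch({
      D <- distance_matrix(prep$clr, "euclidean")
      permanova(D, design, n_perm = n_perm, seed = seed + 13L)
    }, error = function(e) note_failure("permanova", e))
    if (!is.null(pm)) {
      comm$permanova <- tibble::tibble(
        method = "permanova", term = term,
        p_value = pm$p_value[pm$term == term],
        explained_pct = pm$explained_variance_pct[pm$term == term])
    }
  }
  if ("anosim" %in% community_methods) {
    an <- tryCatch({
      D <- distance_matrix(prep$clr, "euclidean")
      anosim(D, cells, n_perm = n_perm, seed = seed + 14L)
    }, error = function(e) note_failure("anosim", e))
    if (!is.null(an)) {
      comm$anosim <- tibble::tibble(
        method = "anosim", term = "combined",
        p_value = an$p_value, explained_pct = 100 * an$r_statistic)
    }
  }

  rankings <- list()
  if ("rotation" %in% otu_methods) {
    rankings$rotation <- tryCatch(
      rotation_pvalues(prep$clr, design, term, n_rot = 0),
      error = function(e) note_failure("rotation", e))
  }
  if ("simper" %in% otu_methods) {
    rankings$simper <- tryCatch(
      simper(prep$rel, md[[term]], pair, n_perm = n_perm, seed = seed + 15L),
      error = function(e) note_failure("simper", e))
  }
  if ("asca_uve" %in% otu_methods && !is.null(asca_fit)) {
    rankings$asca_uve <- tryCatch(
      asca_otu_ranking(asca_fit, term, md[[term]], pair,
                       n_rep = uve_rep, seed = seed + 16L),
      error = function(e) note_failure("asca_uve", e))
  }
  if ("ancom" %in% otu_methods) {
    rankings$ancom <- tryCatch(
      ancom_w(prep$rel_pos, md, term,
              covariates = if (length(other_factors)) other_factors else NULL),
      error = function(e) note_failure("ancom", e))
  }
  kept <- colnames(prep$rel)
  if ("dirichlet_clr" %in% otu_methods) {
    rankings$dirichlet_clr <- tryCatch(
      dirichlet_clr_test(unclass(ds$counts)[, kept, drop = FALSE], md, term,
                         levels_pair = pair, n_mc = n_mc, seed = seed + 17L),
      error = function(e) note_failure("dirichlet_clr", e))
  }
  if ("nbglm" %in% otu_methods) {
    rankings$nbglm <- tryCatch(
      nbglm_test(unclass(ds$counts)[, kept, drop = FALSE], md, term,
                 levels_pair = pair,
                 covariates = if (length(other_factors)) other_factors else NULL),
      error = function(e) note_failure("nbglm", e))
  }
  rankings <- Filter(Negate(is.null), rankings)

  otu_rows <- list()
  if (!is.null(ds$truth)) {
    for (mname in names(rankings)) {
      tab <- rankings[[mname]]
      calls <- stats::setNames(rep(FALSE, length(ds$truth)), names(ds$truth))
      calls[tab$otu_id] <- tab$significant
      perf <- tpr_tnr(calls, ds$truth)
      ab <- abundance_dependence(tab, prep$rel)
      # extremity correlation: do abundant OTUs sit at the statistic's
      # extremes? (the diagnostic pattern of the ANCOM W statistic)
      log_ma <- log10(pmax(colMeans(prep$rel)[tab$otu_id],
                           .Machine$double.xmin))
      ext_rho <- stats::cor(abs(tab$statistic - stats::median(tab$statistic)),
                            log_ma, method = "spearman")
      otu_rows[[mname]] <- tibble::tibble(
        method = mname, tpr = perf$tpr, tnr = perf$tnr,
        n_called = sum(tab$significant), abundance_rho = ab$rho,
        extremity_rho = ext_rho)
    }
  }
  agree <- if (length(rankings) >= 2L) {
    spearman_agreement(rankings)
  } else tibble::tibble()

  list(community = dplyr::bind_rows(comm),
       otu = dplyr::bind_rows(otu_rows),
       agreement = agree,
       failures = dplyr::bind_rows(fail))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d scenario(s) x %d data set(s), alpha = %g, seed = %d\n",
              length(x$scenarios), x$n_datasets, x$alpha, x$seed))
  if (nrow(x$failures)) {
    cat(sprintf("  %d method failure(s) recorded\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Summary tables of a benchmark run
#'
#' Aggregates a [run_benchmark()] result into four report tables:
#' per-scenario community detection and mean explained variance, TPR/TNR
#' per OTU method, median pairwise Spearman agreement, and mean
#' abundance-dependence correlation.
#'
#' @param result a `benchmark_result`.
#' @return list of tibbles `detection`, `tpr_tnr`, `spearman`, `abundance`.
#' @export
summarize_benchmark <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  alpha <- result$alpha
  detection <- if (nrow(result$community)) {
    result$community |>
      dplyr::group_by(.data$scenario, .data$method) |>
      dplyr::summarise(
        n_datasets = dplyr::n(),
        detection_pct = 100 * mean(.data$p_value < alpha),
        mean_explained_pct = mean(.data$explained_pct), .groups = "drop")
  } else tibble::tibble()
  tpr_tnr_tab <- if (nrow(result$otu)) {
    result$otu |>
      dplyr::group_by(.data$scenario, .data$method) |>
      dplyr::summarise(
        n_datasets = dplyr::n(),
        mean_tpr = mean(.data$tpr, na.rm = TRUE),
        mean_tnr = mean(.data$tnr, na.rm = TRUE),
        mean_called = mean(.data$n_called), .groups = "drop")
  } else tibble::tibble()
  spearman <- if (nrow(result$agreement)) {
    result$agreement |>
      dplyr::group_by(.data$scenario, .data$method1, .data$method2) |>
      dplyr::summarise(median_rho = stats::median(.data$rho),
                       n_datasets = dplyr::n(), .groups = "drop")
  } else tibble::tibble()
  abundance <- if (nrow(result$otu)) {
    result$otu |>
      dplyr::group_by(.data$scenario, .data$method) |>
      dplyr::summarise(mean_abs_abundance_rho = mean(abs(.data$abundance_rho)),
                       .groups = "drop")
  } else tibble::tibble()
  list(detection = detection, tpr_tnr = tpr_tnr_tab, spearman = spearman,
       abundance = abundance)
}

#' @rdname run_benchmark
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @export
tidy.benchmark_result <- function(x, ...) summarize_benchmark(x)$detection

#' @rdname run_benchmark
#' @export
glance.benchmark_result <- function(x, ...) {
  tibble::tibble(scenarios = length(x$scenarios),
                 n_datasets = x$n_datasets,
                 alpha = x$alpha, seed = x$seed,
                 n_failures = nrow(x$failures))
}
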