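#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of per-term explained variance
#'
#' @param object an `effect_decomposition` (ASCA, 50-50 MANOVA or PERMANOVA
#'   result).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.effect_decomposition <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term,
                                   y = .data$explained_variance_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      is.na(.data$p_value), "",
      sprintf("p = %.3g", .data$p_value))), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Explained variance (%)") +
    ggplot2::theme_minimal()
}

#' Scores plot of one ASCA effect matrix
#'
#' @param fit an [asca()] result.
#' @param term term label.
#' @param group optional factor used to colour the samples.
#' @return a ggplot object.
#' @export
plot_asca_scores <- function(fit, term, group = NULL) {
  comp <- asca_components(fit, term)
  df <- tibble::tibble(pc1 = comp$scores[, 1L],
                       pc2 = if (ncol(comp$scores) > 1L) comp$scores[, 2L] else 0)
  if (!is.null(group)) df$group <- as.factor(group)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = paste("ASCA scores:", term)) +
    ggplot2::theme_minimal()
  if (is.null(df$group)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Abundance-versus-statistic diagnostic plot
#'
#' The scatter of log mean relative abundance against the ranking
#' statistic (the diagnostic that exposes abundance-dependent rankings,
#' most visibly for the ANCOM W statistic).
#'
#' @param object a [ranking_table()] carrying `mean_rel_abundance`, or the
#'   output of [abundance_dependence()].
#' @param rel optional relative-abundance matrix if the table has no
#'   `mean_rel_abundance` column.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ranking_table <- function(object, rel = NULL, ...) {
  if (!"mean_rel_abundance" %in% names(object)) {
    if (is.null(rel)) stop("provide rel to compute mean abundances", call. = FALSE)
    object$mean_rel_abundance <- colMeans(as.matrix(rel))[object$otu_id]
  }
  ggplot2::ggplot(tibble::as_tibble(as.data.frame(object)),
                  ggplot2::aes(x = log10(.data$mean_rel_abundance),
                               y = .data$statistic,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = paste0(attr(object, "method"), " statistic")) +
    ggplot2::theme_minimal()
}

#' Benchmark summary plots
#'
#' @param object a [run_benchmark()] result.
#' @param type one of `"detection"`, `"tpr"`, `"agreement"`, `"abundance"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.benchmark_result <- function(object,
                                      type = c("detection", "tpr",
                                               "agreement", "abundance"),
                                      ...) {
  type <- match.arg(type)
  s <- summarize_benchmark(object)
  switch(type,
    detection = ggplot2::ggplot(s$detection,
        ggplot2::aes(x = .data$scenario, y = .data$mean_explained_pct,
                     fill = .data$method)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$detection_pct)),
                         position = ggplot2::position_dodge(width = 0.9),
                         vjust = -0.3, size = 2.8) +
      ggplot2::labs(y = "Mean explained variance (%)",
                    caption = "labels: % of data sets detected at alpha") +
      ggplot2::theme_minimal(),
    tpr = ggplot2::ggplot(s$tpr_tnr,
        ggplot2::aes(x = .data$scenario, y = .data$mean_tpr, fill = .data$method)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "True positive rate") + ggplot2::theme_minimal(),
    agreement = ggplot2::ggplot(s$spearman,
        ggplot2::aes(x = paste(.data$method1, .data$method2, sep = " vs "),
                     y = .data$median_rho, fill = .data$scenario)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "Median Spearman rho") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)),
    abundance = ggplot2::ggplot(s$abundance,
        ggplot2::aes(x = .data$method, y = .data$mean_abs_abundance_rho,
                     fill = .data$scenario)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "Mean |Spearman rho| (rank vs log abundance)") +
      ggplot2::theme_minimal()
  )
}
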