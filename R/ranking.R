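#' Per-OTU ranking table
#'
#' The unit of cross-method comparison: one statistic per OTU together with
#' its evidence polarity, evidence rank (1 = strongest evidence, average
#' ranks on ties) and significance flag under the method's own rule.
#'
#' @param otu_id character vector of OTU identifiers.
#' @param statistic numeric statistic, one per OTU.
#' @param polarity `"lower"` if smaller values mean more evidence (p-values)
#'   or `"higher"` (W statistics, |loadings|, |coefficients|).
#' @param significant logical flags under the method's significance rule.
#' @param method,contrast labels recorded on the table.
#' @param mean_rel_abundance optional per-OTU mean relative abundance.
#' @param extra optional tibble of additional per-OTU columns.
#' @return a tibble of class `ranking_table` with columns `otu_id`,
#'   `statistic`, `rank`, `significant` (+ extras), and attributes `method`,
#'   `contrast`, `polarity`.
#' @export
ranking_table <- function(otu_id, statistic, polarity = c("lower", "higher"),
                          significant, method = "", contrast = "",
                          mean_rel_abundance = NULL, extra = NULL) {
  polarity <- match.arg(polarity)
  otu_id <- unname(otu_id)
  statistic <- unname(statistic)
  significant <- unname(significant)
  if (!is.null(mean_rel_abundance)) mean_rel_abundance <- unname(mean_rel_abundance)
  if (anyNA(statistic)) {
    stop("missing statistic for OTU(s): ",
         paste(otu_id[is.na(statistic)], collapse = ", "), call. = FALSE)
  }
  evidence <- if (polarity == "lower") statistic else -statistic
  tab <- tibble::tibble(
    otu_id = as.character(otu_id),
    statistic = statistic,
    rank = rank(evidence, ties.method = "average"),
    significant = as.logical(significant)
  )
  if (!is.null(mean_rel_abundance)) tab$mean_rel_abundance <- mean_rel_abundance
  if (!is.null(extra)) tab <- dplyr::bind_cols(tab, extra[setdiff(names(extra), names(tab))])
  structure(tab, method = method, contrast = contrast, polarity = polarity,
            class = c("ranking_table", class(tab)))
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("<ranking_table> method = %s, contrast = %s, %d OTUs, %d significant\n",
              attr(x, "method"), attr(x, "contrast"), nrow(x), sum(x$significant)))
  NextMethod()
}

#' @rdname ranking_table
#' @param x a `ranking_table`.
#' @param ... unused.
#' @export
tidy.ranking_table <- function(x, ...) tibble::as_tibble(as.data.frame(x))

#' @rdname ranking_table
#' @export
glance.ranking_table <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), contrast = attr(x, "contrast"),
                 polarity = attr(x, "polarity"), n_otus = nrow(x),
                 n_significant = sum(x$significant))
}

# Evidence-ordered values: smaller = more evidence for every method
.evidence <- function(tab) {
  if (attr(tab, "polarity") == "lower") tab$statistic else -tab$statistic
}

#' True positive and true negative rate against simulation truth
#'
#' @param calls logical significance calls per OTU (named, or in `truth`
#'   order).
#' @param truth logical ground-truth differential-abundance labels.
#' @return tibble with `tpr` (TP/P, `NA` when P = 0), `tnr` (TN/N), `tp`,
#'   `p`, `tn`, `n`.
#' @export
tpr_tnr <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth must cover the same OTUs", call. = FALSE)
  }
  if (!is.null(names(calls)) && !is.null(names(truth))) {
    if (!setequal(names(calls), names(truth))) {
      stop("calls and truth must cover the same OTUs", call. = FALSE)
    }
    calls <- calls[names(truth)]
  }
  P <- sum(truth)
  N <- sum(!truth)
  tp <- sum(calls & truth)
  tn <- sum(!calls & !truth)
  tibble::tibble(tpr = if (P == 0) NA_real_ else tp / P,
                 tnr = if (N == 0) NA_real_ else tn / N,
                 tp = tp, p = P, tn = tn, n = N)
}

#' Pairwise Spearman rank agreement between methods
#'
#' Correlates the evidence-ordered statistics of every pair of ranking
#' tables (polarity harmonised so rank 1 is the strongest evidence for all
#' methods); ties are handled by average ranks.
#'
#' @param tables named list of [ranking_table()] objects over the same OTUs.
#' @return tibble with columns `method1`, `method2`, `rho`.
#' @export
spearman_agreement <- function(tables) {
  stopifnot(length(tables) >= 2L)
  ids <- lapply(tables, function(t) sort(t$otu_id))
  if (!all(vapply(ids[-1L], identical, TRUE, ids[[1L]]))) {
    stop("ranking tables cover different OTU sets", call. = FALSE)
  }
  nm <- names(tables)
  if (is.null(nm)) nm <- vapply(tables, attr, "", "method")
  ev <- lapply(tables, function(t) .evidence(t)[order(t$otu_id)])
  pairs <- utils::combn(seq_along(tables), 2L)
  tibble::tibble(
    method1 = nm[pairs[1L, ]],
    method2 = nm[pairs[2L, ]],
    rho = apply(pairs, 2L, function(ij) {
      stats::cor(ev[[ij[1L]]], ev[[ij[2L]]], method = "spearman")
    })
  )
}

#' Dependence of a ranking on OTU abundance
#'
#' Spearman correlation between the evidence rank (1 = strongest) and the
#' log10 mean relative abundance, plus the per-OTU table behind the
#' diagnostic scatterplot of abundance versus statistic.
#'
#' @param table a [ranking_table()].
#' @param rel relative-abundance matrix over the same OTUs.
#' @return list with `rho` and `diagnostic` (tibble `otu_id`,
#'   `log10_mean_abundance`, `statistic`, `rank`, `significant`).
#' @export
abundance_dependence <- function(table, rel) {
  rel <- as.matrix(rel)
  if (!all(table$otu_id %in% colnames(rel))) {
    stop("rel does not cover all ranked OTUs", call. = FALSE)
  }
  ma <- colMeans(rel[, table$otu_id, drop = FALSE])
  log_ma <- log10(pmax(ma, .Machine$double.xmin))
  # evidence strength = negated evidence rank, so rho > 0 means stronger
  # evidence for more abundant OTUs
  rho <- stats::cor(-table$rank, log_ma, method = "spearman")
  list(rho = rho,
       diagnostic = tibble::tibble(
         otu_id = table$otu_id,
         log10_mean_abundance = log_ma,
         statistic = table$statistic,
         rank = table$rank,
         significant = table$significant))
}
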