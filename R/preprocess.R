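#' Close counts to relative abundances
#'
#' Divides each sample (row) by its library size so rows sum to one.
#' Zeros are preserved; zero replacement is a separate, later step.
#'
#' @param counts an [count_matrix()] object.
#' @return an `otu_counts` object in relative mode; rows sum to 1.
#' @export
to_relative <- function(counts) {
  stopifnot(inherits(counts, "otu_counts"))
  if (isTRUE(attr(counts, "relative"))) return(counts)
  ls <- rowSums(counts)
  if (any(ls <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[ls <= 0], collapse = ", "), call. = FALSE)
  }
  out <- unclass(counts) / ls
  cm <- count_matrix(out, relative = TRUE)
  attr(cm, "library_sizes") <- as.integer(ls)
  cm
}

#' Abundance/prevalence filter for OTUs
#'
#' Keeps an OTU if (a) its relative abundance exceeds `min_rel` in at least
#' one sample, and (b) it is present (non-zero) in at least a `prevalence`
#' fraction of the samples of at least one group. The abundance condition is
#' strict (`>`), the prevalence condition inclusive (`>=`), and prevalence is
#' evaluated within each group separately so that group-specific taxa are
#' retained.
#'
#' @param rel relative-abundance `otu_counts` (see [to_relative()]).
#' @param group factor of group labels, one per sample (typically the
#'   combined design cells, e.g. `interaction(diet, dose)`).
#' @param min_rel minimum relative abundance, default `5e-5` (0.005%).
#' @param prevalence minimum within-group presence fraction, default `0.5`.
#' @return the filtered `otu_counts`; the removed OTU ids are attached as
#'   attribute `removed`.
#' @export
filter_otus <- function(rel, group, min_rel = 5e-5, prevalence = 0.5) {
  stopifnot(inherits(rel, "otu_counts"))
  group <- as.factor(group)
  if (length(group) != nrow(rel)) {
    stop("group labels must cover all samples", call. = FALSE)
  }
  x <- unclass(rel)
  abund_ok <- apply(x, 2L, function(col) any(col > min_rel))
  present <- x > 0
  prev_ok <- rep(FALSE, ncol(x))
  for (g in levels(group)) {
    idx <- which(group == g)
    if (length(idx) == 0L) next
    frac <- colMeans(present[idx, , drop = FALSE])
    prev_ok <- prev_ok | (frac >= prevalence)
  }
  keep <- abund_ok & prev_ok
  if (!any(keep)) stop("all OTUs removed by the filter", call. = FALSE)
  out <- count_matrix(x[, keep, drop = FALSE],
                      relative = isTRUE(attr(rel, "relative")))
  attr(out, "library_sizes") <- attr(rel, "library_sizes")
  attr(out, "removed") <- colnames(x)[!keep]
  out
}

#' Multiplicative (count-zero) replacement of zeros
#'
#' Replaces each zero in sample i by `delta_frac` times the sample's
#' detection limit and rescales the non-zero parts multiplicatively so each
#' row still sums to one. The detection limit is `1/library_size_i` when
#' counts are known, otherwise the smallest positive value in the row. The
#' multiplicative rescaling preserves all ratios between originally non-zero
#' parts, which is what makes the subsequent log-ratio analysis coherent.
#'
#' @param rel relative-abundance `otu_counts`, rows closed to 1.
#' @param library_sizes optional per-sample sequencing depths; defaults to
#'   the depths recorded on `rel` when present.
#' @param delta_frac fraction of the detection limit used as the imputed
#'   value, default 0.65.
#' @return strictly positive `otu_counts`, rows summing to 1, with attribute
#'   `replaced` (logical matrix marking imputed entries).
#' @export
replace_zeros_czm <- function(rel, library_sizes = NULL, delta_frac = 0.65) {
  stopifnot(inherits(rel, "otu_counts"))
  x <- unclass(rel)
  if (is.null(library_sizes)) library_sizes <- attr(rel, "library_sizes")
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("row of all zeros", call. = FALSE)
  if (any(rs > 1 + 1e-6)) {
    stop("rows must be closed to (at most) 1 before zero replacement",
         call. = FALSE)
  }
  # rows of filtered tables sum to slightly less than 1 (removed mass);
  # the multiplicative rescaling below re-closes them exactly
  zero <- x == 0
  out <- x
  for (i in seq_len(nrow(x))) {
    zi <- which(zero[i, ])
    if (length(zi) == 0L) next
    dl <- if (!is.null(library_sizes)) 1 / library_sizes[i] else min(x[i, x[i, ] > 0])
    delta <- delta_frac * dl
    if (delta >= min(x[i, -zi])) {
      warning(sprintf("sample %s: replacement value %.3g exceeds an observed value",
                      rownames(x)[i], delta), call. = FALSE)
    }
    nz_sum <- sum(x[i, -zi])
    out[i, zi] <- delta
    out[i, -zi] <- x[i, -zi] * (1 - length(zi) * delta) / nz_sum
  }
  res <- count_matrix(out, relative = TRUE)
  attr(res, "library_sizes") <- attr(rel, "library_sizes")
  attr(res, "replaced") <- zero
  res
}

#' Centred log-ratio transformation
#'
#' `clr(x)_ij = log(x_ij) - mean_k log(x_ik)`: each part is expressed
#' relative to the geometric mean of its sample, mapping compositions into a
#' zero-sum real space where ordinary multivariate statistics apply. The
#' transform is invariant to per-sample scaling, hence to sequencing depth.
#'
#' @param rel strictly positive `otu_counts` (zero-replace first) or matrix.
#' @return numeric matrix of clr values, rows summing to 0, with attribute
#'   `centering = "none"`.
#' @export
clr_transform <- function(rel) {
  x <- unclass(rel)
  if (any(x <= 0)) {
    stop("clr requires strictly positive entries; apply zero replacement first",
         call. = FALSE)
  }
  lx <- log(x)
  out <- lx - rowMeans(lx)
  attr(out, "centering") <- "none"
  out
}

#' Column centering / autoscaling of a clr matrix
#'
#' `center` subtracts column means (the scaling used for ASCA and
#' distance-based analyses); `autoscale` additionally divides by the sample
#' standard deviation (n-1), giving every OTU unit variance (the scaling
#' used for the 50-50 MANOVA and rotation tests). Columns with essentially
#' zero variance are centred only, with a warning.
#'
#' @param X numeric matrix (samples x OTUs).
#' @param mode `"center"` or `"autoscale"`.
#' @return scaled matrix with attribute `centering` set accordingly.
#' @export
scale_columns <- function(X, mode = c("center", "autoscale")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  out <- sweep(X, 2L, colMeans(X))
  if (mode == "autoscale") {
    s <- apply(out, 2L, stats::sd)
    degen <- s < 1e-12
    if (any(degen)) {
      warning(sprintf("%d constant column(s) left centred only", sum(degen)),
              call. = FALSE)
      s[degen] <- 1
    }
    out <- sweep(out, 2L, s, "/")
  }
  attr(out, "centering") <- if (mode == "center") "column-centered" else "autoscaled"
  out
}

#' Standard preprocessing chain
#'
#' Convenience wrapper running the full chain used before every analysis:
#' closure to relative abundances, abundance/prevalence filtering,
#' multiplicative zero replacement, and clr transformation.
#'
#' @inheritParams filter_otus
#' @param counts an [count_matrix()] of raw counts.
#' @param delta_frac passed to [replace_zeros_czm()].
#' @return list with elements `rel` (filtered relative abundances, zeros
#'   intact), `rel_pos` (zero-replaced), `clr` (clr matrix).
#' @export
preprocess_counts <- function(counts, group, min_rel = 5e-5, prevalence = 0.5,
                              delta_frac = 0.65) {
  rel <- to_relative(counts)
  rel <- filter_otus(rel, group, min_rel = min_rel, prevalence = prevalence)
  rel_pos <- replace_zeros_czm(rel, delta_frac = delta_frac)
  list(rel = rel, rel_pos = rel_pos, clr = clr_transform(rel_pos))
}
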