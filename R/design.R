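#' Build sum-to-zero design matrices for a multi-factor model
#'
#' Expands a model formula over the experimental factors into per-term
#' coding matrices with sum-to-zero contrasts, the coding under which the
#' ANOVA effect matrices of a balanced design are mutually orthogonal.
#' Aliased columns (e.g. subject nested in diet in a crossover design) are
#' detected by QR pivoting and dropped with a message.
#'
#' @param metadata data frame of per-sample factor levels (one row per
#'   sample, in the sample order of the abundance matrix).
#' @param formula model formula using columns of `metadata`, e.g.
#'   `~ diet * dose` or `~ treatment:day + subject`, or a character string
#'   such as `"diet*dose"`.
#' @return an object of class `design_matrices`: list with `terms` (term
#'   labels in model order), `matrices` (named list of per-term coding
#'   matrices), `full` (model matrix including intercept, aliased columns
#'   dropped), `df` (per-term degrees of freedom), `n`, `balanced`, `data`.
#' @export
build_design <- function(metadata, formula) {
  metadata <- as.data.frame(metadata)
  if (is.character(formula)) formula <- stats::as.formula(paste("~", formula))
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(metadata))
  if (length(missing_vars) > 0L) {
    stop("factor(s) not in metadata: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  dat <- metadata[, vars, drop = FALSE]
  for (v in vars) {
    dat[[v]] <- droplevels(as.factor(dat[[v]]))
    if (nlevels(dat[[v]]) < 2L) {
      stop("factor '", v, "' has a single level", call. = FALSE)
    }
  }
  contrasts_arg <- stats::setNames(
    replicate(length(vars), "contr.sum", simplify = FALSE), vars)
  mm <- stats::model.matrix(formula, dat, contrasts.arg = contrasts_arg)
  assign <- attr(mm, "assign")
  term_labels <- attr(stats::terms(formula), "term.labels")

  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    keep <- sort(qr_mm$pivot[seq_len(qr_mm$rank)])
    dropped <- colnames(mm)[setdiff(seq_len(ncol(mm)), keep)]
    message("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
    mm <- mm[, keep, drop = FALSE]
    assign <- assign[keep]
  }
  mats <- lapply(seq_along(term_labels), function(k) {
    mm[, assign == k, drop = FALSE]
  })
  names(mats) <- term_labels
  empty <- vapply(mats, ncol, 0L) == 0L
  if (any(empty)) {
    stop("term(s) fully aliased with earlier terms: ",
         paste(term_labels[empty], collapse = ", "), call. = FALSE)
  }
  cells <- interaction(dat, drop = TRUE)
  structure(list(
    terms = term_labels,
    matrices = mats,
    full = mm,
    df = vapply(mats, ncol, 0L),
    n = nrow(mm),
    balanced = length(unique(table(cells))) == 1L,
    data = dat
  ), class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf("<design_matrices> n = %d, %s design\n", x$n,
              if (x$balanced) "balanced" else "unbalanced"))
  for (k in seq_along(x$terms)) {
    cat(sprintf("  %-20s df = %d\n", x$terms[k], x$df[k]))
  }
  invisible(x)
}

#' Concatenate factors into a single grouping factor
#'
#' One-way methods (ANOSIM) cannot model multiple factors; the convention is
#' to analyse the combined design cells as a single factor.
#'
#' @param metadata data frame of factor levels.
#' @param factors character vector of column names to combine.
#' @return a factor with one level per occupied design cell.
#' @export
combine_factors <- function(metadata, factors) {
  metadata <- as.data.frame(metadata)
  interaction(metadata[, factors, drop = FALSE], drop = TRUE, sep = "_")
}

# Orthonormal basis (n x rank) of the column space of M
.basis <- function(M) {
  qr_m <- qr(M)
  qr.Q(qr_m)[, seq_len(qr_m$rank), drop = FALSE]
}

# Orthonormal basis of the orthogonal complement of span(M) in R^n
.basis_complement <- function(M) {
  qr_m <- qr(M)
  qr.Q(qr_m, complete = TRUE)[, -seq_len(qr_m$rank), drop = FALSE]
}

# Cumulative (sequential) and leave-one-out design column spaces
.cumulative_bases <- function(design) {
  n <- design$n
  intercept <- matrix(1, n, 1L)
  bases <- vector("list", length(design$terms) + 1L)
  Z <- intercept
  bases[[1L]] <- .basis(Z)
  for (k in seq_along(design$terms)) {
    Z <- cbind(Z, design$matrices[[k]])
    bases[[k + 1L]] <- .basis(Z)
  }
  bases
}

.leave_one_out_bases <- function(design) {
  n <- design$n
  intercept <- matrix(1, n, 1L)
  lapply(seq_along(design$terms), function(k) {
    Z <- do.call(cbind, c(list(intercept), design$matrices[-k]))
    .basis(Z)
  })
}
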