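#' Multivariate ANOVA partition of an abundance matrix
#'
#' Decomposes a (centred or autoscaled) clr matrix into per-term effect
#' matrices plus residuals. With `ss_type = "sequential"` each term is
#' projected onto its design subspace after removing all previously entered
#' terms (Type I); with `"partial"` each term's effect is adjusted for all
#' other terms in the model (the convention used for the 50-50 MANOVA
#' explained variances). For balanced orthogonal designs the two coincide
#' and the term plus residual sums of squares add up to the total.
#'
#' @param X numeric matrix, samples x OTUs; rows must match the design.
#' @param design a [build_design()] object.
#' @param ss_type `"sequential"` or `"partial"`.
#' @return an object of class `effect_decomposition`: a tibble with columns
#'   `term`, `df`, `ss`, `explained_variance_pct`, `p_value` (NA until a
#'   permutation test fills it), including a `residuals` row, with the
#'   per-term effect matrices, the residual matrix and the total sum of
#'   squares attached as attributes.
#' @export
anova_partition <- function(X, design, ss_type = c("sequential", "partial")) {
  ss_type <- match.arg(ss_type)
  X <- as.matrix(X)
  stopifnot(inherits(design, "design_matrices"))
  if (nrow(X) != design$n) stop("rows of X do not match the design", call. = FALSE)

  Xc <- sweep(X, 2L, colMeans(X))          # remove the intercept (grand mean)
  total_ss <- sum(Xc^2)
  Q_full <- .basis(cbind(matrix(1, design$n, 1L), design$full[, -1L, drop = FALSE]))
  fitted_full <- Q_full %*% crossprod(Q_full, X)
  residual <- X - fitted_full
  res_ss <- sum(residual^2)
  df_res <- design$n - ncol(Q_full)

  K <- length(design$terms)
  effects <- vector("list", K)
  ss <- numeric(K)
  if (ss_type == "sequential") {
    bases <- .cumulative_bases(design)
    prev <- bases[[1L]] %*% crossprod(bases[[1L]], X)
    for (k in seq_len(K)) {
      cur <- bases[[k + 1L]] %*% crossprod(bases[[k + 1L]], X)
      effects[[k]] <- cur - prev
      ss[k] <- sum(effects[[k]]^2)
      prev <- cur
    }
  } else {
    loo <- .leave_one_out_bases(design)
    for (k in seq_len(K)) {
      reduced <- loo[[k]] %*% crossprod(loo[[k]], X)
      effects[[k]] <- fitted_full - reduced
      ss[k] <- sum(effects[[k]]^2)
    }
  }
  names(effects) <- design$terms

  all_ss <- c(ss, res_ss)
  tab <- tibble::tibble(
    term = c(design$terms, "residuals"),
    df = c(design$df, df_res),
    ss = all_ss,
    explained_variance_pct = 100 * all_ss / total_ss,
    p_value = NA_real_
  )
  structure(tab,
            effects = effects, residuals = residual, total_ss = total_ss,
            ss_type = ss_type, design = design,
            class = c("effect_decomposition", class(tab)))
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat(sprintf("<effect_decomposition> (%s sums of squares)\n", attr(x, "ss_type")))
  NextMethod()
}

#' Effect matrix of a term
#' @param decomp an [anova_partition()] result.
#' @param term term label, or `"residuals"`.
#' @return samples x OTUs effect matrix.
#' @export
effect_matrix <- function(decomp, term) {
  if (term == "residuals") return(attr(decomp, "residuals"))
  eff <- attr(decomp, "effects")
  if (!term %in% names(eff)) stop("unknown term: ", term, call. = FALSE)
  eff[[term]]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname anova_partition
#' @param x an `effect_decomposition` object.
#' @param ... unused.
#' @export
tidy.effect_decomposition <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname anova_partition
#' @export
glance.effect_decomposition <- function(x, ...) {
  tibble::tibble(
    total_ss = attr(x, "total_ss"),
    residual_pct = x$explained_variance_pct[x$term == "residuals"],
    ss_type = attr(x, "ss_type"),
    n_terms = sum(x$term != "residuals")
  )
}
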