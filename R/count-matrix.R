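#' Construct an OTU count matrix
#'
#' The basic container of the package: a samples x OTUs matrix of
#' non-negative counts (or, optionally, relative abundances) with unique
#' sample and OTU identifiers and per-sample library sizes.
#'
#' @param values numeric matrix or data frame, samples in rows, OTUs in
#'   columns. Must be non-negative. Integer counts unless
#'   `relative = TRUE`.
#' @param sample_ids,otu_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param relative logical; `TRUE` marks the matrix as relative abundances
#'   (non-integer entries allowed, library sizes unset).
#'
#' @return An object of class `otu_counts`: the value matrix with
#'   `sample_ids`/`otu_ids` as dimnames and an attribute `library_sizes`
#'   (row sums, `NULL` in relative mode).
#' @export
count_matrix <- function(values, sample_ids = rownames(values),
                         otu_ids = colnames(values), relative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("count matrix needs at least 2 samples and 2 OTUs", call. = FALSE)
  }
  if (anyNA(values)) stop("count matrix contains missing values", call. = FALSE)
  if (any(values < 0)) stop("count matrix contains negative entries", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids", call. = FALSE)
  if (length(sample_ids) != nrow(values) || length(otu_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (!relative && any(abs(values - round(values)) > 1e-8)) {
    stop("non-integer entries; use relative = TRUE for relative abundances",
         call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, otu_ids)
  structure(values,
            library_sizes = if (relative) NULL else as.integer(round(rowSums(values))),
            relative = relative,
            class = c("otu_counts", "matrix", "array"))
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("<otu_counts> %d samples x %d OTUs%s\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "relative"))) " (relative abundances)" else ""))
  ls <- attr(x, "library_sizes")
  if (!is.null(ls)) {
    cat(sprintf("  library sizes: %d - %d (median %d)\n",
                min(ls), max(ls), as.integer(stats::median(ls))))
  }
  invisible(x)
}

#' Library sizes of a count matrix
#' @param counts an [count_matrix()] object.
#' @return integer vector of per-sample totals (`NULL` for relative data).
#' @export
library_sizes <- function(counts) attr(counts, "library_sizes")

#' Read an OTU count table from a delimited or spreadsheet file
#'
#' Reads TSV/CSV (and, when the readxl package is available, XLSX) tables of
#' OTU counts. The first column holds row identifiers and the header row
#' column identifiers.
#'
#' @param path file path (.tsv, .txt, .csv or .xlsx).
#' @param orientation `"samples_in_rows"` (default) or `"otus_in_rows"`;
#'   in the latter case the table is transposed so the result is always
#'   samples x OTUs.
#' @param relative logical; allow non-integer entries (relative abundances).
#' @param sheet sheet name or index for XLSX workbooks (one study per sheet).
#' @return an [count_matrix()] object, samples in rows.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_in_rows", "otus_in_rows"),
                             relative = FALSE, sheet = 1L) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    }
    tab <- readxl::read_excel(path, sheet = sheet)
  } else {
    delim <- if (ext == "csv") "," else "\t"
    tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }
  ids <- as.character(tab[[1L]])
  body <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(body)) stop("count table body is not numeric", call. = FALSE)
  rownames(body) <- ids
  if (orientation == "otus_in_rows") body <- t(body)
  count_matrix(body, relative = relative)
}

#' Align a count matrix with sample metadata
#'
#' Restricts counts and metadata to their common samples, in count-table
#' order, and returns both as a joint dataset. Dropped samples are reported
#' with a warning so silent mismatches cannot occur.
#'
#' @param counts an [count_matrix()] object.
#' @param metadata data frame with a `sample_id` column and one column per
#'   experimental factor.
#' @return an object of class `otu_dataset`: a list with elements `counts`
#'   (aligned [count_matrix()]) and `metadata` (tibble in the same order).
#' @export
align_samples <- function(counts, metadata) {
  stopifnot(inherits(counts, "otu_counts"))
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  common <- intersect(rownames(counts), metadata$sample_id)
  if (length(common) == 0L) {
    stop("no samples in common between counts and metadata", call. = FALSE)
  }
  dropped <- setdiff(union(rownames(counts), metadata$sample_id), common)
  if (length(dropped) > 0L) {
    warning(sprintf("dropping %d sample(s) absent from counts or metadata: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  keep <- rownames(counts)[rownames(counts) %in% common]
  sub <- counts[keep, , drop = FALSE]
  cm <- count_matrix(sub, relative = isTRUE(attr(counts, "relative")))
  md <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  structure(list(counts = cm, metadata = md), class = "otu_dataset")
}

#' @export
print.otu_dataset <- function(x, ...) {
  cat(sprintf("<otu_dataset> %d samples x %d OTUs, metadata: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(setdiff(names(x$metadata), "sample_id"), collapse = ", ")))
  invisible(x)
}

#' Write a result table to TSV or JSON
#'
#' @param results a data frame (ranking table, effect decomposition,
#'   benchmark summary, ...).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  results <- as.data.frame(results)
  if (format == "tsv") {
    # readr writes doubles with full precision (>= 6 significant digits)
    readr::write_tsv(results, path, progress = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
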