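#' Expression matrix container
#'
#' A light-weight container for a genes-by-samples expression matrix together
#' with per-sample metadata and a flag stating whether values are on the log2
#' scale. This is the object most pipeline stages consume and return.
#'
#' @param values Numeric matrix, genes in rows (unique rownames required),
#'   samples in columns (unique colnames required). All values must be finite.
#' @param samples Optional `data.frame` of per-sample metadata with a
#'   `sample_id` column matching `colnames(values)` (any order; it is
#'   realigned). When `NULL` a minimal frame holding only `sample_id` is
#'   created.
#' @param log2_scale Logical flag; `TRUE` when `values` are log2-transformed.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `samples` and `log2_scale`.
#' @export
expression_matrix <- function(values, samples = NULL, log2_scale = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("`values` must have unique rownames (gene identifiers)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique colnames (sample identifiers)")
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite")
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(samples) || !"sample_id" %in% names(samples)) {
    stop("`samples` must be a data.frame with a `sample_id` column")
  }
  if (!setequal(samples$sample_id, colnames(values)) ||
      anyDuplicated(samples$sample_id)) {
    stop("`samples$sample_id` must match colnames(values) one-to-one")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(values = values, samples = samples,
         log2_scale = isTRUE(log2_scale)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2_scale) "log2" else "linear"))
  extra <- setdiff(names(x$samples), "sample_id")
  if (length(extra)) {
    cat("sample metadata:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression or count matrix from TSV
#'
#' Expects the first column to hold gene (or probe) identifiers and the header
#' row to hold sample identifiers.
#'
#' @param path Path to a tab-separated file.
#' @param log2_scale Whether the stored values are log2-scale.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path, log2_scale = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, log2_scale = log2_scale)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expression_matrix] or plain matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @export
write_expression_tsv <- function(em, path, id_col = "gene_id") {
  m <- if (inherits(em, "expression_matrix")) em$values else em
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata from a TSV table
#'
#' The table mirrors the sample/data-relationship (SDRF-like) layout used for
#' microarray repositories: columns `sample_id`, `organism`, `label`,
#' `platform_id`, `study_id`, `cell_type` and `characteristics`
#' (semicolon-joined free-text attributes, split into a list-column).
#'
#' @param path Path to a tab-separated metadata file.
#' @return A `data.frame`, with `characteristics` as a list of character
#'   vectors.
#' @export
read_sample_metadata <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(df)) {
    stop("metadata table must contain a `sample_id` column")
  }
  if ("characteristics" %in% names(df)) {
    df$characteristics <- lapply(strsplit(df$characteristics, ";",
                                          fixed = TRUE), trimws)
  } else {
    df$characteristics <- replicate(nrow(df), character(0), simplify = FALSE)
  }
  df
}
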