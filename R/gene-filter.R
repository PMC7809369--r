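#' Apply the TF twofold rule and the non-TF variability cap
#'
#' Transcription factors are kept only when their expression varies at least
#' twofold across all samples (log2 range `max - min >= 1`, equivalent to
#' `max/min >= 2` on the linear scale). Genes that are not TFs are ranked by
#' the standard deviation of their log2 values and either kept up to a total
#' gene cap (TFs fill first) or kept when their SD exceeds a threshold.
#' Ties at a cap boundary are broken by gene symbol (ascending).
#'
#' @param em [expression_matrix] with `log2_scale = TRUE`.
#' @param tf_list Character vector of TF symbols; symbols absent from the
#'   matrix are ignored with a warning.
#' @param total_cap Total number of genes to retain (kept TFs plus the most
#'   variable non-TFs). Exactly one of `total_cap` / `sd_threshold` must be
#'   given.
#' @param sd_threshold Keep non-TFs with log2 SD strictly greater than this.
#' @return The filtered [expression_matrix], rows in their original order.
#' @export
filter_genes <- function(em, tf_list, total_cap = NULL, sd_threshold = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$log2_scale) stop("filter_genes expects log2-scale values")
  if (is.null(total_cap) == is.null(sd_threshold)) {
    stop("give exactly one of `total_cap` or `sd_threshold`")
  }
  genes <- rownames(em$values)
  tf_list <- unique(as.character(tf_list))
  missing_tfs <- setdiff(tf_list, genes)
  if (length(missing_tfs)) {
    warning(length(missing_tfs), " TF symbol(s) not in the matrix; ignored")
  }
  is_tf <- genes %in% tf_list
  v <- em$values

  rng <- apply(v, 1L, function(x) max(x) - min(x))
  keep_tf <- is_tf & rng >= 1

  sds <- apply(v, 1L, stats::sd)
  nontf <- which(!is_tf)
  if (!is.null(total_cap)) {
    room <- total_cap - sum(keep_tf)
    if (room < 0) {
      stop("total_cap (", total_cap, ") smaller than the number of kept TFs (",
           sum(keep_tf), ")")
    }
    ord <- nontf[order(-sds[nontf], genes[nontf])]
    keep_nontf <- ord[seq_len(min(room, length(ord)))]
  } else {
    keep_nontf <- nontf[sds[nontf] > sd_threshold]
  }
  keep <- sort(unique(c(which(keep_tf), keep_nontf)))
  expression_matrix(v[keep, , drop = FALSE],
                    samples = em$samples, log2_scale = TRUE)
}

#' Read a TF symbol list (one symbol per line, optional header)
#'
#' @param path Path to a one-column TSV/text file of TF gene symbols.
#' @return Character vector of unique symbols.
#' @export
read_tf_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) && tolower(x[1]) %in% c("tf", "symbol", "gene", "gene_symbol")) {
    x <- x[-1]
  }
  unique(x)
}
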