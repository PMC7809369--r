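#' Apply sample-inclusion rules to a metadata table
#'
#' Keeps only samples passing four rules: organism whitelist, label whitelist,
#' platform-prefix whitelist, and a case-insensitive substring denylist over
#' the free-text characteristics. The denylist default operationalises the
#' exclusion of cancerous material. Records with a missing or empty organism
#' are rejected with a logged reason. Input order is preserved.
#'
#' @param samples `data.frame` as returned by [read_sample_metadata()].
#' @param organisms Character vector of allowed organisms (exact match).
#' @param labels Character vector of allowed labels, matched
#'   case-insensitively (e.g. `"biotin"`).
#' @param platform_prefixes Allowed platform-id prefixes (e.g. `"A-AFFY"`).
#' @param exclude_terms Denylist of substrings; any characteristic containing
#'   one of them (case-insensitive) rejects the sample.
#' @return The filtered `data.frame`.
#' @export
filter_samples <- function(samples,
                           organisms = "Homo sapiens",
                           labels = "biotin",
                           platform_prefixes = "A-AFFY",
                           exclude_terms = c("carcinoma", "tumor", "tumour",
                                             "cancer", "hcc")) {
  stopifnot(is.data.frame(samples))
  chars <- samples$characteristics
  if (is.null(chars)) chars <- replicate(nrow(samples), character(0),
                                         simplify = FALSE)
  if (!is.list(chars)) chars <- as.list(chars)

  ok <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    org <- samples$organism[i]
    if (is.na(org) || !nzchar(org)) {
      message("sample ", samples$sample_id[i],
              " rejected: missing organism")
      next
    }
    if (!org %in% organisms) next
    lab <- samples$label[i]
    if (is.na(lab) || !tolower(lab) %in% tolower(labels)) next
    plat <- samples$platform_id[i]
    if (is.na(plat) ||
        !any(startsWith(plat, platform_prefixes))) next
    ch <- tolower(paste(unlist(chars[[i]]), collapse = " \n "))
    if (length(exclude_terms) &&
        any(vapply(tolower(exclude_terms), grepl, logical(1), x = ch,
                   fixed = TRUE))) next
    ok[i] <- TRUE
  }
  out <- samples[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no samples pass the inclusion rules")
  out
}

#' Aggregate probe intensities to gene level by geometric mean
#'
#' Probe-level linear-scale intensities are collapsed per gene as
#' `exp(mean(log(intensity)))` over the probes mapping to that gene. Probes
#' without a gene mapping are dropped.
#'
#' @param values Numeric probe-by-sample matrix of strictly positive
#'   linear-scale intensities (for mapped probes).
#' @param probe_to_gene Either a named character vector (names = probe ids,
#'   values = gene symbols) or a `data.frame` with columns `probe_id` and
#'   `gene_symbol`.
#' @param samples Optional sample metadata passed through to the result.
#' @return An [expression_matrix] on the linear scale (`log2_scale = FALSE`),
#'   genes sorted by symbol.
#' @export
aggregate_probes <- function(values, probe_to_gene, samples = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene_symbol),
                           probe_to_gene$probe_id)
  } else {
    map <- probe_to_gene
  }
  map <- map[!is.na(map) & nzchar(map)]
  mapped <- intersect(rownames(values), names(map))
  if (length(mapped) == 0L) stop("no probe maps to a gene")
  v <- values[mapped, , drop = FALSE]
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-positive intensity for mapped probe '%s' in sample '%s'",
      rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  }
  genes <- map[mapped]
  lg <- log(v)
  sums <- rowsum(lg, group = genes)
  n <- as.vector(table(genes)[rownames(sums)])
  out <- exp(sums / n)
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, samples = samples, log2_scale = FALSE)
}

#' Quantile-normalise an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' row-wise mean of the sorted columns. Within-column ranks are preserved and
#' ties receive the average of the reference values over the tied block. This
#' is a documented, weaker stand-in for a full probe-level normalisation of
#' raw arrays; it operates on whatever scale the input is on.
#'
#' @param em An [expression_matrix] with at least two samples.
#' @return The normalised [expression_matrix].
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 2L) {
    stop("quantile normalisation needs at least 2 samples")
  }
  v <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(v) <- dimnames(em$values)
  expression_matrix(v, samples = em$samples, log2_scale = em$log2_scale)
}

#' Summarise a platform for platform selection
#'
#' @param platform_id Platform identifier.
#' @param n_samples Number of retained samples on the platform.
#' @param genes Character vector of gene symbols measured on the platform.
#' @return A `platform_summary` object.
#' @export
platform_summary <- function(platform_id, n_samples, genes) {
  stopifnot(nzchar(platform_id), n_samples >= 1, length(genes) >= 1)
  structure(list(platform_id = platform_id,
                 n_samples = as.integer(n_samples),
                 genes = unique(as.character(genes))),
            class = "platform_summary")
}

# TRUE if sorted id set a precedes b lexicographically (elementwise, with a
# proper prefix ranking first)
.ids_before <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Select the platform subset maximising samples x common genes
#'
#' Exhaustively searches all platform subsets containing the forced platforms
#' and returns the one maximising (total samples) x (number of genes shared by
#' all chosen platforms). The forced-inclusion argument mirrors the practice
#' of manually retaining a platform whose gene set is slightly smaller than
#' optimal when it is the only source for a cell type of interest. Ties are
#' broken by the lexicographically smallest sorted id set. With more than
#' `exhaustive_limit` platforms a greedy forward search is used instead.
#'
#' @param platforms List of [platform_summary] objects.
#' @param forced Character vector of platform ids that must be included.
#' @param exhaustive_limit Maximum platform count for the exhaustive search.
#' @return A list with `chosen` (character vector of platform ids),
#'   `common_genes` (character vector) and `objective` (numeric).
#' @export
select_platforms <- function(platforms, forced = character(0),
                             exhaustive_limit = 20L) {
  stopifnot(length(platforms) >= 1)
  ids <- vapply(platforms, function(p) p$platform_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate platform ids")
  names(platforms) <- ids
  if (!all(forced %in% ids)) {
    stop("forced platform id(s) not present: ",
         paste(setdiff(forced, ids), collapse = ", "))
  }
  ns <- vapply(platforms, function(p) p$n_samples, integer(1))
  if (any(ns < 2L)) {
    warning("platform(s) with a single sample present: ",
            paste(ids[ns < 2L], collapse = ", "),
            " (single-sample platforms are normally excluded upstream)")
  }

  objective <- function(chosen) {
    common <- Reduce(intersect, lapply(platforms[chosen],
                                       function(p) p$genes))
    sum(ns[chosen]) * length(common)
  }

  if (length(platforms) <= exhaustive_limit) {
    free <- setdiff(ids, forced)
    best <- NULL; best_obj <- -Inf
    for (k in 0:(2^length(free) - 1)) {
      inc <- free[bitwAnd(k, bitwShiftL(1L, seq_along(free) - 1L)) != 0L]
      chosen <- c(forced, inc)
      if (length(chosen) == 0L) next
      obj <- objective(chosen)
      if (obj > best_obj ||
          (obj == best_obj && !is.null(best) && .ids_before(chosen, best))) {
        best <- chosen; best_obj <- obj
      }
    }
  } else {
    # greedy forward search from the forced set (or best single platform)
    if (length(forced)) {
      best <- forced
    } else {
      singles <- vapply(ids, function(i) objective(i), numeric(1))
      best <- ids[which.max(singles)]
    }
    best_obj <- objective(best)
    repeat {
      cand <- setdiff(ids, best)
      if (!length(cand)) break
      objs <- vapply(cand, function(i) objective(c(best, i)), numeric(1))
      if (max(objs) <= best_obj) break
      best <- c(best, cand[which.max(objs)])
      best_obj <- max(objs)
    }
  }
  common <- Reduce(intersect, lapply(platforms[best], function(p) p$genes))
  list(chosen = sort(best), common_genes = sort(common),
       objective = best_obj)
}

#' Merge per-platform expression matrices into one log2 matrix
#'
#' Restricts all matrices to their shared genes, concatenates samples,
#' log2-transforms linear-scale inputs as `log2(x + 1)` (stable at low
#' intensities, tolerates zeros) and records the originating platform as a
#' `batch` column in the sample metadata.
#'
#' @param ems Named list of [expression_matrix] objects (names = platform
#'   ids, used as batch labels; a `platform_id` metadata column takes
#'   precedence when present).
#' @return A merged [expression_matrix] with `log2_scale = TRUE`.
#' @export
assemble_matrix <- function(ems) {
  stopifnot(is.list(ems), length(ems) >= 1)
  genes <- Reduce(intersect, lapply(ems, function(e) rownames(e$values)))
  if (length(genes) == 0L) stop("empty gene intersection across platforms")
  parts <- vector("list", length(ems))
  metas <- vector("list", length(ems))
  for (i in seq_along(ems)) {
    e <- ems[[i]]
    v <- e$values[genes, , drop = FALSE]
    if (!e$log2_scale) {
      if (any(v < 0)) stop("negative values in a linear-scale matrix")
      v <- log2(v + 1)
    }
    parts[[i]] <- v
    s <- e$samples
    s$batch <- if ("platform_id" %in% names(s)) s$platform_id
               else if (!is.null(names(ems))) names(ems)[i]
               else paste0("batch", i)
    metas[[i]] <- s
  }
  values <- do.call(cbind, parts)
  common_cols <- Reduce(intersect, lapply(metas, names))
  samples <- do.call(rbind, lapply(metas, function(s)
    s[, common_cols, drop = FALSE]))
  expression_matrix(values, samples = samples, log2_scale = TRUE)
}
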