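#' Motif ranking database
#'
#' Stores a motif-by-gene matrix of integer ranks (each row a permutation of
#' `1..N`, rank 1 = best-scoring gene for that motif) plus optional direct
#' motif-to-TF annotations.
#'
#' @param ranks Integer matrix, motifs in rows (rownames = motif ids), genes
#'   in columns (colnames = gene ids); every row must contain each rank
#'   `1..N` exactly once.
#' @param annotations Optional `data.frame` with columns `motif_id` and `tf`
#'   (direct annotations only).
#' @return A `motif_ranking_db` object.
#' @export
motif_ranking_db <- function(ranks, annotations = NULL) {
  stopifnot(is.matrix(ranks), !is.null(rownames(ranks)),
            !is.null(colnames(ranks)))
  storage.mode(ranks) <- "integer"
  N <- ncol(ranks)
  for (i in seq_len(nrow(ranks))) {
    r <- ranks[i, ]
    if (anyNA(r) || min(r) != 1L || max(r) != N || anyDuplicated(r)) {
      stop("row '", rownames(ranks)[i],
           "' is not a permutation of 1..", N)
    }
  }
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("motif_id", "tf") %in% names(annotations)))
  }
  structure(list(ranks = ranks, annotations = annotations),
            class = "motif_ranking_db")
}

#' @export
print.motif_ranking_db <- function(x, ...) {
  cat(sprintf("motif_ranking_db: %d motifs x %d genes (%d annotated motifs)\n",
              nrow(x$ranks), ncol(x$ranks),
              if (is.null(x$annotations)) 0L
              else length(unique(x$annotations$motif_id))))
  invisible(x)
}

#' Read a motif ranking database from TSV or feather
#'
#' Layout: first column motif id, remaining columns integer gene ranks with
#' gene ids in the header.
#'
#' @param path Path to a `.tsv`-style file or a `.feather` file.
#' @param annotations Optional annotation `data.frame` or path to a TSV with
#'   columns `motif_id`, `tf` (and optionally `annotation_type`).
#' @return A [motif_ranking_db()].
#' @export
read_motif_rankings <- function(path, annotations = NULL) {
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading feather files requires the 'arrow' package")
    }
    df <- as.data.frame(arrow::read_feather(path))
  } else {
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (is.character(annotations)) {
    annotations <- data.table::fread(annotations, sep = "\t", header = TRUE,
                                     data.table = FALSE)
  }
  motif_ranking_db(m, annotations = annotations)
}

# internal: intersect a gene set with db genes (warn on drops, error if empty)
.db_gene_set <- function(db, gene_set) {
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, colnames(db$ranks))
  dropped <- length(gene_set) - length(present)
  if (dropped > 0L) {
    warning(dropped, " gene(s) absent from the ranking database dropped")
  }
  if (length(present) == 0L) {
    stop("gene set is empty after intersecting with database genes")
  }
  present
}

#' Ranking-recovery AUC of a gene set under one motif
#'
#' The recovery curve `rec(x)` counts how many genes of the set have motif
#' rank `<= x`; the AUC is the area under the curve over the top
#' `ceil(top_frac * N)` ranks, normalised to `[0, 1]`:
#' `AUC = sum_{x=1..T} rec(x) / (T * |S|)`.
#'
#' @param db A [motif_ranking_db()].
#' @param motif Motif id.
#' @param gene_set Character vector of gene ids (genes missing from the
#'   database are dropped with a warning).
#' @param top_frac Fraction of the ranking that defines the recovery window
#'   (default 0.05).
#' @return AUC in `[0, 1]`.
#' @export
recovery_auc <- function(db, motif, gene_set, top_frac = 0.05) {
  stopifnot(inherits(db, "motif_ranking_db"), motif %in% rownames(db$ranks))
  S <- .db_gene_set(db, gene_set)
  N <- ncol(db$ranks)
  T_ <- max(1L, ceiling(top_frac * N))
  r <- db$ranks[motif, S]
  sum(pmax(T_ - r + 1L, 0L)) / (T_ * length(S))
}

# recovery curves for all motifs over ranks 1..T: motifs x T matrix
.recovery_curves <- function(ranks_sub, T_) {
  t(apply(ranks_sub, 1L, function(r) {
    cumsum(tabulate(r[r <= T_], nbins = T_))
  }))
}

#' Motif enrichment of a module gene set
#'
#' Computes the recovery AUC of the gene set under every motif in the
#' database, standardises AUCs to normalised enrichment scores
#' `NES = (AUC - mean) / sd` over all motifs, and keeps motifs with
#' `NES >= nes_cut`. For each kept motif a leading edge is extracted: the set
#' members whose rank does not exceed the position `x*` maximising
#' `rec(x) - (mean_rec(x) + 2 sd_rec(x))`, where the critical curve is taken
#' over all motifs in the database.
#'
#' @param db A [motif_ranking_db()].
#' @param module_genes Character vector of module member genes.
#' @param module Optional module label recorded in the output.
#' @param nes_cut NES threshold (default 3).
#' @param top_frac Recovery window fraction (default 0.05).
#' @param min_genes Minimum module genes that must be present in the
#'   database (default 5).
#' @return `data.frame` with one row per enriched motif: `module`,
#'   `motif_id`, `auc`, `nes`, `tfs` (list-column) and `leading_edge`
#'   (list-column). All-motif AUC/NES are attached as attribute
#'   `"all_motifs"`.
#' @export
module_enrichment <- function(db, module_genes, module = NA_character_,
                              nes_cut = 3.0, top_frac = 0.05,
                              min_genes = 5L) {
  stopifnot(inherits(db, "motif_ranking_db"))
  if (nrow(db$ranks) < 2L) {
    stop("NES needs at least 2 motifs in the database")
  }
  S <- .db_gene_set(db, module_genes)
  if (length(S) < min_genes) {
    stop("fewer than ", min_genes, " module genes present in the database")
  }
  N <- ncol(db$ranks)
  T_ <- max(1L, ceiling(top_frac * N))
  R <- db$ranks[, S, drop = FALSE]
  clipped <- pmax(T_ - R + 1L, 0L)
  auc <- rowSums(clipped) / (T_ * length(S))
  mu <- mean(auc)
  sdev <- stats::sd(auc)
  if (sdev == 0) stop("degenerate database: all motif AUCs identical")
  nes <- (auc - mu) / sdev

  keep <- which(nes >= nes_cut)
  all_motifs <- data.frame(motif_id = rownames(db$ranks), auc = auc,
                           nes = nes, row.names = NULL)
  if (length(keep) == 0L) {
    out <- data.frame(module = character(0), motif_id = character(0),
                      auc = numeric(0), nes = numeric(0))
    out$tfs <- list()
    out$leading_edge <- list()
    attr(out, "all_motifs") <- all_motifs
    return(out)
  }

  rec <- .recovery_curves(R, T_)
  crit <- colMeans(rec) + 2 * apply(rec, 2L, stats::sd)
  ann <- db$annotations
  tfs <- vector("list", length(keep))
  ledges <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    m <- keep[i]
    xstar <- which.max(rec[m, ] - crit)
    ledges[[i]] <- S[R[m, ] <= xstar]
    mid <- rownames(db$ranks)[m]
    tfs[[i]] <- if (is.null(ann)) character(0)
                else sort(unique(ann$tf[ann$motif_id == mid]))
  }
  out <- data.frame(module = module, motif_id = rownames(db$ranks)[keep],
                    auc = auc[keep], nes = nes[keep], row.names = NULL)
  out$tfs <- tfs
  out$leading_edge <- ledges
  out <- out[order(-out$nes, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_motifs") <- all_motifs
  out
}

#' Motif enrichment for every module of a module set
#'
#' @param db A [motif_ranking_db()].
#' @param modules A `module_set` from [detect_modules()].
#' @param ... Passed to [module_enrichment()].
#' @return Row-bound enrichment `data.frame` over all non-grey modules with
#'   at least `min_genes` members in the database.
#' @export
enrich_modules <- function(db, modules, ...) {
  sets <- module_gene_sets(modules)
  res <- list()
  for (m in names(sets)) {
    r <- tryCatch(module_enrichment(db, sets[[m]], module = m, ...),
                  error = function(e) NULL)
    if (!is.null(r) && nrow(r)) res[[m]] <- r
  }
  if (!length(res)) {
    out <- data.frame(module = character(0), motif_id = character(0),
                      auc = numeric(0), nes = numeric(0))
    out$tfs <- list(); out$leading_edge <- list()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble TF regulons from motif enrichment results
#'
#' Per TF and module, the regulon targets are the union of the leading edges
#' of that TF's enriched motifs; the best (largest) NES among those motifs is
#' recorded. Enriched motifs without annotation contribute no regulon.
#'
#' @param results Enrichment `data.frame` from [module_enrichment()] /
#'   [enrich_modules()].
#' @return `data.frame` with columns `tf`, `module`, `best_nes`,
#'   `n_targets` and list-column `targets`, ordered by module then TF.
#' @export
build_regulons <- function(results) {
  if (nrow(results) == 0L) {
    out <- data.frame(tf = character(0), module = character(0),
                      best_nes = numeric(0), n_targets = integer(0))
    out$targets <- list()
    return(out)
  }
  rows <- list()
  for (i in seq_len(nrow(results))) {
    for (tf in results$tfs[[i]]) {
      key <- paste(tf, results$module[i], sep = "\r")
      prev <- rows[[key]]
      if (is.null(prev)) {
        rows[[key]] <- list(tf = tf, module = results$module[i],
                            best_nes = results$nes[i],
                            targets = results$leading_edge[[i]])
      } else {
        prev$best_nes <- max(prev$best_nes, results$nes[i])
        prev$targets <- union(prev$targets, results$leading_edge[[i]])
        rows[[key]] <- prev
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(tf = character(0), module = character(0),
                      best_nes = numeric(0), n_targets = integer(0))
    out$targets <- list()
    return(out)
  }
  out <- data.frame(
    tf = vapply(rows, `[[`, character(1), "tf"),
    module = vapply(rows, `[[`, character(1), "module"),
    best_nes = vapply(rows, `[[`, numeric(1), "best_nes"),
    n_targets = vapply(rows, function(r) length(r$targets), integer(1)),
    row.names = NULL)
  out$targets <- lapply(rows, function(r) sort(r$targets))
  out <- out[order(out$module, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}
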