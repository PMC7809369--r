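#' Filter and rank candidate master-regulator TFs
#'
#' The integration core. A candidate is a (TF, module) pair carrying a
#' regulon. It is retained only when all four predicates hold:
#' \enumerate{
#'   \item the TF is differentially expressed and up in the target
#'     population (`significant` and `log2fc > 0` in `de`);
#'   \item its module-membership centrality exceeds `kme_cut` in that module
#'     (whether or not the TF is assigned to it);
#'   \item the module is more active in the target cell type than in the
#'     others (`target_active` in `activity`);
#'   \item the regulon's best NES reaches `nes_cut`.
#' }
#' Survivors are ranked by the fraction of the module's genes they regulate,
#' descending; ties by absolute log2 fold change descending, then symbol.
#'
#' @param de `data.frame` from [nb_wald_de()] (columns `gene`, `log2fc`,
#'   `padj`, `significant`), target versus reference contrast.
#' @param modules A `module_set` from [detect_modules()].
#' @param activity `data.frame` from [celltype_activity()] for the same
#'   target cell type.
#' @param regulons `data.frame` from [build_regulons()].
#' @param kme_cut kME threshold, strict (default 0.5).
#' @param nes_cut NES threshold (default 3).
#' @return `data.frame`: `tf`, `module`, `kme`, `best_nes`, `log2fc`,
#'   `padj`, `fraction_regulated`, `rank`.
#' @export
rank_tfs <- function(de, modules, activity, regulons,
                     kme_cut = 0.5, nes_cut = 3.0) {
  stopifnot(inherits(modules, "module_set"))
  empty <- data.frame(tf = character(0), module = character(0),
                      kme = numeric(0), best_nes = numeric(0),
                      log2fc = numeric(0), padj = numeric(0),
                      fraction_regulated = numeric(0), rank = integer(0))
  if (nrow(regulons) == 0L) return(empty)
  sets <- module_gene_sets(modules)
  active <- stats::setNames(activity$target_active, activity$module)
  de_idx <- match(regulons$tf, de$gene)

  rows <- list()
  for (i in seq_len(nrow(regulons))) {
    tf <- regulons$tf[i]
    mod <- regulons$module[i]
    di <- de_idx[i]
    if (is.na(di)) next
    if (!isTRUE(de$significant[di]) || !isTRUE(de$log2fc[di] > 0)) next
    if (!mod %in% colnames(modules$kme) || !tf %in% rownames(modules$kme)) {
      warning("no kME for candidate ", tf, " / ", mod, "; dropped")
      next
    }
    kme <- modules$kme[tf, mod]
    if (is.na(kme)) {
      warning("missing kME for candidate ", tf, " / ", mod, "; dropped")
      next
    }
    if (!(kme > kme_cut)) next
    if (!isTRUE(active[mod])) next
    if (!(regulons$best_nes[i] >= nes_cut)) next
    mod_genes <- sets[[mod]]
    frac <- length(intersect(regulons$targets[[i]], mod_genes)) /
      length(mod_genes)
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, module = mod, kme = kme, best_nes = regulons$best_nes[i],
      log2fc = de$log2fc[di], padj = de$padj[di],
      fraction_regulated = frac, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction_regulated, -abs(out$log2fc), out$tf), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export node and edge tables for network visualisation
#'
#' Builds tables importable by standard network-visualisation tools. Each
#' ranked TF contributes edges to at most `top_targets` of its regulon
#' targets, chosen by absolute log2 fold change. Nodes carry: colour = the
#' gene's module colour, except that a TF assigned elsewhere is recoloured to
#' the module of interest when its kME there exceeds 0.5; shape = `"ellipse"`
#' for genes up in the target population (`log2fc > 0`), `"rectangle"`
#' otherwise; size = `10 + 2 * outdegree` (so pure targets have size 10).
#'
#' @param rows Ranking `data.frame` from [rank_tfs()].
#' @param regulons `data.frame` from [build_regulons()].
#' @param de DE table providing `gene` and `log2fc`.
#' @param modules A `module_set`.
#' @param top_targets Per-TF edge cap (default 20).
#' @return List with `nodes` (`id`, `colour`, `shape`, `size`) and `edges`
#'   (`source`, `target`, `interaction`).
#' @export
export_network <- function(rows, regulons, de, modules, top_targets = 20L) {
  stopifnot(inherits(modules, "module_set"))
  lfc <- stats::setNames(de$log2fc, de$gene)
  edges <- list()
  for (i in seq_len(nrow(rows))) {
    tf <- rows$tf[i]; mod <- rows$module[i]
    ri <- which(regulons$tf == tf & regulons$module == mod)
    if (!length(ri)) next
    targets <- setdiff(regulons$targets[[ri[1]]], tf)
    tl <- abs(lfc[targets])
    tl[is.na(tl)] <- -Inf
    targets <- targets[order(-tl, targets)]
    targets <- utils::head(targets, top_targets)
    if (!length(targets)) next
    edges[[length(edges) + 1L]] <- data.frame(
      source = tf, target = targets, interaction = "regulates",
      stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               interaction = character(0))
  rownames(edges) <- NULL

  ids <- unique(c(rows$tf, edges$target))
  outdeg <- table(edges$source)
  colour <- modules$assignment[ids]
  colour[is.na(colour)] <- "grey"
  names(colour) <- ids
  # recolour TFs of other modules into the module of interest when central
  for (i in seq_len(nrow(rows))) {
    tf <- rows$tf[i]; mod <- rows$module[i]
    if (!identical(colour[[tf]], mod) &&
        tf %in% rownames(modules$kme) && mod %in% colnames(modules$kme) &&
        isTRUE(modules$kme[tf, mod] > 0.5)) {
      colour[[tf]] <- mod
    }
  }
  nodes <- data.frame(
    id = ids,
    colour = unname(colour),
    shape = ifelse(!is.na(lfc[ids]) & lfc[ids] > 0, "ellipse", "rectangle"),
    size = 10 + 2 * as.integer(ifelse(is.na(outdeg[ids]), 0L, outdeg[ids])),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}

#' TF rankings for every cell type
#'
#' Applies [rank_tfs()] once per cell type, each with its own target-versus-
#' rest DE table and activity table; modules and regulons are shared.
#'
#' @param inputs Named list (one element per cell type), each a list with
#'   elements `de` and `activity`.
#' @param modules A `module_set`.
#' @param regulons `data.frame` from [build_regulons()].
#' @param ... Passed to [rank_tfs()].
#' @return Named list of ranking `data.frame`s, in sorted cell-type order.
#' @export
rank_all_celltypes <- function(inputs, modules, regulons, ...) {
  stopifnot(is.list(inputs), !is.null(names(inputs)))
  cts <- sort(names(inputs))
  out <- lapply(cts, function(ct) {
    rank_tfs(inputs[[ct]]$de, modules, inputs[[ct]]$activity, regulons, ...)
  })
  names(out) <- cts
  out
}
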