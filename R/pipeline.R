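#' Run the full TF prioritisation pipeline
#'
#' Convenience wrapper chaining the stages on already-ingested inputs:
#' batch adjustment (when the sample metadata carries a `batch` column with
#' more than one level), soft-threshold selection, module detection, motif
#' enrichment and regulon assembly, module activity scoring, two-group
#' differential expression of the bulk contrast, and the final TF filter and
#' ranking for the target cell type.
#'
#' @param em [expression_matrix] (log2 scale) with `cell_type` (and
#'   optionally `batch`) sample metadata.
#' @param db A [motif_ranking_db()] with motif-to-TF annotations.
#' @param counts Bulk count matrix for the DE contrast (target versus
#'   reference population).
#' @param groups Two-level factor for `counts` (reference level first).
#' @param target_celltype Cell type whose regulators are sought.
#' @param power Soft-thresholding power; `NULL` (default) picks it via
#'   [pick_soft_threshold()].
#' @param kme_cut,nes_cut Filter thresholds passed to [rank_tfs()].
#' @param min_module_size,merge_cut Passed to [detect_modules()].
#' @param top_frac Recovery window passed to [enrich_modules()].
#' @return List with all intermediate results: `em` (adjusted), `power`,
#'   `modules`, `enrichment`, `regulons`, `scores`, `activity`, `de`,
#'   `ranking`, `network`.
#' @export
prioritize_tfs <- function(em, db, counts, groups, target_celltype,
                           power = NULL, kme_cut = 0.5, nes_cut = 3.0,
                           min_module_size = 30L, merge_cut = 0.3,
                           top_frac = 0.05) {
  if ("batch" %in% names(em$samples) &&
      length(unique(em$samples$batch)) > 1L) {
    model <- fit_combat(em, "batch")
    em <- adjust_combat(em, model, "batch")
  }
  if (is.null(power)) {
    power <- pick_soft_threshold(em)$chosen_power
  }
  modules <- detect_modules(em, power, min_module_size = min_module_size,
                            merge_cut = merge_cut)
  enrichment <- enrich_modules(db, modules, nes_cut = nes_cut,
                               top_frac = top_frac)
  regulons <- build_regulons(enrichment)
  scores <- gsva_scores(em, module_gene_sets(modules))
  activity <- celltype_activity(scores, em$samples$cell_type,
                                target_celltype)
  de <- nb_wald_de(counts, groups)
  ranking <- rank_tfs(de, modules, activity, regulons,
                      kme_cut = kme_cut, nes_cut = nes_cut)
  network <- export_network(ranking, regulons, de, modules)
  list(em = em, power = power, modules = modules, enrichment = enrichment,
       regulons = regulons, scores = scores, activity = activity, de = de,
       ranking = ranking, network = network)
}
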