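# minimal hand-built module_set for predicate-level tests
tiny_modules <- function() {
  genes <- c("TF1", "TF2", paste0("t", 1:8))
  assignment <- stats::setNames(
    c("turquoise", "blue", rep("turquoise", 4), rep("blue", 4)), genes)
  kme <- matrix(0.8, length(genes), 2,
                dimnames = list(genes, c("turquoise", "blue")))
  eig <- matrix(rnorm(2 * 4), 2, 4,
                dimnames = list(c("turquoise", "blue"), paste0("s", 1:4)))
  structure(list(assignment = assignment, eigengenes = eig, kme = kme,
                 sizes = c(5L, 5L)), class = "module_set")
}

tiny_de <- function(lfc_tf1 = 2, sig_tf1 = TRUE) {
  data.frame(gene = c("TF1", "TF2", paste0("t", 1:8)),
             log2fc = c(lfc_tf1, 2, rep(1.5, 8)),
             padj = 0.001,
             significant = c(sig_tf1, TRUE, rep(TRUE, 8)))
}

tiny_regulons <- function() {
  reg <- data.frame(tf = c("TF1", "TF2"),
                    module = c("turquoise", "blue"),
                    best_nes = c(5, 4), n_targets = c(3L, 2L))
  reg$targets <- list(c("t1", "t2", "t3"), c("t5", "t6"))
  reg
}

tiny_activity <- function(turquoise = TRUE, blue = TRUE) {
  data.frame(module = c("turquoise", "blue"),
             target_mean = 0.5, other_mean = -0.5,
             target_active = c(turquoise, blue))
}

test_that("every ranking predicate is enforced individually", {
  ms <- tiny_modules()
  base <- rank_tfs(tiny_de(), ms, tiny_activity(), tiny_regulons())
  expect_equal(base$tf, c("TF1", "TF2"))
  expect_equal(base$fraction_regulated, c(3 / 5, 2 / 5))
  expect_equal(base$rank, 1:2)
  # (a) not significant, or down-regulated
  expect_false("TF1" %in% rank_tfs(tiny_de(sig_tf1 = FALSE), ms,
                                   tiny_activity(), tiny_regulons())$tf)
  expect_false("TF1" %in% rank_tfs(tiny_de(lfc_tf1 = -2), ms,
                                   tiny_activity(), tiny_regulons())$tf)
  # (b) kME at the threshold is excluded (strict cut)
  ms2 <- tiny_modules()
  ms2$kme["TF1", "turquoise"] <- 0.4
  expect_false("TF1" %in% rank_tfs(tiny_de(), ms2, tiny_activity(),
                                   tiny_regulons())$tf)
  ms3 <- tiny_modules()
  ms3$kme["TF1", "turquoise"] <- 0.5
  expect_false("TF1" %in% rank_tfs(tiny_de(), ms3, tiny_activity(),
                                   tiny_regulons())$tf)
  # (c) inactive module
  expect_false("TF1" %in% rank_tfs(tiny_de(), ms,
                                   tiny_activity(turquoise = FALSE),
                                   tiny_regulons())$tf)
  # (d) NES below the cut
  reg <- tiny_regulons()
  reg$best_nes[1] <- 2.5
  expect_false("TF1" %in% rank_tfs(tiny_de(), ms, tiny_activity(), reg)$tf)
  # no candidates at all
  expect_equal(nrow(rank_tfs(tiny_de(), ms, tiny_activity(),
                             tiny_regulons()[0, , drop = FALSE])), 0L)
})

test_that("the planted master regulator ranks first end to end", {
  study <- simulate_study(seed = 13)
  res <- prioritize_tfs(study$em, study$db, study$counts, study$groups,
                        study$target_celltype)
  expect_gte(nrow(res$ranking), 1L)
  expect_equal(res$ranking$tf[1], unname(study$planted_tfs[["M1"]]))
  expect_equal(res$ranking$fraction_regulated[1], 0.6, tolerance = 0.05)
  # re-validate all four predicates on every emitted row
  act <- stats::setNames(res$activity$target_active, res$activity$module)
  sets <- module_gene_sets(res$modules)
  for (i in seq_len(nrow(res$ranking))) {
    row <- res$ranking[i, ]
    di <- match(row$tf, res$de$gene)
    expect_true(res$de$significant[di] && res$de$log2fc[di] > 0)
    expect_gt(res$modules$kme[row$tf, row$module], 0.5)
    expect_true(act[[row$module]])
    expect_gte(row$best_nes, 3)
    ri <- which(res$regulons$tf == row$tf &
                  res$regulons$module == row$module)
    expect_equal(row$fraction_regulated,
                 length(intersect(res$regulons$targets[[ri]],
                                  sets[[row$module]])) /
                   length(sets[[row$module]]))
  }
  # deterministic output ordering on rerun
  res2 <- prioritize_tfs(study$em, study$db, study$counts, study$groups,
                         study$target_celltype)
  expect_identical(res$ranking, res2$ranking)
})

test_that("network export caps edges, shapes nodes and sizes by outdegree", {
  ms <- tiny_modules()
  genes <- c("TF1", "TF2", paste0("t", 1:8))
  # a TF with 25 regulon targets is capped at 20 edges
  manyt <- sprintf("u%02d", 1:25)
  assignment <- stats::setNames(
    c("turquoise", rep("turquoise", 25)), c("TF1", manyt))
  kme <- matrix(0.9, 26, 1, dimnames = list(c("TF1", manyt), "turquoise"))
  msl <- structure(list(assignment = assignment,
                        eigengenes = matrix(rnorm(4), 1, 4,
                                            dimnames = list("turquoise",
                                                            paste0("s", 1:4))),
                        kme = kme, sizes = 26L), class = "module_set")
  reg <- data.frame(tf = "TF1", module = "turquoise", best_nes = 5,
                    n_targets = 25L)
  reg$targets <- list(manyt)
  rows <- data.frame(tf = "TF1", module = "turquoise", kme = 0.9,
                     best_nes = 5, log2fc = 2, padj = 0.001,
                     fraction_regulated = 0.9, rank = 1L)
  de <- data.frame(gene = c("TF1", manyt),
                   log2fc = c(2, seq(3, -3, length.out = 25)))
  net <- export_network(rows, reg, de, msl, top_targets = 20)
  expect_equal(nrow(net$edges), 20L)
  # targets chosen by |log2fc|: the near-zero middle is left out
  expect_true(all(abs(de$log2fc[match(net$edges$target, de$gene)]) >=
                    sort(abs(seq(3, -3, length.out = 25)),
                         decreasing = TRUE)[20] - 1e-9))
  tf_node <- net$nodes[net$nodes$id == "TF1", ]
  expect_equal(tf_node$size, 10 + 2 * 20)
  expect_equal(tf_node$shape, "ellipse")
  # down-regulated genes become rectangles; plain targets have size 10
  down <- net$nodes[net$nodes$id %in% de$gene[de$log2fc < 0], ]
  expect_true(all(down$shape == "rectangle"))
  expect_true(all(down$size == 10))
})

test_that("shared targets are deduplicated and TFs recoloured by kME", {
  genes <- c("TF1", "TF2", "t1", "t2", "t3")
  assignment <- stats::setNames(
    c("turquoise", "blue", rep("turquoise", 3)), genes)
  kme <- matrix(c(0.9, 0.8, 0.9, 0.9, 0.9,
                  0.2, 0.9, 0.1, 0.1, 0.1), 5, 2,
                dimnames = list(genes, c("turquoise", "blue")))
  ms <- structure(list(assignment = assignment,
                       eigengenes = matrix(rnorm(8), 2, 4,
                                           dimnames = list(c("turquoise", "blue"),
                                                           paste0("s", 1:4))),
                       kme = kme, sizes = c(4L, 1L)), class = "module_set")
  reg <- data.frame(tf = c("TF1", "TF2"), module = "turquoise",
                    best_nes = c(5, 4), n_targets = c(2L, 2L))
  reg$targets <- list(c("t1", "t2"), c("t2", "t3"))
  rows <- data.frame(tf = c("TF1", "TF2"), module = "turquoise",
                     kme = c(0.9, 0.8), best_nes = c(5, 4),
                     log2fc = c(2, 1.5), padj = 0.001,
                     fraction_regulated = c(0.5, 0.5), rank = 1:2)
  de <- data.frame(gene = genes, log2fc = c(2, 1.5, 1, 1, 1))
  net <- export_network(rows, reg, de, ms)
  expect_equal(sum(net$nodes$id == "t2"), 1L)          # deduplicated node
  expect_equal(sum(net$edges$target == "t2"), 2L)      # but two edges
  # TF2 is assigned to blue but central in turquoise -> recoloured
  expect_equal(net$nodes$colour[net$nodes$id == "TF2"], "turquoise")
})

test_that("per-cell-type rankings are headed by their own regulators", {
  ms <- tiny_modules()
  reg <- tiny_regulons()
  # cell type A: turquoise active, TF1 up; cell type B: blue active, TF2 up
  de_a <- tiny_de()
  de_a$significant[de_a$gene == "TF2"] <- FALSE
  de_b <- tiny_de()
  de_b$significant[de_b$gene == "TF1"] <- FALSE
  inputs <- list(
    B = list(de = de_b, activity = tiny_activity(turquoise = FALSE)),
    A = list(de = de_a, activity = tiny_activity(blue = FALSE)))
  out <- rank_all_celltypes(inputs, ms, reg)
  expect_equal(names(out), c("A", "B"))                # deterministic order
  expect_equal(out$A$tf, "TF1")
  expect_equal(out$B$tf, "TF2")
  # a cell type with no active modules yields an empty ranking
  none <- rank_all_celltypes(
    list(C = list(de = tiny_de(),
                  activity = tiny_activity(FALSE, FALSE))), ms, reg)
  expect_equal(nrow(none$C), 0L)
})
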