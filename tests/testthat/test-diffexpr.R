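test_that("merged exon lengths are interval-union lengths", {
  gm <- data.frame(chrom = "chr1", start = c(1, 5, 30), end = c(10, 20, 40))
  expect_equal(merged_exon_length(gm), 31L)
  expect_equal(merged_exon_length(
    data.frame(chrom = "chr2", start = 100, end = 199)), 100L)
  # duplicated exons contribute once
  expect_equal(merged_exon_length(gm[c(1, 1, 2, 3), ]),
               merged_exon_length(gm))
  expect_error(merged_exon_length(
    data.frame(chrom = "chr1", start = 10, end = 5)), "malformed")
  models <- data.frame(gene_id = c("A", "A", "B"), chrom = "chr1",
                       start = c(1, 5, 1), end = c(10, 20, 5))
  expect_equal(gene_lengths(models), c(A = 20L, B = 5L))
})

test_that("TPM normalises by length and sums to one million", {
  counts <- matrix(c(10, 20), 2, 1, dimnames = list(c("A", "B"), "s1"))
  out <- tpm(counts, c(A = 1000, B = 2000))
  expect_equal(unname(out[, 1]), c(5e5, 5e5))
  expect_equal(unname(tpm(matrix(7, 1, 1, dimnames = list("A", "s")),
                          c(A = 100))[1, 1]), 1e6)
  # scale invariance within a sample
  set.seed(3)
  m <- matrix(rpois(20, 50), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  len <- stats::setNames(sample(200:2000, 5), paste0("g", 1:5))
  t1 <- tpm(m, len)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  expect_equal(tpm(m2, len)[, 2], t1[, 2])
  expect_equal(unname(colSums(t1)), rep(1e6, 4), tolerance = 1e-6)
  expect_error(tpm(m, stats::setNames(c(0, len[-1]), names(len))), "length")
  mz <- m; mz[, 3] <- 0
  expect_warning(tz <- tpm(mz, len), "all-zero")
  expect_equal(unname(tz[, 3]), rep(0, 5))
})

test_that("size factors are scale-equivariant and guarded", {
  set.seed(4)
  m <- matrix(rpois(40, 100) + 1, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sf <- size_factors(m)
  m2 <- m; m2[, 1] <- m2[, 1] * 5
  sf2 <- size_factors(m2)
  # size factors are defined up to a common constant: the rescaled column's
  # factor grows fivefold relative to the others, and normalised counts are
  # unchanged up to that common constant
  expect_equal(unname((sf2[1] / sf2[2]) / (sf[1] / sf[2])), 5,
               tolerance = 1e-6)
  q1 <- sweep(m, 2, sf, "/"); q2 <- sweep(m2, 2, sf2, "/")
  expect_equal(q2 / q1, matrix(mean(q2 / q1), 10, 4, dimnames = dimnames(m)),
               tolerance = 1e-6)
  expect_error(size_factors(matrix(0, 2, 2)), "all-positive")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # adjusted values never fall below raw and are monotone when sorted
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("NB Wald DE is null on duplicated groups and recovers effects", {
  set.seed(6)
  base <- matrix(rnbinom(500 * 4, mu = 100, size = 20), 500, 4)
  counts <- cbind(base, base)
  dimnames(counts) <- list(sprintf("G%03d", 1:500), sprintf("s%d", 1:8))
  de0 <- nb_wald_de(counts, rep(c("a", "b"), each = 4))
  expect_equal(de0$log2fc, rep(0, 500), tolerance = 1e-6)
  expect_false(any(de0$significant))

  # planted fourfold genes: 100 of 2000, NB mean 100, dispersion 0.05
  planted <- stats::setNames(rep(2, 100), sprintf("G%04d", 1:100))
  cnt <- simulate_counts(n_genes = 2000, n_per_group = 10,
                         planted_log2fc = planted, seed = 5)
  de <- nb_wald_de(cnt$counts, cnt$groups)
  pl <- de$gene %in% names(planted)
  expect_lt(abs(median(abs(de$log2fc[pl])) - 2), 0.25)
  expect_gte(mean(de$padj[pl] < 0.05, na.rm = TRUE), 0.9)
  # every flagged gene satisfies the significance rule
  sig <- de[de$significant, ]
  expect_true(all(sig$padj < 0.05 & abs(sig$log2fc) >= 1))
  expect_error(nb_wald_de(cnt$counts, rep("a", 20)), "two levels")
  expect_error(nb_wald_de(cnt$counts[, 1:3], factor(c("a", "a", "b"))),
               "at least 2 samples")
})

test_that("fold-change estimates agree with the reference NB machinery", {
  planted <- stats::setNames(rep(c(1.5, -1.5), each = 25),
                             sprintf("G%04d", 1:50))
  cnt <- simulate_counts(n_genes = 400, n_per_group = 6,
                         planted_log2fc = planted, seed = 17)
  de <- nb_wald_de(cnt$counts, cnt$groups)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = cnt$counts,
    colData = data.frame(condition = cnt$groups),
    design = ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  ok <- !is.na(ref$log2FoldChange) & !is.na(de$log2fc)
  expect_gte(cor(de$log2fc[ok], ref$log2FoldChange[ok]), 0.95)
})

test_that("rank-sum markers use the exact distribution on small sides", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  out <- wilcoxon_markers(expr, c("a", "a", "a", "b", "b", "b"), "a")
  expect_equal(out$p, 0.1)
  expect_equal(out$p, wilcox_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  # identical groups: p = 1
  expr2 <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  expect_equal(wilcoxon_markers(expr2, rep(c("a", "b"), each = 3), "a")$p, 1)
  # swapping target inverts the fold change, keeps p
  ex3 <- rbind(g1 = c(1, 2, 3, 7, 8, 9))
  lab <- rep(c("a", "b"), each = 3)
  oa <- wilcoxon_markers(ex3, lab, "a")
  ob <- wilcoxon_markers(ex3, lab, "b")
  expect_equal(oa$p, ob$p)
  expect_equal(oa$log2fc, -ob$log2fc)
  # exact branch equals the enumeration oracle on random draws (n <= 8,
  # tie-free: odd values on one side, even on the other)
  set.seed(7)
  for (i in 1:5) {
    x <- sample(seq(1, 199, 2), 5); y <- sample(seq(2, 200, 2), 7)
    ex <- rbind(g = c(x, y))
    got <- wilcoxon_markers(ex, c(rep("t", 5), rep("o", 7)), "t")$p
    expect_equal(got, wilcox_exact_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(wilcoxon_markers(expr, rep("a", 6), "a"), "distinct labels")
  expect_error(wilcoxon_markers(expr, c("a", "a", rep("b", 4)), "a"),
               "3 cells")
})

test_that("marker consensus requires the threshold in every dataset", {
  ds1 <- c(A = 10, B = 8, C = 3)
  ds2 <- c(A = 9, B = 6, C = 12)
  ref <- c(A = 40, B = 50, C = 60)
  out <- consensus_markers(list(ds1, ds2), ref, threshold = 7)
  expect_equal(out$gene, "A")
  # threshold 1 keeps everything, ranked by the reference fold change
  all_out <- consensus_markers(list(ds1, ds2), ref, threshold = 1)
  expect_equal(all_out$gene, c("C", "B", "A"))
  # infinite fold changes survive; missing genes are dropped
  out2 <- consensus_markers(list(c(A = Inf, B = 8)), ref, threshold = 7)
  expect_equal(out2$gene, c("B", "A"))
  expect_equal(nrow(consensus_markers(list(), ref)), 0L)
})

test_that("the required-marker gate flags samples missing canonical genes", {
  tm <- matrix(c(5, 5, 0.2, 5), 2, 2,
               dimnames = list(c("FCGR2B", "STAB2"), c("s1", "s2")))
  gate <- required_genes_gate(tm, c("FCGR2B", "STAB2"), min_tpm = 1)
  expect_equal(gate, c(s1 = TRUE, s2 = FALSE)[colnames(tm)])
  expect_error(required_genes_gate(tm, "CLEC4G"), "absent")
})
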