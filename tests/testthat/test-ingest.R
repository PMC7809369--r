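test_that("sample inclusion rules keep and drop the right records", {
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    organism = c("Homo sapiens", "Mus musculus", "Homo sapiens",
                 "Homo sapiens"),
    label = c("biotin", "biotin", "biotin", "Cy3"),
    platform_id = c("A-AFFY-44", "A-AFFY-44", "A-AFFY-2", "A-AFFY-44"),
    study_id = "E1", cell_type = "EC", stringsAsFactors = FALSE)
  meta$characteristics <- list("liver", "liver",
                               "hepatocellular carcinoma", "liver")
  kept <- filter_samples(meta)
  expect_equal(kept$sample_id, "s1")           # organism, denylist, label rules
  # idempotence
  expect_equal(filter_samples(kept), kept)
  # malformed record (missing organism) rejected with a logged reason
  meta$organism[1] <- NA
  expect_message(out <- suppressWarnings(filter_samples(meta)),
                 "missing organism")
  expect_equal(nrow(out), 0L)
  expect_warning(filter_samples(meta[2, , drop = FALSE]), "no samples")
})

test_that("probe aggregation takes per-gene geometric means", {
  v <- matrix(c(4, 16, 7, 2, 4, 8), nrow = 6,
              dimnames = list(paste0("p", 1:6), "s1"))
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB", p4 = "GC", p5 = "GC", p6 = "GC")
  em <- aggregate_probes(v, map)
  expect_equal(unname(em$values[, 1]), c(8, 7, 4))   # order: GA, GB, GC
  expect_equal(rownames(em$values), c("GA", "GB", "GC"))
  expect_false(em$log2_scale)
  # invariant to probe-row permutation
  perm <- sample(6)
  em2 <- aggregate_probes(v[perm, , drop = FALSE], map)
  expect_equal(em2$values, em$values)
  # unmapped probes dropped; zero intensity among mapped probes is an error
  expect_equal(nrow(aggregate_probes(v, map[1:3])$values), 2L)
  v[2, 1] <- 0
  expect_error(aggregate_probes(v, map), "p2.*s1")
})

test_that("quantile normalisation equalises column distributions", {
  em <- make_em(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  qn <- quantile_normalize(em)
  expect_equal(unname(qn$values), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical columns are a fixed point
  em2 <- make_em(cbind(c(5, 1, 3), c(5, 1, 3)))
  expect_equal(quantile_normalize(em2)$values, em2$values)
  # two-way tie receives the mean of the tied reference block
  em3 <- make_em(cbind(c(1, 1, 3), c(2, 5, 8)))
  qn3 <- quantile_normalize(em3)
  expect_equal(unname(qn3$values[, 1]), c(2.25, 2.25, 5.5))
  expect_equal(unname(qn3$values[, 2]), c(1.5, 3, 5.5))
  # single sample rejected
  expect_error(quantile_normalize(make_em(matrix(1:3, 3, 1))), "2 samples")
  # property: all columns share the same sorted multiset (no-ties case)
  set.seed(4)
  m <- matrix(rnorm(60), 12, 5)
  q <- quantile_normalize(make_em(m))$values
  ref <- unname(sort(q[, 1]))
  for (j in 2:5) expect_identical(unname(sort(q[, j])), ref)
})

test_that("platform selection maximises samples x common genes", {
  gu <- paste0("gene", 1:21000)
  p2g <- gu[1:20000]
  p1g <- c(p2g[1:15000], gu[20001:21000])
  ps <- list(platform_summary("P1", 150, p1g),
             platform_summary("P2", 100, p2g))
  sel <- select_platforms(ps)
  expect_equal(sel$chosen, c("P1", "P2"))
  expect_equal(sel$objective, 250 * 15000)
  # single platform
  one <- select_platforms(ps[1])
  expect_equal(one$chosen, "P1")
  # forced platform disjoint from the rest wins alone
  ps3 <- list(platform_summary("P1", 150, paste0("a", 1:100)),
              platform_summary("P2", 10, paste0("b", 1:50)))
  sel3 <- select_platforms(ps3, forced = "P2")
  expect_equal(sel3$chosen, "P2")
  expect_error(select_platforms(ps3, forced = "PX"), "not present")
  expect_warning(
    select_platforms(list(platform_summary("P1", 1, "g1"))), "single sample")
})

test_that("exhaustive platform search beats every admissible subset", {
  set.seed(11)
  gu <- paste0("g", 1:500)
  ps <- lapply(1:6, function(i)
    platform_summary(paste0("P", i), sample(5:100, 1),
                     sample(gu, sample(100:400, 1))))
  sel <- suppressWarnings(select_platforms(ps))
  ids <- vapply(ps, function(p) p$platform_id, character(1))
  obj <- function(ch) {
    common <- Reduce(intersect, lapply(ps[match(ch, ids)],
                                       function(p) p$genes))
    sum(vapply(ps[match(ch, ids)], function(p) p$n_samples, integer(1))) *
      length(common)
  }
  for (k in 1:(2^6 - 1)) {
    ch <- ids[bitwAnd(k, bitwShiftL(1L, 0:5)) != 0L]
    expect_gte(sel$objective, obj(ch))
  }
  expect_equal(sel$objective, obj(sel$chosen))
})

test_that("matrix assembly intersects genes, log2-transforms and batches", {
  e1 <- expression_matrix(
    matrix(c(3, 7, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2"))),
    log2_scale = FALSE)
  e2 <- expression_matrix(
    matrix(c(2, 4, 8, 5, 1, 9), 3, 2,
           dimnames = list(c("A", "B", "C"), c("s3", "s4"))),
    log2_scale = TRUE)
  merged <- assemble_matrix(list(PA = e1, PB = e2))
  expect_equal(rownames(merged$values), c("A", "B"))
  expect_equal(ncol(merged$values), 4L)
  expect_true(merged$log2_scale)
  expect_equal(merged$values["A", "s1"], log2(4))   # linear 3 -> log2(3+1) = 2
  expect_equal(merged$values["A", "s3"], 2)         # already log2, untouched
  expect_equal(merged$samples$batch, c("PA", "PA", "PB", "PB"))
  # disjoint gene sets are an error
  e3 <- expression_matrix(
    matrix(1, 1, 1, dimnames = list("Z", "s9")), log2_scale = TRUE)
  expect_error(assemble_matrix(list(e1, e3)), "empty gene intersection")
})
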