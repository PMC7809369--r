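#' Merged (union) exon length of a gene model
#'
#' Overlapping or duplicated exon intervals are merged per chromosome and the
#' total number of covered bases is returned. Intervals are 1-based
#' inclusive, so a single exon `(start, end)` contributes
#' `end - start + 1` bases. Strand is ignored.
#'
#' @param exons `data.frame` with columns `chrom`, `start`, `end`.
#' @return Integer: total merged exon length in bp.
#' @export
merged_exon_length <- function(exons) {
  stopifnot(is.data.frame(exons),
            all(c("chrom", "start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  if (any(!is.finite(exons$start) | !is.finite(exons$end) |
          exons$start > exons$end | exons$start < 1)) {
    stop("malformed exon interval(s)")
  }
  total <- 0L
  for (ch in unique(exons$chrom)) {
    e <- exons[exons$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = e$start, end = e$end))
    total <- total + sum(IRanges::width(ir))
  }
  as.integer(total)
}

#' Merged exon lengths for many genes
#'
#' @param models `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end` (one row per exon).
#' @return Named integer vector of merged exon lengths (bp) per gene.
#' @export
gene_lengths <- function(models) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(models)))
  vapply(split(models[, c("chrom", "start", "end")], models$gene_id),
         merged_exon_length, integer(1))
}

#' Read exon gene models from a GTF file
#'
#' @param path Path to a GTF file (exon features are used).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF files requires the 'rtracklayer' package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  data.frame(gene_id = df$gene_id, chrom = as.character(df$seqnames),
             start = df$start, end = df$end, stringsAsFactors = FALSE)
}

#' Transcripts-per-million matrix
#'
#' `TPM_gj = (K_gj / L_g) / sum_h(K_hj / L_h) * 1e6`. Every column of the
#' result sums to 1e6 except all-zero columns, which stay zero (with a
#' warning).
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Named vector of gene lengths in bp (names matching
#'   rownames of `counts`) or an unnamed vector aligned to the rows.
#' @return TPM matrix with the dimensions of `counts`.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(is.matrix(counts))
  if (!is.null(names(lengths))) {
    if (!all(rownames(counts) %in% names(lengths))) {
      stop("lengths missing for some genes")
    }
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  bad <- lengths <= 0 & rowSums(counts) > 0
  if (any(bad)) {
    stop("zero/negative length with nonzero counts: ",
         paste(utils::head(rownames(counts)[bad], 5), collapse = ", "))
  }
  rate <- counts / ifelse(lengths > 0, lengths, 1)
  cs <- colSums(rate)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample column(s) left at zero")
    cs[zero] <- 1
  }
  sweep(rate, 2L, cs, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Per sample, the median ratio of its counts to the gene-wise geometric
#' mean, computed over genes with strictly positive counts in every sample.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos)) stop("no gene with all-positive counts; size factors undefined")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2L, stats::median)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (no NA).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group negative-binomial Wald differential expression
#'
#' A deliberately transparent two-group NB model: size factors by
#' median-of-ratios; per-gene dispersion by method of moments on normalised
#' counts (floored at 1e-8, no shrinkage towards a trend); an NB log-linear
#' model fitted by iteratively reweighted least squares with the log size
#' factors as offsets; a Wald z test on the group coefficient with a
#' two-sided normal p-value; BH adjustment; and the biological-relevance
#' rule: a gene is `significant` only when `padj < alpha` and the absolute
#' log2 fold change is at least `lfc_min` (default 1, i.e. twofold).
#' The fold change is the second factor level relative to the first.
#'
#' @param counts Gene-by-sample integer count matrix.
#' @param groups Two-level factor (or vector) aligned to columns; the first
#'   level is the reference.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change for significance
#'   (default 1).
#' @return `data.frame` (one row per gene): `gene`, `base_mean`, `log2fc`,
#'   `se`, `p`, `padj`, `significant`. Genes with all-zero counts get NA
#'   statistics and are never significant.
#' @export
nb_wald_de <- function(counts, groups, alpha = 0.05, lfc_min = 1) {
  stopifnot(is.matrix(counts))
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  sf <- size_factors(counts)
  q <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(q)
  x <- as.numeric(groups == levels(groups)[2])
  n1 <- sum(x == 0); n2 <- sum(x == 1)

  # method-of-moments dispersion from pooled within-group variance
  m1 <- rowMeans(q[, x == 0, drop = FALSE])
  m2 <- rowMeans(q[, x == 1, drop = FALSE])
  v1 <- apply(q[, x == 0, drop = FALSE], 1L, stats::var)
  v2 <- apply(q[, x == 1, drop = FALSE], 1L, stats::var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  shot <- mbar * mean(1 / sf)                 # Poisson part of Var(K/sf)
  disp <- pmax((vpool - shot) / mbar^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8

  # vectorised IRLS over genes; design (intercept, group), offset log(sf)
  eps <- 1e-8
  b0 <- log(pmax(m1, eps))
  b1 <- log(pmax(m2, eps)) - b0
  o <- matrix(log(sf), nrow(counts), ncol(counts), byrow = TRUE)
  X2 <- matrix(x, nrow(counts), ncol(counts), byrow = TRUE)
  se <- rep(NA_real_, nrow(counts))
  for (it in 1:50) {
    eta <- b0 + b1 * X2
    mu <- exp(eta + o)
    mu <- pmax(mu, 1e-10)
    w <- mu / (1 + disp * mu)
    zresp <- eta + (counts - mu) / mu
    Sw <- rowSums(w)
    Swx <- rowSums(w * X2)
    Swz <- rowSums(w * zresp)
    Swxz <- rowSums(w * X2 * zresp)
    det <- Sw * Swx - Swx^2
    det[det <= 0] <- NA_real_
    b1n <- (Sw * Swxz - Swx * Swz) / det
    b0n <- (Swz - Swx * b1n) / Sw
    b1n <- pmin(pmax(b1n, -30), 30)
    b0n <- pmin(pmax(b0n, -30), 30)
    delta <- pmax(abs(b1n - b1), abs(b0n - b0))
    conv <- all(delta[is.finite(delta)] < 1e-10)
    b0 <- ifelse(is.finite(b0n), b0n, b0)
    b1 <- ifelse(is.finite(b1n), b1n, b1)
    if (conv) break
  }
  eta <- b0 + b1 * X2
  mu <- pmax(exp(eta + o), 1e-10)
  w <- mu / (1 + disp * mu)
  Sw <- rowSums(w); Swx <- rowSums(w * X2)
  det <- Sw * Swx - Swx^2
  se <- sqrt(ifelse(det > 0, Sw / det, NA_real_))

  allzero <- rowSums(counts) == 0 | m1 == 0 & m2 == 0
  zstat <- b1 / se
  p <- 2 * stats::pnorm(-abs(zstat))
  p[allzero] <- NA_real_
  log2fc <- b1 / log(2)
  log2fc[allzero] <- NA_real_
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  significant <- !is.na(padj) & padj < alpha & abs(log2fc) >= lfc_min
  data.frame(gene = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, se = se, p = p, padj = padj,
             significant = significant, row.names = NULL)
}

#' Rank-sum marker test of one cell population against the rest
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the target cells against
#' all other cells (exact enumeration when both sides have at most
#' `exact_max` observations and no ties; normal approximation with tie and
#' continuity correction otherwise), with the linear-scale fold change of
#' group means and BH adjustment over genes.
#'
#' @param expr Gene-by-cell numeric matrix (linear-scale expression).
#' @param labels Cell labels aligned to the columns.
#' @param target_label Label of the population of interest.
#' @param exact_max Largest per-side size for the exact test (default 8).
#' @return `data.frame`: `gene`, `fc` (linear), `log2fc`, `p`, `padj`.
#' @export
wilcoxon_markers <- function(expr, labels, target_label, exact_max = 8L) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (length(unique(labels)) < 2L) stop("need at least two distinct labels")
  tgt <- labels == target_label
  if (sum(tgt) < 3L || sum(!tgt) < 3L) {
    stop("need at least 3 cells on each side")
  }
  exact <- sum(tgt) <= exact_max && sum(!tgt) <= exact_max
  p <- vapply(seq_len(nrow(expr)), function(g) {
    suppressWarnings(stats::wilcox.test(
      expr[g, tgt], expr[g, !tgt], alternative = "two.sided",
      exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  mt <- rowMeans(expr[, tgt, drop = FALSE])
  mo <- rowMeans(expr[, !tgt, drop = FALSE])
  fc <- ifelse(mo == 0, ifelse(mt == 0, NaN, Inf), mt / mo)
  data.frame(gene = rownames(expr), fc = fc, log2fc = log2(fc),
             p = p, padj = bh_adjust(p), row.names = NULL)
}

#' Cross-dataset marker consensus by fold-change threshold
#'
#' Keeps the genes whose fold change exceeds `threshold` in every supplied
#' table (genes missing from any table are dropped; infinite fold changes
#' from zero denominators survive the threshold) and ranks them by the
#' reference (microarray) fold change, descending.
#'
#' @param fc_tables List of named numeric fold-change vectors (or
#'   `data.frame`s with columns `gene` and `fc`), one per validation
#'   dataset.
#' @param microarray_fc Named numeric vector (or `gene`/`fc` data.frame)
#'   used for ranking.
#' @param threshold Fold-change threshold, strict (default 7).
#' @return `data.frame`: `gene`, `microarray_fc`, ordered by fold change
#'   descending.
#' @export
consensus_markers <- function(fc_tables, microarray_fc, threshold = 7.0) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$fc, x$gene) else x
  }
  tabs <- lapply(fc_tables, as_vec)
  ref <- as_vec(microarray_fc)
  if (!length(tabs)) return(data.frame(gene = character(0),
                                       microarray_fc = numeric(0)))
  genes <- Reduce(intersect, c(lapply(tabs, names), list(names(ref))))
  keep <- genes[vapply(genes, function(g)
    all(vapply(tabs, function(t) t[[g]] > threshold, logical(1))),
    logical(1))]
  if (length(keep) == 0L) {
    return(data.frame(gene = character(0), microarray_fc = numeric(0)))
  }
  out <- data.frame(gene = keep, microarray_fc = unname(ref[keep]),
                    row.names = NULL)
  out[order(-out$microarray_fc, out$gene), , drop = FALSE]
}

#' Required-marker expression gate for sample quality screening
#'
#' Flags samples in which every listed marker gene is expressed above a TPM
#' floor; used to drop samples of a labelled cell type that do not express
#' its canonical markers.
#'
#' @param tpm_matrix Gene-by-sample TPM matrix.
#' @param required_genes Marker genes that must all be expressed.
#' @param min_tpm Expression floor (default 1).
#' @return Named logical vector per sample.
#' @export
required_genes_gate <- function(tpm_matrix, required_genes, min_tpm = 1) {
  missing <- setdiff(required_genes, rownames(tpm_matrix))
  if (length(missing)) {
    stop("required gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  apply(tpm_matrix[required_genes, , drop = FALSE] > min_tpm, 2L, all)
}
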