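#' Simulate a module-structured expression matrix with planted truth
#'
#' Generates a log2-scale gene-by-sample matrix emulating the statistical
#' structure the co-expression stage assumes: blocks of genes loading on
#' latent module factors whose means differ by cell type, an additive
#' per-batch array shift applied to all genes, and i.i.d. Gaussian noise.
#' Gene `g` in module `m` for sample `j` is
#' `x_gj = baseline + loading_g * f_{latent(m), j} + shift_{batch(j)} + eps`,
#' with `loading ~ U(loading_range)`, `f ~ N(mean(latent, celltype(j)), 1)`
#' and `eps ~ N(0, noise_sd)`. Genes outside modules are pure noise (plus
#' baseline and batch shift). Two modules can be driven by the same latent
#' factor via `latent_map`, which forces their eigengenes to correlate.
#'
#' @param n_genes Total genes (default 2000).
#' @param module_sizes Integer vector of planted module sizes
#'   (default three modules of 50).
#' @param celltypes Cell-type labels (default `c("LSEC","EC_A","EC_B")`).
#' @param samples_per_celltype Samples per cell type (default 20, min 3).
#' @param factor_means Latent-by-celltype matrix of factor means; default
#'   gives latent `l` mean 2 in cell type `l` (recycled) and -1 elsewhere.
#' @param n_batches Number of batches, assigned round-robin across samples
#'   so batch is not confounded with cell type (default 2).
#' @param batch_shifts Additive shift per batch (default `c(0, 1)`).
#' @param noise_sd Noise standard deviation (default 0.5).
#' @param loading_range Range of the uniform loadings (default `c(0.5, 1)`).
#' @param latent_map Latent factor index per module (default one factor per
#'   module).
#' @param baseline Baseline log2 intensity added to all genes (default 8).
#' @param seed RNG seed; the output is reproducible given the seed.
#' @return List with `em` (an [expression_matrix], `log2_scale = TRUE`) and
#'   `truth` (a `synthetic_truth` list: `assignment`, `factor_means`,
#'   `batch`, `celltype`, `loadings`, `seed`).
#' @export
simulate_expression <- function(n_genes = 2000L,
                                module_sizes = c(50L, 50L, 50L),
                                celltypes = c("LSEC", "EC_A", "EC_B"),
                                samples_per_celltype = 20L,
                                factor_means = NULL,
                                n_batches = 2L,
                                batch_shifts = c(0, 1),
                                noise_sd = 0.5,
                                loading_range = c(0.5, 1),
                                latent_map = seq_along(module_sizes),
                                baseline = 8,
                                seed = 7L) {
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes")
  if (samples_per_celltype < 3L) stop("each cell type needs >= 3 samples")
  if (length(batch_shifts) != n_batches) {
    stop("batch_shifts must have one entry per batch")
  }
  stopifnot(length(latent_map) == length(module_sizes))
  set.seed(seed)
  n_samples <- length(celltypes) * samples_per_celltype
  ct <- rep(celltypes, each = samples_per_celltype)
  batch <- paste0("batch", rep_len(seq_len(n_batches), n_samples))
  n_latent <- max(latent_map)
  if (is.null(factor_means)) {
    factor_means <- matrix(-1, n_latent, length(celltypes),
                           dimnames = list(NULL, celltypes))
    for (l in seq_len(n_latent)) {
      factor_means[l, 1 + (l - 1) %% length(celltypes)] <- 2
    }
  }
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  # latent factor draws per sample
  f <- matrix(stats::rnorm(n_latent * n_samples), n_latent, n_samples)
  for (l in seq_len(n_latent)) {
    f[l, ] <- f[l, ] + factor_means[l, match(ct, colnames(factor_means))]
  }

  assignment <- rep("none", n_genes)
  loadings <- rep(0, n_genes)
  x <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
              n_genes, n_samples)
  pos <- 1L
  for (m in seq_along(module_sizes)) {
    idx <- pos:(pos + module_sizes[m] - 1L)
    pos <- pos + module_sizes[m]
    assignment[idx] <- paste0("M", m)
    lo <- stats::runif(length(idx), loading_range[1], loading_range[2])
    loadings[idx] <- lo
    x[idx, ] <- x[idx, ] + outer(lo, f[latent_map[m], ])
  }
  shift <- batch_shifts[as.integer(sub("batch", "", batch))]
  x <- x + baseline + matrix(shift, n_genes, n_samples, byrow = TRUE)
  dimnames(x) <- list(gene_ids, sample_ids)

  samples <- data.frame(sample_id = sample_ids,
                        organism = "Homo sapiens", label = "biotin",
                        platform_id = batch, study_id = "synthetic",
                        cell_type = ct, batch = batch,
                        stringsAsFactors = FALSE)
  truth <- structure(list(
    assignment = stats::setNames(assignment, gene_ids),
    factor_means = factor_means, latent_map = latent_map,
    batch = stats::setNames(batch, sample_ids),
    celltype = stats::setNames(ct, sample_ids),
    loadings = stats::setNames(loadings, gene_ids),
    noise_sd = noise_sd, seed = seed), class = "synthetic_truth")
  list(em = expression_matrix(x, samples = samples, log2_scale = TRUE),
       truth = truth)
}

#' Simulate a motif ranking database with planted regulons
#'
#' Every planted TF gets one motif whose target genes receive distinct ranks
#' drawn uniformly from the top `top_quantile * N` positions (the remaining
#' genes fill the remaining ranks at random); decoy motifs are fully random
#' permutations. Planted motifs are annotated to their TFs.
#'
#' @param n_decoys Number of decoy motifs (default 200).
#' @param genes Character vector of database gene ids.
#' @param regulons Named list: TF symbol -> character vector of target
#'   genes (subset of `genes`).
#' @param top_quantile Fraction of top positions the planted targets occupy
#'   (default 0.01).
#' @param seed RNG seed.
#' @return A [motif_ranking_db()] with planted + decoy motifs.
#' @export
simulate_ranking_db <- function(n_decoys = 200L, genes,
                                regulons = list(),
                                top_quantile = 0.01, seed = 3L) {
  set.seed(seed)
  genes <- as.character(genes)
  N <- length(genes)
  top <- max(1L, floor(top_quantile * N))
  rows <- list()
  for (tf in names(regulons)) {
    targets <- regulons[[tf]]
    if (!all(targets %in% genes)) stop("targets must be a subset of genes")
    if (length(targets) > top) {
      stop("more targets (", length(targets),
           ") than top positions (", top, ")")
    }
    r <- integer(N)
    names(r) <- genes
    tr <- sample(seq_len(top), length(targets))
    r[targets] <- tr
    r[setdiff(genes, targets)] <- sample(setdiff(seq_len(N), tr))
    rows[[paste0("motif_", tf)]] <- r
  }
  for (d in seq_len(n_decoys)) {
    rows[[sprintf("decoy_%03d", d)]] <- stats::setNames(sample(N), genes)
  }
  ranks <- do.call(rbind, rows)
  ann <- if (length(regulons)) {
    data.frame(motif_id = paste0("motif_", names(regulons)),
               tf = names(regulons), annotation_type = "direct",
               stringsAsFactors = FALSE)
  } else NULL
  motif_ranking_db(ranks, annotations = ann)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Counts follow `NB(mu, size = 1/dispersion)` with the planted log2 fold
#' change split symmetrically across the groups:
#' `mu_ref = mean * 2^(-lfc/2)`, `mu_target = mean * 2^(+lfc/2)`.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_group Samples per group (default 10).
#' @param planted_log2fc Named numeric vector of true log2 fold changes for
#'   a subset of genes (default none). Unnamed full-length vectors are also
#'   accepted.
#' @param mean_count Baseline NB mean (default 100).
#' @param dispersion NB dispersion (default 0.05; must be > 0).
#' @param group_labels Labels for (reference, target) (default
#'   `c("ref", "target")`).
#' @param seed RNG seed.
#' @return List with `counts` (gene-by-sample integer matrix), `groups`
#'   (factor, reference level first) and `truth` (named log2fc vector).
#' @export
simulate_counts <- function(n_genes = 2000L, n_per_group = 10L,
                            planted_log2fc = NULL, mean_count = 100,
                            dispersion = 0.05,
                            group_labels = c("ref", "target"), seed = 5L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  lfc <- stats::setNames(rep(0, n_genes), gene_ids)
  if (!is.null(planted_log2fc)) {
    if (is.null(names(planted_log2fc))) {
      stopifnot(length(planted_log2fc) == n_genes)
      lfc[] <- planted_log2fc
    } else {
      if (!all(names(planted_log2fc) %in% gene_ids)) {
        stop("planted gene names outside the simulated universe")
      }
      lfc[names(planted_log2fc)] <- planted_log2fc
    }
  }
  mu1 <- mean_count * 2^(-lfc / 2)
  mu2 <- mean_count * 2^(lfc / 2)
  k1 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = mu1,
                              size = 1 / dispersion),
               n_genes, n_per_group)
  k2 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = mu2,
                              size = 1 / dispersion),
               n_genes, n_per_group)
  counts <- cbind(k1, k2)
  dimnames(counts) <- list(gene_ids,
                           paste0(rep(group_labels, each = n_per_group),
                                  "_", rep(seq_len(n_per_group), 2)))
  groups <- factor(rep(group_labels, each = n_per_group),
                   levels = group_labels)
  list(counts = counts, groups = groups, truth = lfc)
}

#' Positivity percentage with a 95% Wilson score interval
#'
#' Reporting helper for count-based positivity readouts (e.g. the fraction
#' of cells taking up labelled IgG in an uptake assay).
#'
#' @param positives Number of positive objects (0 <= positives <= total).
#' @param total Total number of objects (>= 1).
#' @return List with `percent` (rounded to 2 decimals) and `wilson_ci`
#'   (length-2 vector, percent scale).
#' @export
positivity_summary <- function(positives, total) {
  if (total < 1) stop("total must be >= 1")
  if (positives < 0 || positives > total) {
    stop("positives must lie in [0, total]")
  }
  phat <- positives / total
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / total
  centre <- (phat + z^2 / (2 * total)) / denom
  half <- z * sqrt(phat * (1 - phat) / total + z^2 / (4 * total^2)) / denom
  list(percent = round(100 * phat, 2),
       wilson_ci = 100 * c(centre - half, centre + half))
}

#' Serialise / restore a synthetic truth object as JSON
#'
#' @param truth A `synthetic_truth` from [simulate_expression()].
#' @param path Output path.
#' @return `path`, invisibly (`write_truth`); the restored list
#'   (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # keep element names of named vectors through JSON (objects, not arrays)
  x <- lapply(x, function(el) {
    if (is.atomic(el) && !is.null(names(el)) && !is.matrix(el)) {
      as.list(el)
    } else el
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "synthetic_truth")
}

#' Simulate a full planted-regulon study
#'
#' Generates every input the end-to-end prioritisation needs, with one
#' planted master-regulator TF per module: an expression matrix (3 modules,
#' 3 cell types, 2 batches), a TF list, a motif ranking database whose
#' planted motifs rank 60% of each module's genes at the top, and a bulk
#' count matrix contrasting the first cell type (target) with a reference
#' population in which the module-1 TF and its module are up-regulated.
#' The first gene of each module acts as that module's TF.
#'
#' @param seed RNG seed (sub-seeds are derived deterministically).
#' @param n_genes Total genes (default 1000).
#' @param module_sizes Planted module sizes (default three modules of 50).
#' @param n_per_group Samples per group in the bulk contrast (default 8).
#' @param regulon_coverage Fraction of each module covered by its TF's
#'   regulon (default 0.6).
#' @return List: `em`, `truth`, `tf_list`, `db`, `counts`, `groups`,
#'   `planted_tfs` (named by module label `M1..`), `target_celltype`.
#' @export
simulate_study <- function(seed = 13L, n_genes = 1000L,
                           module_sizes = c(50L, 50L, 50L),
                           n_per_group = 8L, regulon_coverage = 0.6) {
  sim <- simulate_expression(n_genes = n_genes,
                             module_sizes = module_sizes,
                             seed = seed)
  genes <- names(sim$truth$assignment)
  mods <- paste0("M", seq_along(module_sizes))
  planted_tfs <- vapply(mods, function(m)
    genes[sim$truth$assignment == m][1], character(1))

  regulons <- lapply(mods, function(m) {
    members <- genes[sim$truth$assignment == m]
    members <- setdiff(members, planted_tfs[[m]])
    utils::head(members, ceiling(regulon_coverage * length(
      genes[sim$truth$assignment == m])))
  })
  names(regulons) <- unname(planted_tfs)
  db <- simulate_ranking_db(n_decoys = 200L, genes = genes,
                            regulons = regulons, top_quantile = 0.05,
                            seed = seed + 1L)

  # decoy TFs: noise genes that will fail the filters
  noise_genes <- genes[sim$truth$assignment == "none"]
  tf_list <- c(unname(planted_tfs), utils::head(noise_genes, 20L))

  # bulk contrast (target cell type vs an external reference population):
  # module-1 genes and the module-1 TF up, module-2 TF down, rest null
  m1 <- genes[sim$truth$assignment == "M1"]
  lfc <- stats::setNames(rep(2, length(m1)), m1)
  lfc[planted_tfs[["M1"]]] <- 3
  lfc[planted_tfs[["M2"]]] <- -2
  cnt <- simulate_counts(n_genes = n_genes, n_per_group = n_per_group,
                         planted_log2fc = lfc, seed = seed + 2L)

  list(em = sim$em, truth = sim$truth, tf_list = tf_list, db = db,
       counts = cnt$counts, groups = cnt$groups,
       counts_truth = cnt$truth, planted_tfs = planted_tfs,
       regulons_truth = regulons,
       target_celltype = sim$em$samples$cell_type[1])
}
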