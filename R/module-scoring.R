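#' Gene-set variation scores per sample
#'
#' Single-sample gene-set activity via the weighted Kolmogorov-Smirnov
#' random-walk statistic. Per gene, expression is transformed to a kernel CDF
#' estimate (Gaussian kernel, bandwidth `sd/4`, floored at 1e-8 for constant
#' genes) evaluated at each sample. Per sample, genes are ranked by
#' decreasing statistic and the symmetric rank statistic `|N/2 - rank|` is
#' formed. The random walk increments by the normalised `|r|^tau` weight at
#' in-set genes and decrements uniformly (`1/(N - |S|)`) at out-of-set genes.
#' With `mx_diff = TRUE` (default) the score is the maximum positive plus the
#' minimum negative deviation; otherwise the maximum absolute deviation with
#' its sign. Scores are bounded in `[-1, 1]`.
#'
#' @param em [expression_matrix] with at least 3 samples.
#' @param module_sets Named list of gene sets; each must have at least 2
#'   member genes present in the matrix and be a strict subset of the gene
#'   universe.
#' @param tau Rank-weight exponent (default 1).
#' @param kcdf Kernel for the per-gene CDF estimate; only `"gaussian"` is
#'   implemented.
#' @param mx_diff Score rule, see above (default TRUE).
#' @return Matrix of scores, module sets in rows, samples in columns.
#' @export
gsva_scores <- function(em, module_sets, tau = 1.0, kcdf = "gaussian",
                        mx_diff = TRUE) {
  stopifnot(inherits(em, "expression_matrix"), is.list(module_sets),
            !is.null(names(module_sets)))
  kcdf <- match.arg(kcdf, "gaussian")
  v <- em$values
  n <- ncol(v)
  N <- nrow(v)
  if (n < 3L) stop("need at least 3 samples")
  genes <- rownames(v)
  sets <- lapply(module_sets, function(s) intersect(unique(s), genes))
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < 2L) {
      stop("set '", nm, "' has fewer than 2 member genes in the matrix")
    }
    if (length(sets[[nm]]) >= N) {
      stop("set '", nm, "' equals the whole gene universe")
    }
  }

  # per-gene Gaussian kernel CDF evaluated at each sample
  sds <- apply(v, 1L, stats::sd)
  if (any(sds < 1e-8)) {
    warning(sum(sds < 1e-8), " near-constant gene(s): bandwidth floored")
  }
  h <- pmax(sds / 4, 1e-8)
  z <- matrix(0, N, n, dimnames = dimnames(v))
  for (g in seq_len(N)) {
    z[g, ] <- rowMeans(stats::pnorm(outer(v[g, ], v[g, ], "-") / h[g]))
  }

  # per-sample decreasing ranks and symmetric rank statistic
  rk <- apply(-z, 2L, rank, ties.method = "first")   # genes x samples
  rsym <- abs(N / 2 - rk)

  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(v)))
  for (si in seq_along(sets)) {
    inset <- genes %in% sets[[si]]
    nS <- sum(inset)
    dec <- 1 / (N - nS)
    for (j in seq_len(n)) {
      ord <- order(rk[, j])
      ins <- inset[ord]
      w <- rsym[ord, j]^tau
      w[!ins] <- 0
      step <- ifelse(ins, w / sum(w), -dec)
      walk <- cumsum(step)
      maxpos <- max(0, max(walk))
      minneg <- min(0, min(walk))
      scores[si, j] <- if (mx_diff) maxpos + minneg else {
        if (maxpos >= -minneg) maxpos else minneg
      }
    }
  }
  scores
}

#' Mean module activity per cell type
#'
#' @param scores Module-by-sample score matrix from [gsva_scores()].
#' @param celltypes Character vector of cell-type labels aligned to the
#'   score columns.
#' @return Module-by-cell-type matrix of mean scores.
#' @export
celltype_means <- function(scores, celltypes) {
  stopifnot(length(celltypes) == ncol(scores))
  cts <- sort(unique(celltypes))
  out <- vapply(cts, function(ct)
    rowMeans(scores[, celltypes == ct, drop = FALSE]),
    numeric(nrow(scores)))
  matrix(out, nrow = nrow(scores),
         dimnames = list(rownames(scores), cts))
}

#' Module activity in a target cell type versus all others
#'
#' A module is called active in the target when its mean score over target
#' samples strictly exceeds the mean over all non-target samples (pooled).
#' With `per_type = TRUE` the stricter rule is applied: the target mean must
#' exceed the mean of every other cell type individually.
#'
#' @param scores Module-by-sample score matrix.
#' @param celltypes Cell-type labels aligned to score columns.
#' @param target Target cell-type label.
#' @param per_type Use the stricter per-cell-type comparison (default FALSE).
#' @return `data.frame` with columns `module`, `target_mean`, `other_mean`
#'   and `target_active`.
#' @export
celltype_activity <- function(scores, celltypes, target, per_type = FALSE) {
  stopifnot(length(celltypes) == ncol(scores))
  tgt <- celltypes == target
  if (!any(tgt)) stop("target cell type has no samples")
  if (all(tgt)) stop("all samples belong to the target cell type")
  tm <- rowMeans(scores[, tgt, drop = FALSE])
  om <- rowMeans(scores[, !tgt, drop = FALSE])
  if (per_type) {
    cm <- celltype_means(scores[, !tgt, drop = FALSE], celltypes[!tgt])
    active <- vapply(seq_len(nrow(scores)),
                     function(i) all(tm[i] > cm[i, ]), logical(1))
  } else {
    active <- tm > om
  }
  data.frame(module = rownames(scores), target_mean = tm, other_mean = om,
             target_active = active, row.names = NULL)
}

#' Fisher / hypergeometric GO enrichment of a module
#'
#' One-sided Fisher exact test (upper hypergeometric tail) per term from the
#' 2x2 table of module membership versus term annotation over the background.
#' Annotations are expected to be pre-propagated to ancestor terms (see
#' [propagate_obo_annotations()] for a minimal helper). The `top_n`
#' smallest-p terms are retained per category, ties broken by term id.
#'
#' @param module_genes Character vector; must be a subset of `background`.
#' @param background Character vector of background gene ids.
#' @param annotations `data.frame` with columns `gene`, `term` and
#'   optionally `category` (e.g. BP/CC/MF; a single pseudo-category is used
#'   when absent).
#' @param top_n Terms retained per category (default 15).
#' @return `data.frame` with columns `category`, `term`, `p`,
#'   `n_module_annotated`, `n_module`, `n_annotated`, `n_background`,
#'   ordered by category then p.
#' @export
go_fisher <- function(module_genes, background, annotations, top_n = 15L) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background")
  module_genes <- unique(as.character(module_genes))
  if (!all(module_genes %in% background)) {
    stop("module genes must be a subset of the background")
  }
  stopifnot(is.data.frame(annotations),
            all(c("gene", "term") %in% names(annotations)))
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  if (!"category" %in% names(ann)) ann$category <- "all"
  ann <- unique(ann[, c("gene", "term", "category")])

  Nb <- length(background)
  nmod <- length(module_genes)
  key <- paste(ann$term, ann$category, sep = "\r")
  n_ann <- tapply(ann$gene, key, function(g) length(unique(g)))
  n_hit <- tapply(ann$gene, key, function(g)
    sum(unique(g) %in% module_genes))
  ks <- names(n_ann)
  parts <- strsplit(ks, "\r", fixed = TRUE)
  term <- vapply(parts, `[`, character(1), 1L)
  category <- vapply(parts, `[`, character(1), 2L)
  # upper-tail hypergeometric P(X >= hits) == one-sided Fisher exact
  p <- stats::phyper(n_hit - 1, n_ann, Nb - n_ann, nmod, lower.tail = FALSE)
  res <- data.frame(category = category, term = term, p = as.vector(p),
                    n_module_annotated = as.vector(n_hit),
                    n_module = nmod, n_annotated = as.vector(n_ann),
                    n_background = Nb, row.names = NULL)
  res <- res[order(res$category, res$p, res$term), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(res)), res$category),
                        function(i) utils::head(i, top_n)), use.names = FALSE)
  out <- res[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of gene character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Propagate GO annotations to ancestor terms from a minimal OBO file
#'
#' Parses `is_a` and `relationship: part_of` edges from an OBO file and adds,
#' for every annotated gene, all ancestor terms reachable through those
#' edges. This is a minimal helper for inputs that are not already
#' propagated; it does not interpret any other relationship types.
#'
#' @param annotations `data.frame` with columns `gene`, `term` (and
#'   optionally `category`, which is inherited from the child term).
#' @param obo_path Path to an OBO-format ontology file.
#' @return The augmented annotation `data.frame` (unique rows).
#' @export
propagate_obo_annotations <- function(annotations, obo_path) {
  lines <- readLines(obo_path, warn = FALSE)
  parents <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "[Term]") { cur <- NULL; next }
    if (startsWith(ln, "id: ")) { cur <- sub("^id: ", "", ln); next }
    if (is.null(cur)) next
    if (startsWith(ln, "is_a: ")) {
      p <- sub("^is_a: ([^ !]+).*$", "\\1", ln)
      parents[[cur]] <- c(parents[[cur]], p)
    } else if (startsWith(ln, "relationship: part_of ")) {
      p <- sub("^relationship: part_of ([^ !]+).*$", "\\1", ln)
      parents[[cur]] <- c(parents[[cur]], p)
    }
  }
  ancestors <- function(term) {
    seen <- character(0)
    frontier <- parents[[term]]
    while (length(frontier)) {
      new <- setdiff(frontier, seen)
      seen <- c(seen, new)
      frontier <- unique(unlist(parents[new], use.names = FALSE))
    }
    seen
  }
  extra <- list()
  for (i in seq_len(nrow(annotations))) {
    anc <- ancestors(annotations$term[i])
    if (length(anc)) {
      row <- annotations[i, , drop = FALSE]
      add <- row[rep(1L, length(anc)), , drop = FALSE]
      add$term <- anc
      extra[[length(extra) + 1L]] <- add
    }
  }
  out <- unique(rbind(annotations, do.call(rbind, extra)))
  rownames(out) <- NULL
  out
}
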