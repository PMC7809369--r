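#' Signed co-expression adjacency
#'
#' Builds the signed weighted adjacency `a_ij = ((1 + cor_ij) / 2)^power`
#' from gene-gene Pearson correlations across samples. The signed transform
#' maps anticorrelated pairs near 0 and correlated pairs near 1 before soft
#' thresholding.
#'
#' @param values Gene-by-sample numeric matrix (no constant rows).
#' @param power Soft-thresholding exponent (beta).
#' @return Symmetric adjacency matrix with zero diagonal.
#' @export
signed_adjacency <- function(values, power) {
  stopifnot(is.matrix(values), power >= 1)
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene row(s): ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  }
  a <- ((1 + stats::cor(t(values))) / 2)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit index of a connectivity vector
#'
#' Bins connectivities into `n_bins` equal-occupancy bins and regresses
#' `log10` bin density (count per unit connectivity) on `log10` mean bin
#' connectivity. The returned fit is the regression R-squared signed so that
#' a negative slope (the scale-free expectation) gives a positive index.
#'
#' @param k Numeric vector of node connectivities.
#' @param n_bins Number of equal-occupancy bins (default 10).
#' @return List with `fit` (signed R^2), `slope`, and `degenerate` (TRUE when
#'   the connectivity distribution cannot support the regression, e.g. all
#'   connectivities essentially equal).
#' @export
scale_free_fit_index <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  brk <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  # a near-constant connectivity distribution (e.g. all genes essentially
  # identical, adjacency ~ 1 everywhere) cannot support the log-log fit
  if (length(brk) < 4L || stats::sd(k) < 1e-4 * mean(k)) {
    return(list(fit = NA_real_, slope = NA_real_, degenerate = TRUE))
  }
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  count <- tapply(k, bin, length)
  width <- diff(brk)
  dens <- count / (length(k) * width)
  ok <- is.finite(mean_k) & dens > 0 & mean_k > 0
  if (sum(ok) < 3L) {
    return(list(fit = NA_real_, slope = NA_real_, degenerate = TRUE))
  }
  lx <- log10(mean_k[ok]); ly <- log10(dens[ok])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit = -sign(slope) * r2, slope = slope, degenerate = FALSE)
}

#' Choose a soft-thresholding power for the signed network
#'
#' For every candidate power the signed adjacency is formed, node
#' connectivities are computed, and the scale-free topology fit index is
#' evaluated. The chosen power is the smallest one whose fit reaches
#' `r2_cut` *and* whose regression slope lies in `slope_range` — the
#' scale-free exponent sanity band (a genuine scale-free degree distribution
#' has a log-log slope around -1 to -2; a very steep slope indicates a
#' compact, non-scale-free connectivity distribution even when R-squared is
#' high). If no power satisfies both, the slope condition is dropped; if
#' none reaches `r2_cut` at all, the power with the maximal fit is used.
#'
#' @param em [expression_matrix].
#' @param powers Candidate powers (default 1:30).
#' @param r2_cut Scale-free fit target (default 0.8).
#' @param slope_range Admissible log-log slope window (default `c(-3, -1)`).
#' @return List of class `soft_threshold_report` with a per-power table
#'   (`power`, `fit`, `slope`, `mean_connectivity`, `degenerate`) and
#'   `chosen_power`.
#' @export
pick_soft_threshold <- function(em, powers = 1:30, r2_cut = 0.8,
                                slope_range = c(-3, -1)) {
  stopifnot(inherits(em, "expression_matrix"), length(powers) >= 1)
  v <- em$values
  if (nrow(v) < 2L) stop("need at least 2 genes")
  if (ncol(v) < 20L) {
    warning("fewer than 20 samples; co-expression estimates will be noisy")
  }
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene row(s): ",
         paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "))
  }
  sim <- (1 + stats::cor(t(v))) / 2
  diag(sim) <- 0
  tab <- data.frame(power = powers, fit = NA_real_, slope = NA_real_,
                    mean_connectivity = NA_real_, degenerate = FALSE)
  a <- NULL
  for (i in seq_along(powers)) {
    a <- sim^powers[i]
    diag(a) <- 0
    kk <- rowSums(a)
    sf <- scale_free_fit_index(kk)
    tab$fit[i] <- sf$fit
    tab$slope[i] <- sf$slope
    tab$mean_connectivity[i] <- mean(kk)
    tab$degenerate[i] <- sf$degenerate
  }
  in_band <- which(!tab$degenerate & tab$fit >= r2_cut &
                     tab$slope >= slope_range[1] &
                     tab$slope <= slope_range[2])
  above_cut <- which(!tab$degenerate & tab$fit >= r2_cut)
  chosen <- if (length(in_band)) tab$power[in_band[1]]
  else if (length(above_cut)) tab$power[above_cut[1]]
  else if (all(tab$degenerate)) tab$power[1]
  else tab$power[which.max(ifelse(tab$degenerate, -Inf, tab$fit))]
  structure(list(table = tab, chosen_power = chosen, r2_cut = r2_cut),
            class = "soft_threshold_report")
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat(sprintf("soft_threshold_report: chosen power %d (r2_cut %.2f)\n",
              x$chosen_power, x$r2_cut))
  print(utils::head(x$table, 12))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the node
#' connectivity. The diagonal is 1 and off-diagonal values lie in `[0, 1]`.
#'
#' @param a Symmetric adjacency matrix with values in `[0, 1]` (diagonal
#'   ignored).
#' @return The topological overlap matrix.
#' @export
tom_matrix <- function(a) {
  stopifnot(is.matrix(a))
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  d <- a
  diag(d) <- 0
  if (any(d < 0 | d > 1)) stop("adjacency values must lie in [0, 1]")
  L <- d %*% d                                # with zero diagonal, u != i, j
  k <- rowSums(d)
  denom <- outer(k, k, pmin) + 1 - d
  w <- (L + d) / denom
  diag(w) <- 1
  w[w > 1] <- 1
  w[w < 0] <- 0
  dimnames(w) <- dimnames(a)
  w
}

# size-ordered module label palette (conventional colour ordering)
module_palette <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen",
           "darkturquoise", "darkgrey", "orange", "darkorange", "white")
  if (n <= length(pal)) pal[seq_len(n)]
  else c(pal, paste0("module", seq_len(n - length(pal)) + length(pal)))
}

# first singular vector over samples of the per-gene z-scored submatrix,
# unit norm, oriented towards the mean z-profile
.module_eigengene <- function(values) {
  z <- t(scale(t(values)))
  z[!is.finite(z)] <- 0
  v <- svd(z, nu = 0L, nv = 1L)$v[, 1]
  ref <- colMeans(z)
  s <- sum(v * ref)
  if (is.finite(s) && s < 0) v <- -v
  v
}

#' Detect co-expression modules from the topological overlap matrix
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height`; branches of at least `min_module_size` genes become modules
#' (labelled by colour in decreasing size order), smaller branches are
#' assigned to `"grey"`. Each raw branch is then pruned by module
#' membership: genes whose correlation with the branch eigengene falls below
#' `kme_prune` are returned to grey (average-linkage chaining otherwise
#' attaches weakly correlated genes to strong branches just below the cut;
#' the floor re-uses the same kME = 0.5 centrality threshold the downstream
#' TF filter applies). Module eigengenes are the first singular vectors of
#' the per-gene standardised module submatrices, oriented so they correlate
#' non-negatively with the module mean profile. Modules whose eigengene
#' dissimilarity `1 - cor` falls below `merge_cut` are merged iteratively
#' (closest pair first, eigengenes recomputed after each merge). kME is the
#' Pearson correlation of every gene with every module eigengene.
#'
#' @param em [expression_matrix] with at least 3 samples.
#' @param power Soft-thresholding power (from [pick_soft_threshold()]).
#' @param min_module_size Minimum genes per module (default 30).
#' @param merge_cut Eigengene dissimilarity below which modules merge
#'   (default 0.3).
#' @param cut_height Static tree cut height on `1 - TOM` dissimilarity
#'   (default 0.99).
#' @param kme_prune Module-membership floor below which a branch gene is
#'   returned to grey (default 0.5; 0 disables pruning).
#' @return A `module_set`: list with `assignment` (named character vector,
#'   `"grey"` = unassigned), `eigengenes` (module-by-sample matrix, rows unit
#'   norm), `kme` (gene-by-module matrix), `sizes`, and `dendrogram`.
#' @export
detect_modules <- function(em, power, min_module_size = 30L,
                           merge_cut = 0.3, cut_height = 0.99,
                           kme_prune = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (ncol(v) < 3L) stop("eigengenes need at least 3 samples")
  if (nrow(v) < min_module_size) stop("fewer genes than min_module_size")
  a <- signed_adjacency(v, power)
  w <- tom_matrix(a)
  h <- stats::hclust(stats::as.dist(1 - w), method = "average")
  cl <- stats::cutree(h, h = cut_height)

  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # deterministic size order; ties by first gene index
  first_idx <- vapply(big, function(b) min(which(cl == as.integer(b))),
                      integer(1))
  big <- big[order(-as.vector(sizes[big]), first_idx)]

  assignment <- rep("grey", nrow(v))
  names(assignment) <- rownames(v)
  groups <- lapply(big, function(b) which(cl == as.integer(b)))

  # membership pruning: drop branch genes weakly correlated with the branch
  # eigengene, then re-apply the size rule
  if (kme_prune > 0 && length(groups)) {
    groups <- lapply(groups, function(idx) {
      eg <- .module_eigengene(v[idx, , drop = FALSE])
      kme <- as.vector(suppressWarnings(stats::cor(t(v[idx, , drop = FALSE]),
                                                   eg)))
      idx[!is.na(kme) & kme >= kme_prune]
    })
    groups <- groups[vapply(groups, length, integer(1)) >= min_module_size]
  }

  # iterative merging on eigengene dissimilarity
  if (length(groups) >= 2L) {
    repeat {
      me <- t(vapply(groups, function(idx)
        .module_eigengene(v[idx, , drop = FALSE]), numeric(ncol(v))))
      dis <- 1 - stats::cor(t(me))
      diag(dis) <- Inf
      if (min(dis) >= merge_cut) break
      pair <- which(dis == min(dis), arr.ind = TRUE)[1, ]
      i <- min(pair); j <- max(pair)
      groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
      groups[[j]] <- NULL
      if (length(groups) < 2L) break
    }
  }

  # final size-ordered labels
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, min, integer(1)))
  groups <- groups[ord]
  labels <- module_palette(length(groups))
  for (i in seq_along(groups)) assignment[groups[[i]]] <- labels[i]

  if (length(groups)) {
    eigengenes <- t(vapply(groups, function(idx)
      .module_eigengene(v[idx, , drop = FALSE]), numeric(ncol(v))))
    rownames(eigengenes) <- labels
    colnames(eigengenes) <- colnames(v)
    kme <- suppressWarnings(stats::cor(t(v), t(eigengenes)))
  } else {
    eigengenes <- matrix(0, 0, ncol(v),
                         dimnames = list(NULL, colnames(v)))
    kme <- matrix(0, nrow(v), 0, dimnames = list(rownames(v), NULL))
  }

  structure(list(assignment = assignment, eigengenes = eigengenes,
                 kme = kme,
                 sizes = vapply(groups, length, integer(1)),
                 power = power, dendrogram = h),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- nrow(x$eigengenes)
  cat(sprintf("module_set: %d modules over %d genes (%d unassigned)\n",
              n_mod, length(x$assignment), sum(x$assignment == "grey")))
  if (n_mod) {
    tab <- x$sizes
    names(tab) <- rownames(x$eigengenes)
    print(tab)
  }
  invisible(x)
}

#' Module gene sets from a module assignment
#'
#' @param modules A `module_set`.
#' @param drop_grey Drop the unassigned pseudo-module (default TRUE).
#' @return Named list of gene character vectors.
#' @export
module_gene_sets <- function(modules, drop_grey = TRUE) {
  stopifnot(inherits(modules, "module_set"))
  sets <- split(names(modules$assignment), modules$assignment)
  if (drop_grey) sets$grey <- NULL
  labs <- rownames(modules$eigengenes)
  sets[intersect(labs, names(sets))]
}
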