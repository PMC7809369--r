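#' Fit a parametric empirical-Bayes batch model
#'
#' Fits the classical location-scale batch model: expression is standardised
#' gene-wise around a batch-size-weighted grand mean and pooled variance, raw
#' per-batch location (`gamma`) and scale (`delta^2`) effects are estimated,
#' normal / inverse-gamma priors are moment-matched across genes within each
#' batch, and the conditional posterior means are iterated to convergence.
#' No covariates are modelled. Genes with zero pooled variance are flagged and
#' left unadjusted (they carry no batch information and would divide by zero).
#'
#' @param em An [expression_matrix]; values are expected on the log2 scale.
#' @param batch Either a vector of batch labels aligned to the samples or the
#'   name of a column in `em$samples` (default `"batch"`).
#' @param conv Convergence tolerance on the maximum absolute change of the
#'   posterior estimates (default `1e-4`).
#' @param max_iter Iteration cap (default 500).
#' @return A `batch_model` object holding `alpha` (gene grand means),
#'   `sigma2` (pooled variances), `gamma_star` and `delta2_star`
#'   (batch-by-gene posterior effects), the moment-matched hyperpriors and an
#'   `identity` flag (set for a single batch, in which case adjustment is a
#'   no-op).
#' @export
fit_combat <- function(em, batch = "batch", conv = 1e-4, max_iter = 500L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$log2_scale) {
    warning("fit_combat expects log2-scale values; proceeding anyway")
  }
  batches <- .resolve_batch(em, batch)
  X <- em$values
  levs <- levels(batches)
  n_i <- as.vector(table(batches))
  names(n_i) <- levs
  N <- ncol(X)

  base <- list(batch_levels = levs, batches = batches,
               gene_ids = rownames(X), sample_ids = colnames(X))

  if (length(levs) < 2L) {
    return(structure(c(base, list(identity = TRUE)), class = "batch_model"))
  }
  if (any(n_i < 2L)) {
    stop("every batch needs at least 2 samples; offending batch(es): ",
         paste(levs[n_i < 2L], collapse = ", "))
  }

  # batch means per gene; weighted grand mean; pooled residual variance
  B <- vapply(levs, function(l) rowMeans(X[, batches == l, drop = FALSE]),
              numeric(nrow(X)))                       # genes x batches
  alpha <- as.vector(B %*% (n_i / N))
  fitted <- B[, as.integer(batches), drop = FALSE]
  sigma2 <- rowSums((X - fitted)^2) / N
  constant <- sigma2 <= .Machine$double.eps
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) flagged and left unadjusted")
  }
  s <- sqrt(ifelse(constant, 1, sigma2))
  Z <- (X - alpha) / s

  G <- nrow(X)
  gamma_star <- delta2_star <- matrix(
    NA_real_, length(levs), G, dimnames = list(levs, rownames(X)))
  hyper <- vector("list", length(levs))
  names(hyper) <- levs
  iters <- integer(length(levs))

  for (bi in seq_along(levs)) {
    idx <- which(batches == levs[bi])
    n <- length(idx)
    Zb <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- rowSums((Zb - g_hat)^2) / (n - 1)

    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    if (!is.finite(s2) || s2 < .Machine$double.eps) s2 <- .Machine$double.eps
    if (!is.finite(t2) || t2 < .Machine$double.eps) t2 <- .Machine$double.eps
    lambda <- (2 * s2 + m^2) / s2          # inverse-gamma shape
    theta <- (m * s2 + m^3) / s2           # inverse-gamma rate

    g_old <- g_hat
    d_old <- d_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
      sum2 <- rowSums((Zb - g_new)^2)
      d_new <- (0.5 * sum2 + theta) / (n / 2 + lambda - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < conv || it >= max_iter) break
    }
    gamma_star[bi, ] <- g_old
    delta2_star[bi, ] <- d_old
    hyper[[bi]] <- list(gamma_bar = g_bar, tau2 = t2,
                        lambda = lambda, theta = theta)
    iters[bi] <- it
  }

  structure(c(base, list(
    identity = FALSE, alpha = stats::setNames(alpha, rownames(X)),
    sigma2 = stats::setNames(sigma2, rownames(X)), constant = constant,
    gamma_star = gamma_star, delta2_star = delta2_star,
    hyper = hyper, iterations = iters)), class = "batch_model")
}

.resolve_batch <- function(em, batch) {
  if (length(batch) == 1L && is.character(batch)) {
    if (!batch %in% names(em$samples)) {
      stop("batch column '", batch, "' not found in sample metadata")
    }
    batch <- em$samples[[batch]]
  }
  if (length(batch) != ncol(em$values)) {
    stop("batch labels must align with samples")
  }
  factor(batch)
}

#' Apply a fitted batch model to an expression matrix
#'
#' Back-transforms each sample from the standardised scale after removing its
#' batch's posterior location and scale effect:
#' `X* = sigma * (Z - gamma_star) / sqrt(delta2_star) + alpha`.
#'
#' @param em [expression_matrix] on the same gene/sample universe used for
#'   fitting (gene set must match; samples may be any subset with known batch
#'   labels).
#' @param model A `batch_model` from [fit_combat()].
#' @param batch Batch labels or metadata column name, as in [fit_combat()].
#' @return The adjusted [expression_matrix].
#' @export
adjust_combat <- function(em, model, batch = "batch") {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(model, "batch_model"))
  if (model$identity) return(em)
  if (!identical(rownames(em$values), model$gene_ids)) {
    stop("gene universe differs from the fitted model")
  }
  batches <- .resolve_batch(em, batch)
  unseen <- setdiff(levels(batches), model$batch_levels)
  if (length(unseen)) {
    stop("batch label(s) not seen at fit time: ",
         paste(unseen, collapse = ", "))
  }
  X <- em$values
  s <- sqrt(ifelse(model$constant, 1, model$sigma2))
  Z <- (X - model$alpha) / s
  out <- Z
  for (l in levels(batches)) {
    idx <- which(batches == l)
    g <- model$gamma_star[l, ]
    d <- model$delta2_star[l, ]
    out[, idx] <- (Z[, idx, drop = FALSE] - g) / sqrt(d)
  }
  out <- out * s + model$alpha
  out[model$constant, ] <- X[model$constant, , drop = FALSE]
  expression_matrix(out, samples = em$samples, log2_scale = em$log2_scale)
}

#' @export
print.batch_model <- function(x, ...) {
  if (x$identity) {
    cat("batch_model: single batch (identity adjustment)\n")
  } else {
    cat(sprintf("batch_model: %d batches x %d genes (EB, parametric)\n",
                length(x$batch_levels), length(x$gene_ids)))
  }
  invisible(x)
}
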