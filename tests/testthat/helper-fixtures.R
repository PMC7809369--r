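# shared fixture builders and independent oracles

make_em <- function(values, samples = NULL, log2_scale = TRUE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  expression_matrix(values, samples = samples, log2_scale = log2_scale)
}

# brute-force O(n^3) topological overlap oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  d <- a
  diag(d) <- 0
  w <- diag(n)
  k <- rowSums(d)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + d[i, u] * d[u, j]
    w[i, j] <- (l + d[i, j]) / (min(k[i], k[j]) + 1 - d[i, j])
  }
  w
}

# recovery-curve enumeration oracle for the ranking-recovery AUC
auc_oracle <- function(ranks_of_set, N, top_frac) {
  T_ <- max(1L, ceiling(top_frac * N))
  rec <- vapply(seq_len(T_), function(x) sum(ranks_of_set <= x), numeric(1))
  sum(rec) / (T_ * length(ranks_of_set))
}

# exact two-sided rank-sum p by full enumeration of rank assignments
wilcox_exact_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  centre <- n * m / 2
  mean(abs(ws - centre) >= abs(w_obs - centre) - 1e-9)
}

# exact upper hypergeometric tail by direct summation of choose() terms
hyper_tail_oracle <- function(hits, n_ann, n_mod, n_bg) {
  xs <- hits:min(n_ann, n_mod)
  sum(choose(n_ann, xs) * choose(n_bg - n_ann, n_mod - xs)) /
    choose(n_bg, n_mod)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
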