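# Independent brute-force oracles. These deliberately use plain double
# loops / exhaustive enumeration, not the package's vectorized code paths.

# Minimum PAE over all inter-chain cells, by explicit double loop.
bf_min_inter_pae <- function(pae, len_a, len_b) {
  best <- Inf
  chain_of <- rep(c(1L, 2L), c(len_a, len_b))
  for (i in seq_len(nrow(pae))) {
    for (j in seq_len(ncol(pae))) {
      if (chain_of[i] != chain_of[j] && pae[i, j] < best) best <- pae[i, j]
    }
  }
  best
}

# Per-residue minimum inter-chain PAE for the second chain, double loop.
bf_profile_chain2 <- function(pae, len_a, len_b) {
  out <- numeric(len_b)
  for (r in seq_len(len_b)) {
    i <- len_a + r
    best <- Inf
    for (j in seq_len(len_a)) {
      best <- min(best, pae[i, j], pae[j, i])
    }
    out[r] <- best
  }
  out
}

# ROC AUC by exhaustive pair counting: concordant + half-credit ties,
# over all (pos, neg) pairs; `higher` scores rank better here.
bf_auc_pairs <- function(pos, neg) {
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# TPR at FDR = 0 by direct counting against the best negative (strict).
bf_tpr0 <- function(pos, neg) {
  best_neg <- max(neg)
  100 * sum(pos > best_neg) / length(pos)
}

# PR-AUC by explicit confusion counting at every distinct threshold
# (higher scores rank better), trapezoid over recall with the conventional
# (0, 1) starting point.
bf_pr_auc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  recall <- 0
  precision <- 1
  for (t in thr) {
    tp <- sum(pos >= t)
    fp <- sum(neg >= t)
    recall <- c(recall, tp / length(pos))
    precision <- c(precision, tp / (tp + fp))
  }
  sum(diff(recall) * (precision[-1] + precision[-length(precision)]) / 2)
}

# Maximal contiguous run around the arg-min whose values are <= min + delta.
bf_band_run <- function(v, delta) {
  a <- which.min(v)
  lo <- min(v) + delta
  s <- a
  while (s > 1L && v[s - 1L] <= lo) s <- s - 1L
  e <- a
  while (e < length(v) && v[e + 1L] <= lo) e <- e + 1L
  c(start = s, end = e, anchor = a)
}

# A record with a fully specified PAE matrix (no file round-trip).
record_from_pae <- function(pae, len_a, len_b, ptm = 0.5, iptm = 0.5,
                            plddt = NULL, id = "inmem") {
  prediction_record(
    record_id = id,
    partition = chain_partition(c("A", "B"), c(len_a, len_b)),
    pae = pae,
    plddt = plddt %||% rep(50, len_a + len_b),
    ptm = ptm, iptm = iptm,
    max_pae = max(31.75, max(pae))
  )
}

random_two_chain_pae <- function(len_a, len_b) {
  L <- len_a + len_b
  matrix(round(runif(L * L, 0.2, 31.75), 3), L, L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
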