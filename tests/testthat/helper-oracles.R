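# Independent brute-force oracles used by both the module tests and the
# acceptance checks. These deliberately share no code with the package.

# O(n^2) pairwise AUC: wins + half ties over all presence/absence pairs.
oracle_auc_pairwise <- function(p, a) {
  (sum(outer(p, a, ">")) + 0.5 * sum(outer(p, a, "=="))) /
    (length(p) * length(a))
}

# Exhaustive threshold scan for the max(sensitivity + specificity) objective
# under the rule "suitable iff score >= t".
oracle_maxsss_scan <- function(p, a) {
  cands <- sort(unique(c(-Inf, Inf, p, a,
                         (sort(unique(c(p, a)))[-1] +
                            head(sort(unique(c(p, a))), -1)) / 2)))
  best <- -Inf
  for (t in cands) {
    v <- mean(p >= t) + mean(a < t)
    if (v > best) best <- v
  }
  best
}

# Occupied environmental-cell count by direct enumeration.
oracle_occupied_cells <- function(m, widths) {
  bins <- sapply(seq_len(ncol(m)), function(j)
    floor((m[, j] - min(m[, j])) / widths[j]))
  if (nrow(m) == 1) bins <- matrix(bins, nrow = 1)
  nrow(unique(as.data.frame(bins)))
}

# Plain sort-and-count implementation of the envelope percentile score.
oracle_bioclim_score <- function(x, calib) {
  point_score <- function(row) {
    min(sapply(names(calib), function(v) {
      vv <- calib[[v]]
      n <- length(vv)
      if (row[[v]] < min(vv) || row[[v]] > max(vv)) return(0)
      f <- (sum(vv < row[[v]]) + 0.5 * sum(vv == row[[v]]) + 0.5) / (n + 1)
      min(max(2 * min(f, 1 - f), 0), 1)
    }))
  }
  apply(x, 1, function(r) point_score(as.list(r)))
}
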