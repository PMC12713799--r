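# independent brute-force oracles and small fixture builders

# BH step-up by its definition: min over the tail of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- vapply(seq_len(m), function(k) {
    min(1, min(sorted[k:m] * m / (k:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Pearson chi-square by exhaustive cell-by-cell summation
pearson_chi2_oracle <- function(observed, expected) {
  sum((observed - expected)^2 / expected)
}

chi2_gof_oracle <- function(k, n, p0) {
  pearson_chi2_oracle(c(k, n - k), c(n * p0, n * (1 - p0)))
}

chi2_2x2_oracle <- function(k1, n1, k2, n2) {
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pearson_chi2_oracle(tab, expected)
}

# partial correlation of columns i and j by regressing out all others
pcor_residual_oracle <- function(data, i, j) {
  others <- setdiff(seq_len(ncol(data)), c(i, j))
  d <- as.data.frame(data)
  names(d) <- paste0("v", seq_len(ncol(d)))
  rhs <- if (length(others)) paste(names(d)[others], collapse = " + ") else "1"
  ri <- stats::resid(stats::lm(stats::as.formula(paste(names(d)[i], "~", rhs)), d))
  rj <- stats::resid(stats::lm(stats::as.formula(paste(names(d)[j], "~", rhs)), d))
  stats::cor(ri, rj)
}

# match estimated factors to planted ones by max absolute congruence,
# then fix signs
align_loadings <- function(est, truth) {
  k <- ncol(truth)
  perm <- integer(k)
  cong <- abs(t(est) %*% truth)
  for (j in seq_len(k)) {
    perm[j] <- which.max(cong[, j])
    cong[perm[j], ] <- -Inf
  }
  A <- est[, perm, drop = FALSE]
  for (j in seq_len(k)) {
    if (sum(A[, j] * truth[, j]) < 0) A[, j] <- -A[, j]
  }
  A
}

# minimal valid probe table: one row per participant x condition
make_probes <- function(hyp_items, fmt_items,
                        hyp_int = NULL, fmt_int = NULL,
                        hyp_temp = NULL, fmt_temp = NULL) {
  n <- nrow(hyp_items)
  default_int <- rep(c("deliberate", "spontaneous"), length.out = n)
  default_temp <- rep(c("past", "present", "future", "none"), length.out = n)
  build <- function(items, cond, int, temp) {
    df <- as.data.frame(items)
    names(df) <- probe_items()
    cbind(data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                     condition = cond),
          df,
          data.frame(intentionality = int %||% default_int,
                     temporality = temp %||% default_temp))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  rbind(build(hyp_items, "hypnagogia", hyp_int, hyp_temp),
        build(fmt_items, "fmt", fmt_int, fmt_temp))
}

random_likert <- function(n, seed) {
  set.seed(seed)
  matrix(sample(1:5, n * 11, replace = TRUE), n, 11)
}

# annotations for a cohort given per-row cued counts (single condition)
make_annotations <- function(direct_cued, indirect_cued,
                             cue = "Tree", condition = "hypnagogia",
                             rater = "R1",
                             direct_uncued = 0, indirect_uncued = 0) {
  n <- length(direct_cued)
  direct_cued <- as.integer(direct_cued)
  indirect_cued <- as.integer(indirect_cued)
  direct_uncued <- as.integer(rep_len(direct_uncued, n))
  indirect_uncued <- as.integer(rep_len(indirect_uncued, n))
  tree <- cue == "Tree"
  data.frame(
    rater_id = rater,
    participant_id = sprintf("P%03d", seq_len(n)),
    condition = condition,
    cue_object = cue,
    direct_fork = if (tree) direct_uncued else direct_cued,
    indirect_fork = if (tree) indirect_uncued else indirect_cued,
    direct_tree = if (tree) direct_cued else direct_uncued,
    indirect_tree = if (tree) indirect_cued else indirect_uncued)
}
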