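# Independent brute-force oracles used to check the statistical kernels.
# These deliberately avoid the code paths (and library calls) they verify.

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample (no ties assumed).
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  # two-sided: double the smaller tail (U symmetric about n1*n2/2)
  lo <- min(u_obs, n1 * n2 - u_obs)
  min(1, 2 * mean(u_all <= lo))
}

# Two-sided Fisher exact p by summing hypergeometric probabilities no
# larger than the observed table's (with base R's relative tolerance).
fisher_enumeration_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square statistic by the direct (O - E)^2 / E sum.
chisq_direct_stat <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expected)^2 / expected)
}

# Fine-grid midpoint Riemann sum of the piecewise-linear interpolant,
# with cell boundaries aligned to the knots so each cell is linear.
riemann_auc <- function(times, means, n_per_segment = 1000) {
  total <- 0
  for (i in seq_len(length(times) - 1)) {
    h <- (times[i + 1] - times[i]) / n_per_segment
    mids <- times[i] + (seq_len(n_per_segment) - 0.5) * h
    total <- total + sum(stats::approx(times, means, xout = mids)$y) * h
  }
  total
}

# Sorted "a|b" edge keys of every pair at or above the threshold,
# by an explicit double loop.
edges_double_loop <- function(corr, threshold, absolute = FALSE) {
  nodes <- colnames(corr)
  out <- character(0)
  for (i in seq_len(ncol(corr) - 1)) {
    for (j in (i + 1):ncol(corr)) {
      r <- corr[i, j]
      if (is.na(r)) next
      if ((absolute && abs(r) >= threshold) || (!absolute && r >= threshold))
        out <- c(out, paste(nodes[i], nodes[j], sep = "|"))
    }
  }
  sort(out)
}

# Small cohort config shared across tests (missingness off so counting
# arguments are exact).
small_config <- function(seed = 42, ...) {
  simulation_config(n_per_group = c(10, 12), missing_prob = 0,
                    seed = seed, ...)
}
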