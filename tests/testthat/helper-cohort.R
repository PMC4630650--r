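# Shared fixture builders. Everything is generated in code at test time.

# A small, fast cohort: few subjects/metabolites, deterministic seed.
tiny_spec <- function(n_subjects = 6, n_metabolites = 8, seed = 11, ...) {
  cohort_spec(n_subjects = n_subjects, n_metabolites = n_metabolites,
              seed = seed, ...)
}

tiny_processed <- function(spec = tiny_spec()) {
  autoscale(log10_transform(normalize_to_pool(generate_cohort(spec))))
}

# Hand-rolled BH step-up, the independent oracle for bh_adjust().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force tie-corrected Kendall tau-b over all subject pairs.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- choose(n, 2)
  tx <- sum(choose(table(x), 2))
  ty <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
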