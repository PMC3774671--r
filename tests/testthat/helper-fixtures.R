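# Shared fixture builders; everything is generated in code under fixed seeds.

# Two-population unadmixed cohort from Balding-Nichols panels.
make_two_pops <- function(n1 = 30, n2 = 30, m = 2000, fst = 0.1, seed = 1,
                          F_true = 0) {
  pan <- simulate_panel(m, 2, c(fst, fst), seed = seed)
  Q <- rbind(matrix(c(1, 0), n1, 2, byrow = TRUE),
             matrix(c(0, 1), n2, 2, byrow = TRUE))
  sim <- simulate_genotypes(pan, Q, F_true, seed = seed + 1)
  list(g1 = sim$genotypes[seq_len(n1), , drop = FALSE],
       g2 = sim$genotypes[n1 + seq_len(n2), , drop = FALSE],
       sim = sim, panel = pan)
}

# K unadmixed populations (one-hot Q), equal sizes.
make_k_pops <- function(K = 3, n_per = 30, m = 800, fst = 0.1, seed = 1) {
  pan <- simulate_panel(m, K, rep(fst, K), seed = seed)
  Q <- diag(K)[rep(seq_len(K), each = n_per), , drop = FALSE]
  sim <- simulate_genotypes(pan, Q, 0, seed = seed + 1)
  list(g = sim$genotypes, Q_true = Q, panel = pan,
       pop = rep(seq_len(K), each = n_per))
}

# Exact-test HWE oracle via the heterozygote-count recurrence
# P(h+2)/P(h) = 4 nAA(h) naa(h) / ((h+2)(h+1)); independent of the
# lgamma-based implementation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  h <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- numeric(length(h))
  pr[1] <- 1
  if (length(h) > 1) {
    for (i in seq_len(length(h) - 1)) {
      hc <- h[i]
      nAAc <- (nA - hc) / 2
      naac <- (na - hc) / 2
      pr[i + 1] <- pr[i] * 4 * nAAc * naac / ((hc + 2) * (hc + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}
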