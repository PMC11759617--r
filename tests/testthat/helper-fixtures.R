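# Small fixture builders shared across test files.

# GenotypeData from a plain dosage matrix (variants x samples)
gd <- function(m, samples = NULL) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  storage.mode(m) <- "integer"
  GenotypeData(m, samples = samples)
}

# single-population cohort: m variants, n samples, allele freq p
sim_pop <- function(m, n, p = 0.3, fst = 0, seed = 1, missing_rate = 0) {
  panel <- drawAncestralFrequencies(m, 1, fst, base_freqs = rep(p, m),
                                    seed = seed)
  adm <- drawAdmixture(n, 1, seed = seed + 1)
  simulateGenotypes(panel, adm, missing_rate = missing_rate,
                    seed = seed + 2)
}

# two-population structured cohort plus its admixture spec
sim_structured <- function(m, n, alpha = c(1, 1), fst = 0.15, seed = 1) {
  k <- length(alpha)
  panel <- drawAncestralFrequencies(m, k, fst, seed = seed)
  adm <- drawAdmixture(n, alpha, seed = seed + 1)
  list(g = simulateGenotypes(panel, adm, seed = seed + 2),
       panel = panel, adm = adm)
}

# independent full-enumeration HWE distribution over heterozygote counts
# for a class of tables sharing (n genotypes, nA copies of allele A),
# computed directly from log-factorials
hwe_class_oracle <- function(n, nA) {
  na <- 2 * n - nA
  nr <- min(nA, na)
  hets <- seq.int(nr %% 2, nr, by = 2)
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  list(hets = hets, prob = p)
}

# oracle mid-p for one table, from the class distribution
hwe_midp_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (min(nA, 2 * n - nA) == 0) return(1)
  cl <- hwe_class_oracle(n, nA)
  obs <- cl$prob[match(n_Aa, cl$hets)]
  min(1, sum(cl$prob[cl$prob < obs * (1 - 1e-12)]) +
        0.5 * sum(cl$prob[abs(cl$prob - obs) <= obs * 1e-12]))
}
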