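# Independent oracles and small fixture builders used across the suite.

# Exhaustive-enumeration oracle for the probability that at least k of n
# masses match by chance: sums outcome probabilities over all 2^n
# match/no-match configurations, independently of any distribution code.
enum_tail_prob <- function(k, n, p) {
  if (n == 0L) return(if (k <= 0) 1 else 0)
  counts <- vapply(0:(2^n - 1), function(code) {
    sum(bitwAnd(code, bitwShiftL(1L, 0:(n - 1))) != 0L)
  }, integer(1))
  sum(p^counts * (1 - p)^(n - counts) * (counts >= k))
}

# Independently typed element masses (different source transcription than
# the package tables) for recomputing residue/adduct masses.
oracle_element_mass <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                         O = 15.9949146196, S = 31.97207100)
oracle_element_avg <- c(C = 12.011, H = 1.008, N = 14.007,
                        O = 15.999, S = 32.06)

oracle_formula_mass <- function(formula, masses = oracle_element_mass) {
  m <- regmatches(formula, gregexpr("([A-Z])(-?[0-9]*)", formula))[[1]]
  elem <- sub("([A-Z])(-?[0-9]*)", "\\1", m)
  cnt <- sub("([A-Z])(-?[0-9]*)", "\\2", m)
  cnt[cnt == ""] <- "1"
  sum(masses[elem] * as.integer(cnt))
}

# A random centroided MS2 spectrum for round-trip property tests.
random_ms2_spectrum <- function(id, n_peaks = 25L) {
  mz <- sort(runif(n_peaks, 100, 2000))
  ms_spectrum(id, 2L,
              data.frame(mz = mz, intensity = runif(n_peaks, 1, 1e5)),
              precursor_mz = runif(1, 300, 1200),
              precursor_charge = sample(1:3, 1),
              retention_time = runif(1, 0, 3600))
}
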