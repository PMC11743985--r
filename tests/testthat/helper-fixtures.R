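# Fixtures are built in code: small record tables, hand-made spectra, and
# independent brute-force oracles used to cross-check the implementation.

make_es_records <- function(responses, subject_id = "s1") {
  data.frame(subject_id = subject_id, trial = seq_along(responses),
             response = responses, stringsAsFactors = FALSE)
}

# NI trial table with exact per-condition values in the analysis blocks
make_ni_records <- function(pain_rts, nopain_rts, subject_id = "s1") {
  rbind(
    data.frame(subject_id = subject_id, block = 3L, condition = "no_pain",
               rt_ms = nopain_rts, stringsAsFactors = FALSE),
    data.frame(subject_id = subject_id, block = 4L, condition = "pain",
               rt_ms = pain_rts, stringsAsFactors = FALSE))
}

# Hand-built power_spectrum object (uniform grid) for AUC / PAF unit tests
make_spectrum <- function(freq, power, fs = 1000) {
  structure(list(freq = freq, power = power, fs = fs,
                 config = welch_config(), n_segments = 1L,
                 normalized_input = TRUE),
            class = "power_spectrum")
}

# Brute-force Mann-Whitney U: pair counting with ties worth one half
brute_force_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Brute-force Spearman rho: Pearson correlation of mid-ranks
brute_force_spearman <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

# Trapezoid-rule AUC oracle over [f_lo, f_hi] (closed band)
trapezoid_auc <- function(spectrum, f_lo, f_hi) {
  df <- spectrum$freq[2] - spectrum$freq[1]
  idx <- which(spectrum$freq >= f_lo - 1e-9 & spectrum$freq <= f_hi + 1e-9)
  p <- spectrum$power[idx]
  sum((p[-length(p)] + p[-1]) / 2) * df
}

# Per-trial weights evaluation of the IAP score (independent of the
# count-based implementation)
brute_force_iap <- function(responses) {
  w <- c(only_pain = 2, mostly_pain = 1, mostly_else = -1, only_else = -2)
  mean(w[responses])
}
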