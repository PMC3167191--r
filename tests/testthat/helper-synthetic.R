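# Shared fixtures built in code: small cohorts, deterministic records, and a
# degenerate (noise-free) cohort spec used across test files.

# cohort with all randomness switched off: matrices equal class profiles
noise_free_spec <- function(n = 10, seed = 1) {
  cohort_spec(n_subjects = n, prevalence_excess = 0.5,
              factor_sd = 0, noise_sd = 0, seed = seed)
}

default_features <- function(seed = 1, n = 70) {
  co <- simulate_amplitude_cohort(cohort_spec(n_subjects = n, seed = seed))
  feature_table(co$matrices, co$labels)
}

# noise-free waveform spec: clean periodic beat train
clean_waveform_spec <- function(seed = 1, ...) {
  waveform_spec(wander_amplitude = 0, spike_rate = 0, seed = seed, ...)
}

# single-variable LOOCV helpers for threshold rules
single_rule_fit <- function(X, y) fit_threshold_single(X[, 1], y)
single_rule_predict <- function(m, nd) ifelse(nd[, 1] >= m$alpha, "excess", "deficient")
mixed_rule_fit <- function(X, y) fit_thresholds(X[, 1], X[, 2], y)
mixed_rule_predict <- function(m, nd) classify_mixed(nd[, 1], nd[, 2], m)
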