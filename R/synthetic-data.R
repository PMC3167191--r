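# Synthetic two-class pulse cohorts with known ground truth: amplitude-level
# cohorts with a latent block-factor correlation structure, and waveform-level
# records with baseline wander and motion spikes, so the whole analysis chain
# is testable without clinical data.

#' Hold-down pressure protocol
#'
#' The five stepped hold-down pressures of the acquisition protocol, each
#' held constant while a record is taken. Defaults are the mean (and SD) of
#' the protocol's steps: 37 +/- 4, 73 +/- 5, 109 +/- 5, 143 +/- 7 and
#' 184 +/- 7 mmHg, held for 5 s each.
#'
#' @param step_means five strictly increasing positive pressures (mmHg).
#' @param step_sds five positive SDs (mmHg).
#' @param hold_seconds hold duration per step (s).
#' @return a `pressure_protocol`.
#' @export
pressure_protocol <- function(step_means = c(37, 73, 109, 143, 184),
                              step_sds = c(4, 5, 5, 7, 7),
                              hold_seconds = 5) {
  stopifnot(length(step_means) == 5L, length(step_sds) == 5L,
            all(step_means > 0), all(step_sds > 0), hold_seconds > 0)
  if (any(diff(step_means) <= 0))
    stop("pressure steps must be strictly increasing")
  structure(list(step_means = step_means, step_sds = step_sds,
                 hold_seconds = hold_seconds),
            class = "pressure_protocol")
}

#' Default class-mean amplitude surfaces
#'
#' 3x5 mean surfaces (arb units; rows = Chon, Gwan, Cheok, columns =
#' pressure steps 1..5). Both classes peak at mid pressures (the artery
#' flattens, then occludes under heavy pressure); Chon peaks shallower than
#' Gwan/Cheok. The excess surface is a uniform upward shift of the deficient
#' one, so the class separation concentrates in the pulse-force summaries.
#' The default shift of 0.6 arb is calibrated so a single standardized
#' summary separates the classes at roughly 75% training accuracy under the
#' default noise — the moderate-concordance regime the classifier is meant
#' to operate in.
#'
#' @param separation uniform excess-minus-deficient shift (arb).
#' @return list with `deficient` and `excess` 3x5 matrices.
#' @export
default_class_profiles <- function(separation = 0.6) {
  deficient <- rbind(Chon  = c(5.5, 7.5, 7.0, 5.0, 3.0),
                     Gwan  = c(6.0, 8.5, 10.0, 9.0, 6.5),
                     Cheok = c(5.0, 7.5, 9.5, 10.0, 8.0))
  list(deficient = deficient, excess = deficient + separation)
}

#' Default latent block structure of the 15 amplitudes
#'
#' Five latent blocks mirroring the factor grouping seen in clinical
#' amplitude data: Cheok at heavy pressures, light-pressure amplitudes at
#' Gwan/Cheok, and the remaining per-position heavy/light groups. Cells in
#' a block share one latent factor, producing within-block correlation.
#'
#' @param loading factor loading applied to every cell of each block (arb).
#' @return list of blocks, each `list(name, cells, loading)`.
#' @export
default_factor_structure <- function(loading = 1) {
  cell <- function(i, j) cbind(i, j)
  list(
    list(name = "cheok_heavy", cells = cell(3, 3:5), loading = loading),
    list(name = "light_pressure", cells = rbind(cell(2, 1:2), cell(3, 1:2)), loading = loading),
    list(name = "chon_heavy", cells = cell(1, 3:5), loading = loading),
    list(name = "gwan_heavy", cells = cell(2, 3:5), loading = loading),
    list(name = "chon_light", cells = cell(1, 1:2), loading = loading)
  )
}

#' Specification of a synthetic amplitude cohort
#'
#' Defines a two-class cohort of 3x5 amplitude matrices. Each subject's
#' matrix is its class-mean surface plus block-correlated latent-factor
#' displacements plus independent Gaussian noise, truncated at 0. The
#' default calibration mirrors the clinical study's scale: n = 70 with
#' excess prevalence 44/70, five latent blocks grouping Cheok amplitudes,
#' light-pressure amplitudes, and the heavy-pressure amplitudes per
#' position, and class separation concentrated in the pulse-force
#' summaries.
#'
#' @param n_subjects cohort size.
#' @param prevalence_excess fraction of excess subjects in (0, 1).
#' @param class_profiles list with `deficient` and `excess` 3x5 non-negative
#'   mean surfaces (arb).
#' @param factor_structure list of blocks, each `list(name, cells, loading)`
#'   where `cells` is a 2-column (position, step) matrix; every cell must
#'   belong to exactly one block.
#' @param factor_sd SD of each latent block factor (arb).
#' @param noise_sd SD of the independent within-class noise (arb).
#' @param seed root seed; per-subject streams are derived by a counter so a
#'   subject's draw does not depend on cohort size.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 70L,
                        prevalence_excess = 44 / 70,
                        class_profiles = default_class_profiles(),
                        factor_structure = default_factor_structure(),
                        factor_sd = 1,
                        noise_sd = 0.5,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, prevalence_excess > 0, prevalence_excess < 1,
            factor_sd >= 0, noise_sd >= 0)
  for (cls in c("deficient", "excess")) {
    pr <- class_profiles[[cls]]
    if (is.null(pr) || !all(dim(as.matrix(pr)) == c(3L, 5L)))
      stop("class profile '", cls, "' must be a 3x5 matrix")
    if (any(pr < 0)) stop("class profile '", cls, "' has negative entries")
  }
  seen <- matrix(FALSE, 3L, 5L)
  for (b in factor_structure) {
    cells <- as.matrix(b$cells)
    if (ncol(cells) != 2L || any(cells[, 1] < 1 | cells[, 1] > 3) ||
        any(cells[, 2] < 1 | cells[, 2] > 5))
      stop("block '", b$name, "' has invalid (position, step) cells")
    if (any(seen[cells]))
      stop("block '", b$name, "' overlaps another block; ",
         "cells must partition the 3x5 grid")
    seen[cells] <- TRUE
    if (b$loading < 0) stop("block '", b$name, "' has negative loading")
  }
  spec <- structure(list(n_subjects = as.integer(n_subjects),
                         prevalence_excess = prevalence_excess,
                         class_profiles = lapply(class_profiles, as.matrix),
                         factor_structure = factor_structure,
                         factor_sd = factor_sd, noise_sd = noise_sd,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_correlation(spec)
  spec
}

# The implied 15x15 amplitude covariance must be positive definite whenever
# any randomness is present; with block loadings lambda and noise sd the
# covariance is block diagonal with lambda^2 * factor_sd^2 * J + noise^2 * I,
# singular iff noise_sd = 0 on a multi-cell block (reported per block).
validate_cohort_correlation <- function(spec) {
  if (spec$noise_sd > 0) return(invisible(TRUE))
  for (b in spec$factor_structure) {
    if (nrow(as.matrix(b$cells)) > 1L && b$loading > 0 && spec$factor_sd > 0)
      stop("correlation specification is not positive definite: block '",
           b$name, "' has perfectly correlated cells (noise_sd = 0 with a ",
           "shared factor); increase noise_sd or drop the block loading")
  }
  invisible(TRUE)
}

# Per-subject RNG stream derived from the root seed and a subject counter,
# independent of cohort size (subject k draws identically in any cohort).
subject_seed <- function(root, counter) {
  as.integer((as.numeric(root) * 100003 + counter * 7919) %% 2147483647)
}

#' Simulate an amplitude-level cohort
#'
#' Draws per-subject class labels (fixed class counts: `round(n *
#' prevalence_excess)` excess subjects, interleaved deterministically), then
#' for each subject a 3x5 amplitude matrix: class-mean surface + latent
#' block factors + independent Gaussian noise, truncated at 0. Bit-identical
#' under a fixed seed; subject-level streams make any subject's draw
#' reproducible under cohort subsetting.
#'
#' @param spec a [cohort_spec()].
#' @return list with `labels` (character vector) and `matrices` (list of
#'   [amplitude_matrix()]); ground-truth latent factors are attached as
#'   `attr(, "factors")`.
#' @export
simulate_amplitude_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_exc <- round(n * spec$prevalence_excess)
  labels <- rep("deficient", n)
  if (n_exc > 0) {
    # deterministic interleaving so any prefix of the cohort is two-class
    pos <- unique(round(seq(1, n, length.out = n_exc)))
    labels[pos] <- "excess"
    while (sum(labels == "excess") < n_exc)
      labels[which(labels == "deficient")[1]] <- "excess"
  }
  blocks <- spec$factor_structure
  fac <- matrix(NA_real_, n, length(blocks),
                dimnames = list(NULL, vapply(blocks, `[[`, "", "name")))
  matrices <- vector("list", n)
  for (s in seq_len(n)) {
    rs <- subject_seed(spec$seed, s)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(rs)
    f <- stats::rnorm(length(blocks), 0, spec$factor_sd)
    eps <- matrix(stats::rnorm(15, 0, spec$noise_sd), 3L, 5L)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    H <- spec$class_profiles[[labels[s]]]
    for (b in seq_along(blocks)) {
      cells <- as.matrix(blocks[[b]]$cells)
      H[cells] <- H[cells] + blocks[[b]]$loading * f[b]
    }
    H <- pmax(H + eps, 0)
    fac[s, ] <- f
    matrices[[s]] <- amplitude_matrix(H, subject_id = sprintf("S%03d", s))
  }
  structure(list(labels = labels, matrices = matrices), factors = fac)
}

#' Specification of a synthetic waveform record
#'
#' Controls the waveform-level generator: a smooth periodic beat template
#' (two asymmetric Gaussian lobes, systolic peak plus dicrotic wave),
#' sinusoidal baseline wander emulating respiration, and single-sample
#' motion spikes. Defaults: 200 Hz sampling, 72 beats/min, systolic peak at
#' 30% of the beat with a dicrotic wave at 65% of 30% relative height,
#' wander of 2 arb at 0.25 Hz (a breathing rate of 15/min), and on average
#' 1 motion spike per record.
#'
#' @param sampling_rate Hz, >= 100.
#' @param heart_rate beats/min, in (30, 200).
#' @param peak_time_frac systolic-peak position as a fraction of the beat.
#' @param peak_width_frac systolic Gaussian SD as a fraction of the beat.
#' @param dicrotic_rel_height dicrotic lobe height relative to systolic.
#' @param dicrotic_time_frac,dicrotic_width_frac dicrotic lobe position and
#'   SD as fractions of the beat.
#' @param wander_amplitude baseline-wander amplitude (arb).
#' @param wander_freq baseline-wander frequency (Hz).
#' @param spike_rate expected motion spikes per record (Poisson).
#' @param spike_height spike excursion in multiples of the beat amplitude.
#' @param seed integer seed for this record's noise.
#' @return a `waveform_spec`.
#' @export
waveform_spec <- function(sampling_rate = 200, heart_rate = 72,
                          peak_time_frac = 0.30, peak_width_frac = 0.13,
                          dicrotic_rel_height = 0.30,
                          dicrotic_time_frac = 0.65, dicrotic_width_frac = 0.16,
                          wander_amplitude = 2, wander_freq = 0.25,
                          spike_rate = 1, spike_height = 10,
                          seed = 1L) {
  stopifnot(sampling_rate >= 100, heart_rate > 30, heart_rate < 200,
            spike_rate >= 0, wander_amplitude >= 0, wander_freq > 0,
            peak_time_frac > 0, peak_time_frac < 1,
            dicrotic_rel_height >= 0, dicrotic_rel_height < 1)
  structure(as.list(environment()), class = "waveform_spec")
}

# beat template on a unit period: two Gaussian lobes, normalized on a dense
# grid so (max - min) = 1 and min = 0
beat_template <- function(spec) {
  g <- function(u, c, w) exp(-(u - c)^2 / (2 * w^2))
  f <- function(u) {
    # wrap neighbouring periods so the template is exactly periodic
    v <- 0
    for (sh in -1:1) {
      v <- v + g(u + sh, spec$peak_time_frac, spec$peak_width_frac) +
        spec$dicrotic_rel_height *
          g(u + sh, spec$dicrotic_time_frac, spec$dicrotic_width_frac)
    }
    v
  }
  dense <- f(seq(0, 1, length.out = 4001L)[-4001L])
  lo <- min(dense); hi <- max(dense)
  list(f = function(u) (f(u) - lo) / (hi - lo), lo = lo, hi = hi)
}

#' Simulate one pulse waveform record
#'
#' A periodic beat train with foot-to-peak excursion `true_amplitude`, plus
#' sinusoidal baseline wander and Poisson-placed single-sample motion
#' spikes. Ground truth is kept in `meta`: `true_amplitude`, `n_spikes`,
#' `spike_index`, `heart_rate`.
#'
#' @param spec a [waveform_spec()].
#' @param protocol a [pressure_protocol()] (sets the record duration).
#' @param true_amplitude foot-to-peak beat excursion (arb), >= 0.
#' @param position_index,step_index indices stored on the record.
#' @return a [pulse_record()] of duration `protocol$hold_seconds`.
#' @export
simulate_pulse_record <- function(spec, protocol, true_amplitude,
                                  position_index = 1L, step_index = 1L) {
  stopifnot(inherits(spec, "waveform_spec"), inherits(protocol, "pressure_protocol"),
            true_amplitude >= 0)
  period <- 60 / spec$heart_rate
  if (spec$sampling_rate * period < 20)
    stop("sampling too coarse: fewer than 20 samples per beat")
  t <- seq(0, protocol$hold_seconds, by = 1 / spec$sampling_rate)
  t <- t[t < protocol$hold_seconds]
  tpl <- beat_template(spec)
  signal <- true_amplitude * tpl$f((t / period) %% 1)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  phase <- stats::runif(1, 0, 2 * pi)
  if (spec$wander_amplitude > 0)
    signal <- signal + spec$wander_amplitude *
      sin(2 * pi * spec$wander_freq * t + phase)
  n_spikes <- stats::rpois(1, spec$spike_rate)
  spike_index <- integer(0)
  if (n_spikes > 0) {
    spike_index <- sort(sample(seq_along(t), n_spikes))
    signal[spike_index] <- signal[spike_index] +
      spec$spike_height * max(true_amplitude, 1) *
      sample(c(-1, 1), n_spikes, replace = TRUE)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  pulse_record(t, signal, position_index, step_index,
               applied_pressure = protocol$step_means[step_index],
               meta = list(true_amplitude = true_amplitude,
                           n_spikes = n_spikes, spike_index = spike_index,
                           heart_rate = spec$heart_rate))
}

#' Simulate all 15 waveform records for one subject
#'
#' One record per (position, step) cell, with per-cell true amplitudes taken
#' from an [amplitude_matrix()] and per-record seeds derived from the
#' waveform spec's seed.
#'
#' @param spec a [waveform_spec()]; its `seed` is the subject-level root.
#' @param protocol a [pressure_protocol()].
#' @param truth an [amplitude_matrix()] of per-cell true amplitudes.
#' @return list of 15 [pulse_record()]s.
#' @export
simulate_subject_records <- function(spec, protocol, truth) {
  stopifnot(inherits(truth, "amplitude_matrix"))
  records <- vector("list", 15L)
  k <- 0L
  for (i in 1:3) for (j in 1:5) {
    k <- k + 1L
    rspec <- spec
    rspec$seed <- subject_seed(spec$seed, k)
    records[[k]] <- simulate_pulse_record(rspec, protocol, truth$H[i, j],
                                          position_index = i, step_index = j)
  }
  records
}

#' Write / read an amplitude cohort as CSV
#'
#' One row per subject: `subject_id,label,H11..H35` (position-major,
#' pressure-minor).
#'
#' @param cohort result of [simulate_amplitude_cohort()] (or a compatible
#'   list with `labels` and `matrices`).
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a list with `labels` and `matrices`.
#' @export
write_cohort_csv <- function(cohort, path) {
  rows <- t(vapply(cohort$matrices, function(m) as.vector(t(m$H)), numeric(15)))
  colnames(rows) <- H_COLUMNS
  d <- cbind(data.frame(subject_id = vapply(cohort$matrices, `[[`, "", "subject_id"),
                        label = cohort$labels, stringsAsFactors = FALSE),
             rows)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", H_COLUMNS)
  if (!all(need %in% names(d)))
    stop("cohort CSV is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  matrices <- lapply(seq_len(nrow(d)), function(r)
    amplitude_matrix(matrix(as.numeric(d[r, H_COLUMNS]), 3L, 5L, byrow = TRUE),
                     subject_id = d$subject_id[r]))
  list(labels = d$label, matrices = matrices)
}
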