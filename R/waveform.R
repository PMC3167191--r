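# Preprocessing chain for raw tonometry records: despiking, baseline-wander
# removal (5th-order polynomial + foot-anchored spline), beat segmentation
# with ensemble averaging, and extraction of the pulse amplitude H_ij.

#' A raw pulse waveform record
#'
#' One uniformly sampled pressure-signal time series taken at palpation
#' position `i` (1 = Chon, 2 = Gwan, 3 = Cheok) under hold-down pressure step
#' `j` (1 = lightest ... 5 = heaviest). Times are record-local seconds from 0.
#'
#' @param time strictly increasing, uniformly spaced times (s).
#' @param signal pressure amplitudes (arbitrary device units), finite.
#' @param position_index palpation position, 1-3.
#' @param step_index pressure step, 1-5.
#' @param applied_pressure hold-down pressure (mmHg), informational.
#' @param meta optional list of provenance metadata (e.g. generator ground
#'   truth).
#' @return a `pulse_record`.
#' @export
pulse_record <- function(time, signal, position_index, step_index,
                         applied_pressure = NA_real_, meta = list()) {
  stopifnot(is.numeric(time), is.numeric(signal), length(time) == length(signal),
            length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("time grid must be uniform")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (!position_index %in% 1:3) stop("position_index must be 1, 2 or 3")
  if (!step_index %in% 1:5) stop("step_index must be in 1..5")
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 position_index = as.integer(position_index),
                 step_index = as.integer(step_index),
                 applied_pressure = applied_pressure, meta = meta),
            class = "pulse_record")
}

#' @export
print.pulse_record <- function(x, ...) {
  fs <- 1 / stats::median(diff(x$time))
  cat(sprintf("Pulse record: position %d (%s), step %d, %.1f s at %.0f Hz\n",
              x$position_index, POSITION_NAMES[x$position_index], x$step_index,
              diff(range(x$time)), fs))
  invisible(x)
}

record_fs <- function(record) 1 / stats::median(diff(record$time))

#' Remove abrupt motion artifacts by nearest-neighbour replacement
#'
#' Flags samples whose first difference exceeds `k` robust standard
#' deviations (median absolute deviation scale) of the record's first
#' differences, and repairs each flagged run by nearest-neighbour
#' interpolation: flagged samples are replaced with the straight line between
#' the nearest unflagged samples on either side (or that neighbour's value at
#' a record edge), so no artificial step is left even when a spike sits on a
#' beat upstroke. Both endpoints of an abrupt difference are treated as
#' suspect (a spiked sample can never serve as a repair source), and repair
#' sweeps repeat against the original (frozen) threshold until no abrupt
#' variation remains, which also catches artifacts spanning two or three
#' adjacent samples. The threshold is not re-estimated between sweeps,
#' keeping clean beat upstrokes safe. The time grid is unchanged.
#'
#' @param record a [pulse_record()].
#' @param k spike threshold in robust-SD units (default 6).
#' @return the despiked `pulse_record`; `meta$n_despiked` counts replaced
#'   samples.
#' @export
despike <- function(record, k = 6) {
  stopifnot(inherits(record, "pulse_record"), k > 0)
  s <- record$signal
  n <- length(s)
  d0 <- diff(s)
  med <- stats::median(d0)
  thr <- k * stats::mad(d0)
  total <- logical(n)
  for (sweep in 1:10) {
    big <- abs(diff(s) - med) > thr
    flagged <- logical(n)
    flagged[which(big)] <- TRUE       # jump origin
    flagged[which(big) + 1L] <- TRUE  # jump landing
    if (!any(flagged)) break
    total <- total | flagged
    if (mean(total) > 0.5)
      stop("more than 50% of samples flagged as spikes; record unusable")
    # repair each flagged run from its unflagged neighbours
    runs <- rle(flagged)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      a <- starts[k]; b <- ends[k]
      l <- a - 1L; r <- b + 1L
      if (l >= 1L && r <= n)
        s[a:b] <- s[l] + (s[r] - s[l]) * (seq.int(a, b) - l) / (r - l)
      else if (l >= 1L) s[a:b] <- s[l]
      else if (r <= n) s[a:b] <- s[r]
      else stop("no unflagged samples left")
    }
  }
  out <- record
  out$signal <- s
  out$meta$n_despiked <- sum(total)
  out
}

# local maxima above a prominence threshold, with a refractory window
find_beat_peaks <- function(signal, fs, refractory = 0.3) {
  n <- length(signal)
  rng <- range(signal)
  thr <- rng[1] + 0.5 * diff(rng)
  is_peak <- c(FALSE, signal[2:(n - 1)] > signal[1:(n - 2)] &
                 signal[2:(n - 1)] >= signal[3:n], FALSE) & signal > thr
  cand <- which(is_peak)
  if (!length(cand)) return(integer(0))
  # enforce refractory window, keeping the taller of two close peaks
  min_gap <- round(refractory * fs)
  keep <- integer(0)
  for (p in cand[order(-signal[cand])]) {
    if (!length(keep) || all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
  }
  sort(keep)
}

# beat feet: signal minima between consecutive peaks, plus the minima before
# the first and after the last peak
find_beat_feet <- function(signal, peaks) {
  if (length(peaks) == 0L) return(integer(0))
  n <- length(signal)
  bounds <- c(1L, peaks, n)
  feet <- integer(length(peaks) + 1L)
  for (k in seq_len(length(peaks) + 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    feet[k] <- a - 1L + which.min(signal[a:b])
  }
  unique(feet)
}

#' Remove baseline wander by polynomial detrending and foot-anchored splines
#'
#' Two stages. (1) A least-squares 5th-order polynomial in time captures the
#' slow trend; on the detrended residual the beat feet (local minima between
#' beats) are located. (2) A natural cubic spline through the signal's foot
#' samples — the baseline estimate — is subtracted, pinning every beat foot
#' to 0. The foot-anchored correction is re-applied (feet re-detected on the
#' corrected signal) until the incremental correction falls below `tol` of
#' the signal range, which makes the operation idempotent: a
#' baseline-corrected record passes through essentially unchanged. The
#' polynomial stage steers foot detection but is not itself subtracted when
#' anchors are available: with only a handful of beats per record a
#' least-squares quintic partly tracks the beat oscillation, and subtracting
#' it would distort within-beat amplitudes, whereas the spline through the
#' diastolic feet follows every baseline component slower than the beat
#' rate (the quintic trend included) without touching beat morphology.
#'
#' With fewer than 4 anchor points the spline stage is skipped with a
#' warning (`meta$spline_skipped = TRUE`) and the polynomial fit itself is
#' subtracted (polynomial-only correction). `spline = FALSE` forces that
#' behaviour, e.g. for signals with no beats.
#'
#' @param record a despiked [pulse_record()].
#' @param spline apply the foot-anchored spline stage (default TRUE).
#' @param refractory minimum peak spacing (s) used when locating beat feet.
#' @param tol convergence tolerance for the iterated correction, as a
#'   fraction of the signal range.
#' @param max_iter iteration cap for the repeated correction.
#' @return baseline-corrected `pulse_record`.
#' @export
remove_baseline <- function(record, spline = TRUE, refractory = 0.3,
                            tol = 1e-8, max_iter = 25L) {
  stopifnot(inherits(record, "pulse_record"))
  t <- record$time
  s <- record$signal
  fs <- record_fs(record)
  rng <- diff(range(s))
  if (rng == 0) rng <- 1
  P <- cbind(1, stats::poly(t, degree = 5, simple = TRUE))
  trend <- drop(P %*% stats::lm.fit(P, s)$coefficients)
  out <- record
  out$meta$spline_skipped <- FALSE
  if (!spline) {
    out$meta$spline_skipped <- TRUE
    out$signal <- s - trend
    return(out)
  }
  detect <- s - trend          # detection copy; first pass must see past wander
  # if nearly everything is trend, there are no beats to anchor on
  if (diff(range(detect)) < 0.05 * rng) {
    warning("fewer than 4 beat-foot anchors; spline stage skipped ",
            "(polynomial-only baseline correction)")
    out$meta$spline_skipped <- TRUE
    out$signal <- detect
    return(out)
  }
  d <- s
  for (it in seq_len(max_iter)) {
    peaks <- find_beat_peaks(detect, fs, refractory)
    feet <- find_beat_feet(detect, peaks)
    # refine each foot to the local minimum of the signal being corrected, so
    # converged anchors are re-detected exactly on a second pass
    w <- max(1L, as.integer(round(0.1 * fs)))
    feet <- unique(vapply(as.integer(feet), function(f) {
      a <- max(1L, f - w); b <- min(length(d), f + w)
      a - 1L + which.min(d[a:b])
    }, integer(1)))
    if (length(feet) < 4L) {
      if (it == 1L) {
        warning("fewer than 4 beat-foot anchors; spline stage skipped ",
                "(polynomial-only baseline correction)")
        out$meta$spline_skipped <- TRUE
        out$signal <- s - trend
        return(out)
      }
      break
    }
    base <- stats::splinefun(t[feet], d[feet], method = "natural")(t)
    d <- d - base
    detect <- d                # later passes anchor on the corrected signal
    if (max(abs(base)) <= tol * rng) break
  }
  out$signal <- d
  out
}

#' Segment a record into beats and ensemble-average them
#'
#' Beats are delimited foot-to-foot: peaks are detected with a refractory
#' window, the signal minimum between consecutive peaks (and before the
#' first / after the last peak) defines the feet, and each foot-to-foot
#' segment is linearly resampled to a common length. The ensemble mean beat
#' is the pointwise average.
#'
#' @param record a baseline-corrected [pulse_record()].
#' @param beat_length common resampled beat length (samples, default 100).
#' @param refractory minimum peak spacing in seconds (default 0.3, capping
#'   detectable heart rate at 200 beats/min).
#' @return a `beat_ensemble`: `beats` (n_beats x beat_length matrix),
#'   `mean_beat`, `n_beats`.
#' @export
segment_periods <- function(record, beat_length = 100L, refractory = 0.3) {
  stopifnot(inherits(record, "pulse_record"), beat_length >= 10L)
  s <- record$signal
  fs <- record_fs(record)
  peaks <- find_beat_peaks(s, fs, refractory)
  if (length(peaks) == 0L)
    stop("no beats detected in record (position ", record$position_index,
         ", step ", record$step_index, ")")
  feet <- find_beat_feet(s, peaks)
  if (length(feet) < 2L) {
    # single peak with one usable foot: treat the whole record as one beat
    feet <- c(1L, length(s))
  }
  segs <- cbind(feet[-length(feet)], feet[-1])
  segs <- segs[segs[, 2] - segs[, 1] >= 3L, , drop = FALSE]
  if (!nrow(segs)) stop("no beat segment long enough to resample")
  beats <- t(apply(segs, 1L, function(ab) {
    idx <- seq(ab[1], ab[2], length.out = beat_length)
    stats::approx(seq(ab[1], ab[2]), s[ab[1]:ab[2]], xout = idx)$y
  }))
  structure(list(beats = beats, mean_beat = colMeans(beats),
                 n_beats = nrow(beats)),
            class = "beat_ensemble")
}

#' @export
print.beat_ensemble <- function(x, ...) {
  cat(sprintf("Beat ensemble: %d beat(s), %d samples each, amplitude %.3f\n",
              x$n_beats, ncol(x$beats), pulse_amplitude(x)))
  invisible(x)
}

#' Pulse amplitude of an ensemble-averaged beat
#'
#' `H = max(mean_beat) - min(mean_beat)`: the foot-to-peak excursion of the
#' averaged beat, invariant to vertical translation.
#'
#' @param ensemble a `beat_ensemble` from [segment_periods()].
#' @return non-negative amplitude (arb units).
#' @export
pulse_amplitude <- function(ensemble) {
  stopifnot(inherits(ensemble, "beat_ensemble"))
  max(ensemble$mean_beat) - min(ensemble$mean_beat)
}

#' Run the full preprocessing chain on one record
#'
#' [despike()] then [remove_baseline()] then [segment_periods()] then
#' [pulse_amplitude()].
#'
#' @param record a raw [pulse_record()].
#' @param k spike threshold (robust-SD units).
#' @param beat_length resampled beat length.
#' @param refractory peak-detection refractory window (s).
#' @return the pulse amplitude H (arb units).
#' @export
process_record <- function(record, k = 6, beat_length = 100L, refractory = 0.3) {
  rec <- despike(record, k = k)
  rec <- remove_baseline(rec, refractory = refractory)
  pulse_amplitude(segment_periods(rec, beat_length = beat_length,
                                  refractory = refractory))
}

#' Assemble a subject's amplitude matrix from its 15 records
#'
#' Requires exactly one record per (position, step) cell; duplicates or
#' missing cells reject the whole subject, naming the offending cells. Any
#' record failing preprocessing also rejects the subject. Assembly is keyed
#' by each record's indices, so input order is irrelevant.
#'
#' @param records list of 15 [pulse_record()]s covering all (i, j) pairs.
#' @param subject_id identifier for the resulting matrix.
#' @param ... passed to [process_record()].
#' @return an [amplitude_matrix()].
#' @export
extract_amplitude_matrix <- function(records, subject_id = "subject", ...) {
  stopifnot(is.list(records))
  keys <- vapply(records, function(r) {
    stopifnot(inherits(r, "pulse_record"))
    paste0(r$position_index, ",", r$step_index)
  }, character(1))
  all_keys <- as.vector(outer(1:3, 1:5, paste, sep = ","))
  dup <- unique(keys[duplicated(keys)])
  missing <- setdiff(all_keys, keys)
  if (length(dup) || length(missing))
    stop("bad record set for subject ", subject_id,
         if (length(dup)) paste0("; duplicate cells (i,j): ", paste(dup, collapse = " ")),
         if (length(missing)) paste0("; missing cells (i,j): ", paste(missing, collapse = " ")))
  H <- matrix(NA_real_, 3L, 5L)
  failed <- character(0)
  for (r in records) {
    h <- tryCatch(process_record(r, ...), error = function(e) {
      failed <<- c(failed, paste0("(", r$position_index, ",", r$step_index,
                                  "): ", conditionMessage(e)))
      NA_real_
    })
    H[r$position_index, r$step_index] <- h
  }
  if (length(failed))
    stop("subject ", subject_id, " rejected; failing cells: ",
         paste(failed, collapse = "; "))
  amplitude_matrix(H, subject_id = subject_id)
}

#' Read / write waveform CSV files
#'
#' Waveform records travel as two-column CSV (`time_s,signal_arb`), one file
#' per (subject, position, step), named `subj{ID}_pos{i}_step{j}.csv`.
#'
#' @param record a [pulse_record()].
#' @param dir directory for the file.
#' @param subject_id subject identifier used in the filename.
#' @return `write_waveform_csv` returns the file path invisibly;
#'   `read_waveform_csv` returns a [pulse_record()].
#' @export
write_waveform_csv <- function(record, dir, subject_id) {
  stopifnot(inherits(record, "pulse_record"))
  path <- file.path(dir, sprintf("subj%s_pos%d_step%d.csv", subject_id,
                                 record$position_index, record$step_index))
  utils::write.csv(data.frame(time_s = record$time, signal_arb = record$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param path a waveform CSV file whose name follows the
#'   `subj{ID}_pos{i}_step{j}.csv` pattern.
#' @export
read_waveform_csv <- function(path) {
  m <- regmatches(basename(path),
                  regexec("^subj(.+)_pos([1-3])_step([1-5])\\.csv$", basename(path)))[[1]]
  if (length(m) != 4L)
    stop("filename does not match subj{ID}_pos{i}_step{j}.csv: ", basename(path))
  d <- utils::read.csv(path)
  pulse_record(d$time_s, d$signal_arb,
               position_index = as.integer(m[3]), step_index = as.integer(m[4]),
               meta = list(subject_id = m[2]))
}
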