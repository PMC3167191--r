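# Pulse quantities derived from the 3 x 5 amplitude matrix, cohort-level
# standardization, and the flat analysis table used by the modelling stages.

POSITION_NAMES <- c("Chon", "Gwan", "Cheok")
H_COLUMNS <- as.vector(t(outer(1:3, 1:5, function(i, j) paste0("H", i, j))))
SUMMARY_COLUMNS <- c("PP1", "PP2", "PP3", "MPA1", "MPA2", "MPA3",
                     "PP_avg", "PP_max", "MPA_avg", "MPA_max")

#' Per-subject pulse amplitude matrix
#'
#' The core measurement container: pulse amplitudes `H[i, j]` at palpation
#' position `i` (1 = Chon, 2 = Gwan, 3 = Cheok) and hold-down pressure step
#' `j` (1 = lightest ... 5 = heaviest).
#'
#' @param H 3x5 numeric matrix of non-negative, finite amplitudes (arbitrary
#'   device units).
#' @param subject_id opaque subject identifier.
#' @return an `amplitude_matrix` object.
#' @export
amplitude_matrix <- function(H, subject_id = "subject") {
  H <- as.matrix(H)
  if (!all(dim(H) == c(3L, 5L)))
    stop("amplitude matrix must be 3 positions x 5 pressure steps, got ",
         nrow(H), "x", ncol(H))
  if (!all(is.finite(H))) stop("amplitude matrix contains non-finite entries")
  if (any(H < 0)) stop("pulse amplitudes must be non-negative")
  dimnames(H) <- list(position = POSITION_NAMES, step = paste0("P", 1:5))
  structure(list(H = H, subject_id = as.character(subject_id)),
            class = "amplitude_matrix")
}

#' @export
print.amplitude_matrix <- function(x, ...) {
  cat("Pulse amplitude matrix for subject", x$subject_id, "(arb units)\n")
  print(round(x$H, 3))
  invisible(x)
}

#' Pulse-pressure and mean-pulse-amplitude summaries
#'
#' From an [amplitude_matrix()] computes, per position `i`, the pulse
#' pressure `PP_i = max_j H_ij` (maximum excursion over the pressure sweep,
#' the tonometric analogue of systolic-minus-diastolic pressure) and the
#' mean pulse amplitude `MPA_i = mean_j H_ij`, then their across-position
#' average and maximum: `PP_avg`, `PP_max`, `MPA_avg`, `MPA_max`. These
#' scalars summarize pulse force, the property that separates the deficient
#' from the excess pulse quality.
#'
#' @param matrix an [amplitude_matrix()].
#' @return a `pulse_summary` (named list with `PP`, `MPA` length-3 vectors
#'   and the four scalar aggregates).
#' @export
summarize_pulse <- function(matrix) {
  stopifnot(inherits(matrix, "amplitude_matrix"))
  H <- matrix$H
  PP <- apply(H, 1L, max)
  MPA <- rowMeans(H)
  structure(list(subject_id = matrix$subject_id,
                 PP = PP, MPA = MPA,
                 PP_avg = mean(PP), PP_max = max(PP),
                 MPA_avg = mean(MPA), MPA_max = max(MPA)),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat("Pulse summary for subject", x$subject_id, "(arb units)\n")
  m <- rbind(PP = x$PP, MPA = x$MPA)
  colnames(m) <- POSITION_NAMES
  print(round(m, 3))
  cat(sprintf("  <PP> = %.3f  PP_max = %.3f  <MPA> = %.3f  MPA_max = %.3f\n",
              x$PP_avg, x$PP_max, x$MPA_avg, x$MPA_max))
  invisible(x)
}

#' Standardize a cohort feature to z-scores
#'
#' Centers and scales with the sample standard deviation (n - 1 denominator),
#' so the output has mean 0 and sample SD 1. Order-preserving and invariant
#' under positive affine transforms of the input. Threshold criteria of the
#' classification rules are expressed on this scale.
#'
#' @param values numeric vector over a cohort (length >= 2, nonzero variance).
#' @return z-scores; attributes `center` and `scale` hold the cohort mean and
#'   SD so new subjects can be projected onto the same scale.
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("standardization needs a cohort of at least 2")
  if (anyNA(values)) stop("missing values in feature")
  s <- stats::sd(values)
  if (s == 0) stop("feature has zero variance; cannot standardize")
  z <- (values - mean(values)) / s
  attr(z, "center") <- mean(values)
  attr(z, "scale") <- s
  z
}

#' Assemble the per-subject analysis table
#'
#' One row per subject: the 15 raw amplitudes `H11..H35` (position-major),
#' the ten summaries (`PP1..PP3`, `MPA1..MPA3`, `PP_avg`, `PP_max`,
#' `MPA_avg`, `MPA_max`), and the expert label. This is the table the factor
#' analysis, discriminant analysis and threshold models consume.
#'
#' @param matrices list of [amplitude_matrix()] objects with unique
#'   `subject_id`s.
#' @param labels vector of `"deficient"`/`"excess"` labels, one per matrix.
#' @return data.frame with columns `subject_id`, `H11..H35`,
#'   `PP1..MPA_max`, `label`.
#' @export
feature_table <- function(matrices, labels) {
  stopifnot(is.list(matrices), length(matrices) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% PULSE_CLASSES))
    stop("labels must be 'deficient' or 'excess'")
  ids <- vapply(matrices, function(m) m$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(matrices, function(m) {
    s <- summarize_pulse(m)
    c(as.vector(t(m$H)),                      # H11..H15, H21..H25, H31..H35
      s$PP, s$MPA, s$PP_avg, s$PP_max, s$MPA_avg, s$MPA_max)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(H_COLUMNS, SUMMARY_COLUMNS)
  cbind(subject_id = ids, out, label = labels, stringsAsFactors = FALSE)
}

#' Write / read the cohort feature table as CSV
#'
#' Plain-text round trip of the [feature_table()] schema.
#'
#' @param table a feature table (or amplitude-cohort data.frame).
#' @param path file path.
#' @return `read_feature_csv` returns the data.frame; `write_feature_csv`
#'   returns `path` invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
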