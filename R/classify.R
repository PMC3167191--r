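# Decision rules and evaluation for the deficient/excess pulse qualities:
# single-variable banded threshold, two-stage mixed-variable model, confusion
# tables, accuracy and the Matthews correlation coefficient.

PULSE_CLASSES <- c("deficient", "excess")

#' Banded threshold rule on a standardized pulse variable
#'
#' A rule with an upper criterion `alpha` and a lower criterion `beta`
#' (`alpha >= beta`): values at or above `alpha` are called excess, values
#' below `beta` deficient, and values in `[beta, alpha)` are left
#' intermediate. With `alpha == beta` the rule is total (every input gets a
#' definite label). Thresholds are expressed in z-units of the standardized
#' variable (see [standardize()]).
#'
#' @param variable name of the standardized summary the rule applies to
#'   (e.g. `"PP_avg"`); informational.
#' @param alpha upper criterion (z-units); inputs `>= alpha` are excess.
#' @param beta lower criterion (z-units); inputs `< beta` are deficient.
#' @return an object of class `threshold_rule`.
#' @seealso [classify_single()], [mixed_threshold_model()]
#' @export
threshold_rule <- function(variable, alpha, beta) {
  stopifnot(is.character(variable), length(variable) == 1L,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha) || is.infinite(alpha),
            is.numeric(beta), length(beta) == 1L)
  if (is.na(alpha) || is.na(beta)) stop("threshold criteria must not be NA")
  if (alpha < beta) stop("invalid threshold rule: alpha (", alpha,
                         ") must be >= beta (", beta, ")")
  structure(list(variable = variable, alpha = alpha, beta = beta),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("Threshold rule on %s: excess if z >= %.4g, deficient if z < %.4g\n",
              x$variable, x$alpha, x$beta))
  if (x$alpha > x$beta)
    cat(sprintf("  intermediate band: [%.4g, %.4g)\n", x$beta, x$alpha))
  invisible(x)
}

#' Two-stage mixed-variable classification model
#'
#' Combines a primary banded [threshold_rule()] with a secondary rule that
#' resolves the primary's intermediate band `[beta, alpha)`. The secondary
#' criteria are conventionally written gamma (upper) and delta (lower); by
#' default the model requires `gamma == delta` so every subject receives a
#' definite label. A secondary band (`gamma > delta`) is allowed only with
#' `tie_break = "midpoint"`, which sends secondary-intermediate subjects to
#' excess when the secondary value is at or above `(gamma + delta) / 2`.
#'
#' @param primary,secondary [threshold_rule()] objects; the secondary rule's
#'   `alpha`/`beta` play the roles of gamma/delta.
#' @param tie_break `"none"` (default; requires `gamma == delta`) or
#'   `"midpoint"`.
#' @return an object of class `mixed_threshold_model`.
#' @seealso [classify_mixed()], [fit_thresholds()]
#' @export
mixed_threshold_model <- function(primary, secondary, tie_break = c("none", "midpoint")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(primary, "threshold_rule"), inherits(secondary, "threshold_rule"))
  if (secondary$alpha > secondary$beta && tie_break == "none")
    stop("secondary rule has gamma > delta, so some inputs would stay ",
         "intermediate; set gamma = delta or use tie_break = \"midpoint\"")
  structure(list(primary = primary, secondary = secondary, tie_break = tie_break),
            class = "mixed_threshold_model")
}

#' @export
print.mixed_threshold_model <- function(x, ...) {
  cat("Mixed-variable threshold model\n")
  cat(sprintf("  primary   %s: alpha = %.4g, beta = %.4g\n",
              x$primary$variable, x$primary$alpha, x$primary$beta))
  cat(sprintf("  secondary %s: gamma = %.4g, delta = %.4g\n",
              x$secondary$variable, x$secondary$alpha, x$secondary$beta))
  invisible(x)
}

#' Classify standardized values with a banded threshold rule
#'
#' Applies the rule: `z >= alpha` gives `"excess"`, `z < beta` gives
#' `"deficient"`, anything in between is `"intermediate"`. Boundaries are
#' inclusive on the excess side (`>=`).
#'
#' @param z numeric vector of standardized values.
#' @param rule a [threshold_rule()].
#' @return character vector in `{"excess", "deficient", "intermediate"}`.
#' @export
classify_single <- function(z, rule) {
  stopifnot(inherits(rule, "threshold_rule"), is.numeric(z))
  out <- rep("intermediate", length(z))
  out[z >= rule$alpha] <- "excess"
  out[z < rule$beta] <- "deficient"
  out
}

#' Classify with the two-stage mixed-variable model
#'
#' The primary rule is applied first; subjects falling in its intermediate
#' band `[beta, alpha)` are resolved by the secondary rule (criteria
#' gamma/delta, inclusive `>=` on the excess side throughout).
#'
#' @param z_primary,z_secondary numeric vectors of standardized values for
#'   the primary and secondary variables (same length).
#' @param model a [mixed_threshold_model()].
#' @return character vector in `{"excess", "deficient"}`.
#' @export
classify_mixed <- function(z_primary, z_secondary, model) {
  stopifnot(inherits(model, "mixed_threshold_model"),
            length(z_primary) == length(z_secondary))
  lab <- classify_single(z_primary, model$primary)
  mid <- lab == "intermediate"
  if (any(mid)) {
    sec <- classify_single(z_secondary[mid], model$secondary)
    if (any(sec == "intermediate")) {
      # only reachable with tie_break = "midpoint" (validated at build time)
      cut <- (model$secondary$alpha + model$secondary$beta) / 2
      sec[sec == "intermediate"] <-
        ifelse(z_secondary[mid][sec == "intermediate"] >= cut, "excess", "deficient")
    }
    lab[mid] <- sec
  }
  lab
}

# Candidate thresholds for grid fitting: midpoints between sorted unique
# values, plus -Inf/+Inf so "always excess"/"always deficient" are reachable.
threshold_candidates <- function(z, grid_resolution = NULL) {
  u <- sort(unique(z))
  if (!is.null(grid_resolution)) {
    stopifnot(grid_resolution > 0)
    if (length(u) > grid_resolution)
      u <- unique(stats::quantile(u, probs = seq(0, 1, length.out = grid_resolution),
                                  names = FALSE, type = 7))
  }
  if (length(u) >= 2L) mids <- (u[-1] + u[-length(u)]) / 2 else mids <- numeric(0)
  c(-Inf, mids, Inf)
}

#' Fit the mixed-variable threshold model by exhaustive grid search
#'
#' Searches all pairs `(alpha, beta)` with `alpha >= beta` over candidate
#' thresholds for the primary variable and, for each pair, the best single
#' secondary criterion `gamma = delta` for the intermediate band. Candidate
#' thresholds are the midpoints between sorted unique values plus `-Inf` and
#' `+Inf`. The objective is training accuracy; ties are broken first by MCC,
#' then by the smallest band width `|alpha - beta|`. Because `alpha == beta`
#' (secondary never consulted) is in the search space, the fitted model's
#' training accuracy is always at least that of the best single-threshold
#' rule on the primary variable.
#'
#' The selection procedure is this package's own: it is a transparent
#' exhaustive search, not an estimator with known sampling properties, and
#' training accuracy is an optimistic estimate — evaluate fitted models by
#' cross-validation (see [loocv()]).
#'
#' @param z_primary,z_secondary standardized values (same length).
#' @param labels vector of `"deficient"`/`"excess"` expert labels.
#' @param grid_resolution optional cap on the number of candidate thresholds
#'   per variable (quantile-thinned); `NULL` uses every midpoint.
#' @param primary_name,secondary_name variable names stored in the rules.
#' @return a [mixed_threshold_model()] with attributes `train_accuracy` and
#'   `train_mcc`.
#' @export
fit_thresholds <- function(z_primary, z_secondary, labels, grid_resolution = NULL,
                           primary_name = "primary", secondary_name = "secondary") {
  labels <- as.character(labels)
  stopifnot(length(z_primary) == length(labels),
            length(z_secondary) == length(labels),
            all(labels %in% PULSE_CLASSES))
  if (length(unique(labels)) < 2L)
    stop("threshold fitting needs both classes present")

  n <- length(labels)
  is_exc <- labels == "excess"
  A <- threshold_candidates(z_primary, grid_resolution)    # alpha/beta candidates
  C <- threshold_candidates(z_secondary, grid_resolution)  # gamma candidates

  ord <- order(z_primary)
  exc <- is_exc[ord]

  # position of each candidate in the sorted primary values:
  # subjects with sorted index > pos(c) satisfy z >= c (midpoints never tie data)
  pos <- findInterval(A, z_primary[ord])

  # class composition of the decided regions, per candidate position
  cum_exc <- c(0, cumsum(exc))          # excess among the first k sorted subjects
  cum_def <- c(0, cumsum(!exc))
  n_exc <- sum(exc)
  n_def <- n - n_exc

  # per-gamma cumulative counts over the primary-sorted order:
  # secondary predicts excess iff z_s >= gamma
  pe <- outer(z_secondary[ord], C, ">=")               # n x |C| predicted-excess
  cum_pe_exc <- rbind(0, apply(pe & exc, 2L, cumsum))  # pred exc & true exc
  cum_pe_def <- rbind(0, apply(pe & !exc, 2L, cumsum)) # pred exc & true def

  mcc_counts <- function(tp, fn, fp, tn) {
    den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    ifelse(den2 == 0, 0, (tp * tn - fp * fn) / sqrt(den2))
  }

  best <- list(count = -1L, mcc = -Inf, width = Inf)
  for (ia in seq_along(A)) {
    pa <- pos[ia]
    ib <- seq_len(ia)                   # beta <= alpha
    pb <- pos[ib]
    hi_exc <- n_exc - cum_exc[pa + 1L]  # z >= alpha region (predicted excess)
    hi_def <- n_def - cum_def[pa + 1L]
    lo_def <- cum_def[pb + 1L]          # z < beta region (predicted deficient)
    lo_exc <- cum_exc[pb + 1L]
    # intermediate band [beta, alpha): secondary decides
    mid_pe_exc <- rep(cum_pe_exc[pa + 1L, ], each = length(ib)) -
      cum_pe_exc[pb + 1L, , drop = FALSE]               # |ib| x |C|
    mid_pe_def <- rep(cum_pe_def[pa + 1L, ], each = length(ib)) -
      cum_pe_def[pb + 1L, , drop = FALSE]
    mid_exc <- cum_exc[pa + 1L] - cum_exc[pb + 1L]
    mid_def <- cum_def[pa + 1L] - cum_def[pb + 1L]

    correct <- hi_exc + lo_def + mid_pe_exc + (mid_def - mid_pe_def)
    m <- max(correct)
    if (m < best$count) next
    hits <- which(correct == m, arr.ind = TRUE)
    # MCC tie-break (deficient = positive class), then smallest band width
    hb <- hits[, 1L]
    tn <- hi_exc + mid_pe_exc[hits]                       # pred exc & true exc
    fn <- hi_def + mid_pe_def[hits]                       # pred exc & true def
    tp <- lo_def[hb] + (mid_def[hb] - mid_pe_def[hits])   # pred def & true def
    fp <- lo_exc[hb] + (mid_exc[hb] - mid_pe_exc[hits])   # pred def & true exc
    mccs <- mcc_counts(tp, fn, fp, tn)
    widths <- A[ia] - A[ib[hb]]
    widths[A[ia] == A[ib[hb]]] <- 0   # alpha == beta, incl. infinite candidates
    for (h in seq_len(nrow(hits))) {
      better <- m > best$count ||
        mccs[h] > best$mcc + 1e-12 ||
        (abs(mccs[h] - best$mcc) <= 1e-12 && widths[h] < best$width)
      if (better) {
        best <- list(count = m, mcc = mccs[h], width = widths[h],
                     alpha = A[ia], beta = A[ib[hits[h, 1L]]],
                     gamma = C[hits[h, 2L]])
      }
    }
  }
  best$acc <- best$count / n

  model <- mixed_threshold_model(
    threshold_rule(primary_name, best$alpha, best$beta),
    threshold_rule(secondary_name, best$gamma, best$gamma))
  attr(model, "train_accuracy") <- best$acc
  attr(model, "train_mcc") <- best$mcc
  model
}

#' Fit a single-variable total threshold (alpha = beta)
#'
#' Grid search over midpoint candidates for the best single cutpoint
#' (`z >= alpha` excess), maximizing training accuracy with MCC tie-break.
#'
#' @inheritParams fit_thresholds
#' @param z standardized values of the variable.
#' @param variable name stored in the rule.
#' @return a [threshold_rule()] with `alpha == beta` and attributes
#'   `train_accuracy`, `train_mcc`.
#' @export
fit_threshold_single <- function(z, labels, grid_resolution = NULL,
                                 variable = "primary") {
  labels <- as.character(labels)
  stopifnot(length(z) == length(labels), all(labels %in% PULSE_CLASSES))
  if (length(unique(labels)) < 2L) stop("threshold fitting needs both classes present")
  A <- threshold_candidates(z, grid_resolution)
  is_exc <- labels == "excess"
  n <- length(labels)
  ord <- order(z)
  exc <- is_exc[ord]
  pos <- findInterval(A, z[ord])
  cum_exc <- c(0, cumsum(exc))
  cum_def <- c(0, cumsum(!exc))
  n_exc <- sum(exc); n_def <- n - n_exc
  tn <- n_exc - cum_exc[pos + 1L]   # pred excess & true excess
  fn <- n_def - cum_def[pos + 1L]   # pred excess & true deficient
  tp <- cum_def[pos + 1L]           # pred deficient & true deficient
  fp <- cum_exc[pos + 1L]           # pred deficient & true excess
  acc <- (tn + tp) / n
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mccs <- ifelse(den2 == 0, 0, (tp * tn - fp * fn) / sqrt(den2))
  cand <- which(acc == max(acc))
  pick <- cand[which.max(mccs[cand])]
  best <- list(acc = acc[pick], mcc = mccs[pick], alpha = A[pick])
  rule <- threshold_rule(variable, best$alpha, best$alpha)
  attr(rule, "train_accuracy") <- best$acc
  attr(rule, "train_mcc") <- best$mcc
  rule
}

#' Confusion table of expert vs predicted labels
#'
#' @param true_labels,predicted_labels equal-length vectors with values in
#'   `{"deficient", "excess"}`.
#' @return a `confusion_table`: 2x2 integer matrix, rows = expert label,
#'   columns = predicted label.
#' @export
confusion <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), PULSE_CLASSES)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(true_labels, levels = PULSE_CLASSES),
               factor(predicted_labels, levels = PULSE_CLASSES))
  m <- matrix(as.integer(tab), 2L, 2L,
              dimnames = list(expert = PULSE_CLASSES, predicted = PULSE_CLASSES))
  structure(m, class = c("confusion_table", "matrix"))
}

#' Build a confusion table directly from its four counts
#'
#' Convenience for evaluating published 2x2 tables. Counts follow the layout
#' rows = expert label (deficient, excess), columns = predicted label.
#'
#' @param dd,de,ed,ee counts: expert-deficient predicted-deficient,
#'   expert-deficient predicted-excess, expert-excess predicted-deficient,
#'   expert-excess predicted-excess.
#' @return a `confusion_table`.
#' @export
confusion_from_counts <- function(dd, de, ed, ee) {
  counts <- c(dd, de, ed, ee)
  stopifnot(length(counts) == 4L, all(counts >= 0), all(counts == round(counts)))
  m <- matrix(as.integer(c(dd, ed, de, ee)), 2L, 2L,
              dimnames = list(expert = PULSE_CLASSES, predicted = PULSE_CLASSES))
  structure(m, class = c("confusion_table", "matrix"))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Confusion table (rows = expert diagnosis, columns = prediction)\n")
  print(unclass(x))
  cat(sprintf("accuracy = %.1f%%, MCC = %.2f\n", 100 * accuracy(x), mcc(x)))
  invisible(x)
}

#' Classification accuracy of a confusion table
#'
#' @param table a `confusion_table` (see [confusion()]).
#' @return fraction of concordant labels, `trace / total`.
#' @export
accuracy <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  total <- sum(table)
  if (total == 0) stop("empty confusion table")
  sum(diag(table)) / total
}

#' Matthews correlation coefficient of a confusion table
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' chance-corrected statistic in `[-1, 1]` that stays informative under the
#' class imbalance typical of clinical cohorts. Deficient is bookkept as the
#' positive class; MCC is invariant to that choice. When any marginal is
#' zero (e.g. all predictions in one class) the coefficient is defined as 0.
#'
#' @param table a `confusion_table`.
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  if (sum(table) == 0) stop("empty confusion table")
  tp <- as.numeric(table["deficient", "deficient"])
  fn <- as.numeric(table["deficient", "excess"])
  fp <- as.numeric(table["excess", "deficient"])
  tn <- as.numeric(table["excess", "excess"])
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}
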