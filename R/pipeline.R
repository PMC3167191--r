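# End-to-end orchestration: simulate -> (preprocess) -> extract -> fit ->
# evaluate, with persisted intermediates and a comparison grid of candidate
# decision variables (entire-data and leave-one-out accuracy/MCC).

SINGLE_VARIABLES <- c("PP_avg", "PP_max", "MPA_avg", "MPA_max")

#' Run configuration for an end-to-end analysis
#'
#' @param stages prefix of the canonical order `simulate`, `preprocess`,
#'   `extract`, `fit`, `evaluate`. `preprocess` routes the cohort through
#'   waveform simulation and the full signal-processing chain rather than
#'   using amplitude-level matrices directly.
#' @param seed root seed recorded in all outputs.
#' @param cohort a [cohort_spec()] (its seed is overridden by `seed`).
#' @param waveform a [waveform_spec()] used when `preprocess` is in
#'   `stages`.
#' @param protocol a [pressure_protocol()].
#' @param primary,secondary variable names for the mixed threshold model.
#' @param prior LDA prior convention, `"proportional"` or `"equal"`.
#' @param grid_resolution optional threshold-grid cap for [fit_thresholds()].
#' @param out_dir directory for persisted intermediates (`NULL` = keep in
#'   memory only).
#' @param verbose print per-stage progress.
#' @return a `run_config`.
#' @export
run_config <- function(stages = c("simulate", "extract", "fit", "evaluate"),
                       seed = 1L,
                       cohort = cohort_spec(seed = seed),
                       waveform = waveform_spec(seed = seed),
                       protocol = pressure_protocol(),
                       primary = "PP_avg", secondary = "PP_max",
                       prior = "proportional",
                       grid_resolution = NULL,
                       out_dir = NULL, verbose = FALSE) {
  canonical <- c("simulate", "preprocess", "extract", "fit", "evaluate")
  stages <- match.arg(stages, canonical, several.ok = TRUE)
  idx <- match(stages, canonical)
  if (any(diff(idx) <= 0) || !identical(stages[1], "simulate"))
    stop("stages must be an ordered prefix-style subset of: ",
         paste(canonical, collapse = " -> "))
  stopifnot(primary %in% SUMMARY_COLUMNS, secondary %in% SUMMARY_COLUMNS)
  cohort$seed <- as.integer(seed)
  waveform$seed <- as.integer(seed)
  structure(list(stages = stages, seed = as.integer(seed), cohort = cohort,
                 waveform = waveform, protocol = protocol,
                 primary = primary, secondary = secondary, prior = prior,
                 grid_resolution = grid_resolution,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

eval_model_grid <- function(features, prior, grid_resolution,
                            primary = "PP_avg", secondary = "PP_max",
                            include_factors = TRUE) {
  y <- features$label
  rows <- list()
  add_row <- function(model_name, train_tab, cv_tab) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model_name,
      accuracy = accuracy(train_tab), mcc = mcc(train_tab),
      cv_accuracy = accuracy(cv_tab), cv_mcc = mcc(cv_tab))
  }

  lda_fit <- function(X, yy) fisher_lda(X, yy, prior = prior)
  for (v in SINGLE_VARIABLES) {
    X <- as.matrix(features[, v, drop = FALSE])
    fit <- lda_fit(X, y)
    add_row(v, confusion(y, predict(fit, X)), loocv(lda_fit, X, y)$table)
  }

  if (include_factors) {
    XH <- as.matrix(features[, H_COLUMNS])
    factor_lda_fit <- function(X, yy) {
      fm <- suppressWarnings(factor_analysis(X))
      sc <- factor_scores(fm, X)
      list(fm = fm, lda = fisher_lda(sc, yy, prior = prior))
    }
    factor_lda_predict <- function(m, nd) {
      predict(m$lda, factor_scores(m$fm, nd))
    }
    fit <- factor_lda_fit(XH, y)
    train_tab <- confusion(y, factor_lda_predict(fit, XH))
    cv_tab <- loocv(factor_lda_fit, XH, y, predict_fun = factor_lda_predict)$table
    add_row("factors", train_tab, cv_tab)
  }

  X4 <- as.matrix(features[, SINGLE_VARIABLES])
  fit4 <- lda_fit(X4, y)
  add_row("all_four", confusion(y, predict(fit4, X4)), loocv(lda_fit, X4, y)$table)

  # mixed-variable threshold model on standardized primary/secondary
  zp <- standardize(features[[primary]])
  zs <- standardize(features[[secondary]])
  mixed_fit <- function(X, yy) {
    fit_thresholds(X[, 1], X[, 2], yy, grid_resolution = grid_resolution,
                   primary_name = primary, secondary_name = secondary)
  }
  mixed_predict <- function(m, nd) classify_mixed(nd[, 1], nd[, 2], m)
  Z <- cbind(zp, zs)
  model <- mixed_fit(Z, y)
  train_tab <- confusion(y, classify_mixed(zp, zs, model))
  cv_tab <- loocv(mixed_fit, Z, y, predict_fun = mixed_predict)$table
  add_row("mixed", train_tab, cv_tab)

  list(grid = do.call(rbind, rows), mixed_model = model)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order on a synthetic cohort: simulate
#' amplitudes (optionally render waveforms and recover amplitudes through
#' the preprocessing chain), build the feature table, fit the candidate
#' models, and evaluate each with entire-data and leave-one-out
#' accuracy/MCC. The evaluation grid covers the four across-position
#' summaries as single-variable discriminants, the factor-score
#' discriminant, the four-variable discriminant, and the mixed-variable
#' threshold model. With `out_dir` set, every intermediate is persisted
#' (cohort CSV, feature CSV, model JSON, report JSON + Markdown) along with
#' a manifest.
#'
#' @param config a [run_config()].
#' @return a `run_report`: `stages`, `seed`, per-stage `summaries`,
#'   `features` (the analysis table), `grid` (model x accuracy/MCC/LOOCV
#'   data.frame), `mixed_model`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(...)
  out <- list(stages = config$stages, seed = config$seed,
              summaries = list())
  persist <- !is.null(config$out_dir)
  if (persist) dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("stage simulate: n = ", config$cohort$n_subjects)
  cohort <- simulate_amplitude_cohort(config$cohort)
  out$summaries$simulate <- list(
    n_subjects = config$cohort$n_subjects,
    n_excess = sum(cohort$labels == "excess"),
    n_deficient = sum(cohort$labels == "deficient"),
    seed = config$seed)
  if (persist)
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort_true.csv"))

  matrices <- cohort$matrices
  if ("preprocess" %in% config$stages) {
    say("stage preprocess: rendering and re-extracting waveforms")
    rejected <- character(0)
    matrices <- vector("list", length(cohort$matrices))
    for (s in seq_along(cohort$matrices)) {
      wspec <- config$waveform
      wspec$seed <- subject_seed(config$seed, 1000L + s)
      recs <- simulate_subject_records(wspec, config$protocol, cohort$matrices[[s]])
      matrices[[s]] <- tryCatch(
        extract_amplitude_matrix(recs, subject_id = cohort$matrices[[s]]$subject_id),
        error = function(e) {
          rejected <<- c(rejected, cohort$matrices[[s]]$subject_id)
          NULL
        })
    }
    keep <- !vapply(matrices, is.null, logical(1))
    out$summaries$preprocess <- list(n_rejected = sum(!keep), rejected = rejected)
    matrices <- matrices[keep]
    cohort$labels <- cohort$labels[keep]
    if (persist)
      write_cohort_csv(list(labels = cohort$labels, matrices = matrices),
                       file.path(config$out_dir, "cohort_measured.csv"))
  }
  if (!"extract" %in% config$stages) return(finish_report(out, config, persist))

  say("stage extract: feature table")
  features <- feature_table(matrices, cohort$labels)
  out$features <- features
  out$summaries$extract <- list(n_rows = nrow(features),
                                n_feature_columns = ncol(features) - 2L)
  if (persist) write_feature_csv(features, file.path(config$out_dir, "features.csv"))
  if (!"fit" %in% config$stages) return(finish_report(out, config, persist))

  say("stage fit/evaluate: model grid")
  ev <- eval_model_grid(features, prior = config$prior,
                        grid_resolution = config$grid_resolution,
                        primary = config$primary, secondary = config$secondary)
  out$grid <- ev$grid
  out$mixed_model <- ev$mixed_model
  out$summaries$fit <- list(
    mixed_alpha = ev$mixed_model$primary$alpha,
    mixed_beta = ev$mixed_model$primary$beta,
    mixed_gamma = ev$mixed_model$secondary$alpha)
  if (persist)
    write_model_json(ev$mixed_model,
                     file.path(config$out_dir, "mixed_model.json"),
                     standardization = list(
                       primary = attributes(standardize(features[[config$primary]]))[c("center", "scale")],
                       secondary = attributes(standardize(features[[config$secondary]]))[c("center", "scale")]),
                     seed = config$seed)
  finish_report(out, config, persist)
}

finish_report <- function(out, config, persist) {
  report <- structure(out, class = "run_report")
  if (persist) {
    json <- list(seed = out$seed, stages = out$stages, summaries = out$summaries)
    if (!is.null(out$grid)) json$grid <- out$grid
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report_md(report), file.path(config$out_dir, "report.md"))
    manifest <- data.frame(file = list.files(config$out_dir))
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  report
}

format_report_md <- function(report) {
  lines <- c("# Pulse classification run report", "",
             paste0("seed: ", report$seed),
             paste0("stages: ", paste(report$stages, collapse = " -> ")), "")
  if (!is.null(report$grid)) {
    g <- report$grid
    lines <- c(lines, "| model | accuracy | MCC | LOOCV accuracy | LOOCV MCC |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.1f%% | %.2f | %.1f%% | %.2f |",
                       g$model, 100 * g$accuracy, g$mcc,
                       100 * g$cv_accuracy, g$cv_mcc))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}

#' Serialize / load a mixed threshold model as JSON
#'
#' @param model a [mixed_threshold_model()].
#' @param path JSON file path.
#' @param standardization optional list of per-variable `center`/`scale`
#'   used to put new data on the model's z-scale.
#' @param seed optional seed recorded for provenance.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the [mixed_threshold_model()] with the standardization block
#'   attached as an attribute.
#' @export
write_model_json <- function(model, path, standardization = NULL, seed = NULL) {
  stopifnot(inherits(model, "mixed_threshold_model"))
  obj <- list(
    primary = list(var = model$primary$variable,
                   alpha = model$primary$alpha, beta = model$primary$beta),
    secondary = list(var = model$secondary$variable,
                     gamma = model$secondary$alpha, delta = model$secondary$beta),
    tie_break = model$tie_break,
    standardization = standardization,
    metadata = list(seed = seed,
                    package = "pulsedx",
                    version = as.character(utils::packageVersion("pulsedx"))))
  # JSON has no Inf; open-ended criteria are serialized as +/-1e308
  obj$primary$alpha <- min(max(obj$primary$alpha, -1e308), 1e308)
  obj$primary$beta <- min(max(obj$primary$beta, -1e308), 1e308)
  obj$secondary$gamma <- min(max(obj$secondary$gamma, -1e308), 1e308)
  obj$secondary$delta <- min(max(obj$secondary$delta, -1e308), 1e308)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- mixed_threshold_model(
    threshold_rule(obj$primary$var, obj$primary$alpha, obj$primary$beta),
    threshold_rule(obj$secondary$var, obj$secondary$gamma, obj$secondary$delta),
    tie_break = if (is.null(obj$tie_break)) "none" else obj$tie_break)
  attr(model, "standardization") <- obj$standardization
  model
}
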