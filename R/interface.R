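# Run configuration, visit-level CSV contract, and the end-to-end pipeline
# (simulate -> clean -> prune -> featurize -> split -> train -> calibrate ->
# evaluate -> track -> explain).

#' End-to-end run configuration
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param schema feature schema name.
#' @param model a [model_spec()].
#' @param split_fractions train/valid/calibration/test fractions.
#' @param split_seed seed of the patient-level split.
#' @param confidences confidence levels (percent) at which confusion tables
#'   are reported.
#' @param eps_grid significance grid for the calibration/efficiency curves.
#' @param sustain sustained-tail length for transition detection.
#' @param explain_n number of test visits attributed for the global
#'   importance summary (kept moderate: attributions are the slow stage).
#' @return object of class `run_config` with a content hash.
#' @export
run_config <- function(sim = sim_config(),
                       schema = "no_msis",
                       model = model_spec("random_forest"),
                       split_fractions = c(train = 0.65, valid = 0.05,
                                           calibration = 0.05, test = 0.25),
                       split_seed = 1L,
                       confidences = c(93, 95, 99),
                       eps_grid = seq(0.01, 0.5, 0.01),
                       sustain = 2,
                       explain_n = 200) {
  stopifnot(all(confidences > 0 & confidences < 100))
  cfg <- list(sim = sim, schema = schema, model = model,
              split_fractions = split_fractions, split_seed = split_seed,
              confidences = confidences, eps_grid = eps_grid,
              sustain = sustain, explain_n = explain_n)
  cfg$hash <- fnv1a_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Read a visit-level CSV
#'
#' Parses and validates the documented visit schema (`patient_id`,
#' ISO-8601 `visit_date`, `edss` on the half-point 0-10 grid,
#' `recorded_course`, plus the optional measurement-stream columns).
#' Unknown columns raise a warning; unparseable dates or off-grid EDSS raise
#' row-numbered validation errors; a per-patient visit cap can be enforced to
#' mirror interactive service limits.
#'
#' @param path CSV path.
#' @param max_visits per-patient visit cap (`Inf` for batch use; interactive
#'   front-ends conventionally cap at 25).
#' @return visits data frame with parsed dates.
#' @export
read_visits_csv <- function(path, max_visits = Inf) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no records in ", path, call. = FALSE)
  required <- c("patient_id", "visit_date", "edss", "recorded_course")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  known <- c(required, "sdmt", "sdmt_date", "t2_count", "t1_gd_brain_count",
             "t1_gd_spinal_count", "mri_date", "msis_physical",
             "msis_psychological", "msis_date", "treatment_drug",
             "treatment_start_date")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  dates <- as.Date(df$visit_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(df$visit_date) & df$visit_date != "")
  if (length(bad)) {
    stop("unparseable visit_date at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$visit_date <- dates
  off_grid <- which(!is.na(df$edss) &
                      (df$edss < 0 | df$edss > 10 | (df$edss * 2) %% 1 != 0))
  if (length(off_grid)) {
    stop("EDSS off the 0-10 half-point grid at row(s): ",
         paste(utils::head(off_grid, 5), collapse = ", "), call. = FALSE)
  }
  nv <- table(df$patient_id)
  over <- names(nv)[nv > max_visits]
  if (length(over)) {
    stop("patient(s) exceed the ", max_visits, "-visit cap: ",
         paste(over, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(c("sdmt_date", "mri_date", "msis_date",
                         "treatment_start_date"), names(df))) {
    df[[cl]] <- as.Date(df[[cl]])
  }
  df
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort, cleans it, prunes the undetermined RRMS tail, builds
#' features, splits patients, trains and conformally calibrates the model,
#' and evaluates validity, efficiency, confusion tables, error concentration
#' and transition timing on the test patients; a sample of test visits is
#' attributed for global feature importance. Every artifact carries the
#' configuration hash, and a metrics list is serializable to JSON.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: writes the feature matrix and
#'   prediction CSVs and a `metrics.json`.
#' @return object of class `ms_run` with the fitted calibrator, curves,
#'   confusion tables, trajectory analysis, importances, and `metrics`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cohort <- stage("simulate", simulate_cohort(config$sim))
  cleaned <- stage("clean", clean_cohort(cohort))
  pruned <- stage("prune", prune_rrms_tail(cleaned$cohort))
  features <- stage("featurize", build_features(pruned$cohort, config$schema))
  split <- stage("split", stratified_patient_split(
    pruned$cohort, config$split_fractions, config$split_seed))

  tr <- feature_matrix(split_features(features, split, "train+valid"))
  cal <- feature_matrix(split_features(features, split, "calibration"))
  te <- feature_matrix(split_features(features, split, "test"))

  model <- stage("train", train_model(config$model, tr$X, tr$y,
                                      patient_ids = tr$patient_ids,
                                      fingerprint = tr$fingerprint))
  icp <- stage("calibrate", mondrian_icp(model, cal$X, cal$y,
                                         patient_ids = cal$patient_ids,
                                         fingerprint = cal$fingerprint))

  pred <- stage("predict", predict(icp, te$X, eps = min(config$eps_grid),
                                   fingerprint = te$fingerprint))
  curve <- stage("evaluate", efficiency_curve(pred, te$y, config$eps_grid))
  cal_curve <- calibration_curve(pred, te$y, config$eps_grid)
  eps_star <- peak_confidence(curve)
  confusions <- lapply(config$confidences, function(cf) {
    list(visit = confusion_at(pred, te$y, cf, te$patient_ids, "visit"),
         patient_final = confusion_at(pred, te$y, cf, te$patient_ids,
                                      "patient_final"))
  })
  names(confusions) <- paste0("conf", config$confidences)
  sets_star <- prediction_sets(pred$p_rrms, pred$p_spms, eps_star)
  concentration <- error_concentration(sets_star, te$y, te$patient_ids)

  track <- stage("track", transition_analysis(
    pred, te$visit_dates, as.character(te$y), te$patient_ids,
    eps = eps_star, sustain = config$sustain))

  n_exp <- min(config$explain_n, nrow(te$X))
  importance <- stage("explain", if (model$kind %in%
                                     c("random_forest", "gradient_boosting")) {
    global_importance(model, te$X[seq_len(n_exp), , drop = FALSE])
  } else {
    global_importance(model, te$X[seq_len(min(n_exp, 25)), , drop = FALSE],
                      method = "sampling")
  })

  # transitioning patients only: recorded RRMS at the first visit
  trans <- track[!is.na(track$recorded) & track$recorded > 1, , drop = FALSE]
  offsets <- trans$offset_visits[!is.na(trans$offset_visits)]
  metrics <- list(
    config_hash = config$hash,
    n_patients = nrow(pruned$cohort$patients),
    n_visits = nrow(pruned$cohort$visits),
    peak_epsilon = eps_star,
    peak_confidence_pct = 100 * (1 - eps_star),
    correct_single_at_peak = curve$correct_single[curve$epsilon == eps_star],
    error_at_peak = curve$error[curve$epsilon == eps_star],
    efficiency_at_first_confidence = confusions[[1]]$visit$efficiency,
    median_offset_visits = if (length(offsets)) stats::median(offsets) else NA,
    n_transitions_scored = length(offsets),
    top_feature = importance$feature[1]
  )

  run <- structure(list(
    config = config, cohort = pruned$cohort, features = features,
    split = split, model = model, icp = icp, predictions = pred,
    test = te, efficiency = curve, calibration = cal_curve,
    peak_epsilon = eps_star, confusions = confusions,
    concentration = concentration, transitions = track,
    importance = importance, metrics = metrics,
    reports = list(clean = cleaned$report, prune = pruned$report)
  ), class = "ms_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fm <- features
    attr(fm, "schema") <- NULL
    attr(fm, "fingerprint") <- NULL
    utils::write.csv(fm, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(
      cbind(patient_id = te$patient_ids,
            visit_date = as.character(te$visit_dates), pred),
      file.path(out_dir, "predictions.csv"), row.names = FALSE)
    utils::write.csv(curve, file.path(out_dir, "efficiency_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.ms_run <- function(x, ...) {
  cat("mscourse pipeline run (config", x$config$hash, ")\n")
  cat(sprintf("  cohort: %d patients, %d visits after QC\n",
              x$metrics$n_patients, x$metrics$n_visits))
  cat(sprintf("  peak single-label confidence: %.0f%% (significance %.2f)\n",
              x$metrics$peak_confidence_pct, x$metrics$peak_epsilon))
  cat(sprintf("  correct single-label fraction at peak: %.1f%%\n",
              100 * x$metrics$correct_single_at_peak))
  cat(sprintf("  transitions scored: %d (median offset %s visits)\n",
              x$metrics$n_transitions_scored,
              format(x$metrics$median_offset_visits)))
  invisible(x)
}
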