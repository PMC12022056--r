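# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal hand-built cohort: one patient, explicit visits/relapses. Used for
# the feature-rule fixtures where every expected value is hand-computed.
manual_cohort <- function(visits, relapses = NULL, patients = NULL,
                          ground_truth = NULL) {
  if (is.null(relapses)) {
    relapses <- data.frame(patient_id = character(0),
                           relapse_date = as.Date(character(0)),
                           category = character(0),
                           steroid_treated = integer(0),
                           remission = integer(0))
  }
  if (is.null(patients)) {
    ids <- unique(visits$patient_id)
    patients <- data.frame(patient_id = ids, sex = "F",
                           birth_date = as.Date("1970-01-01"),
                           debut_date = as.Date("2000-01-01"),
                           debut_relapse_date = as.Date("2000-01-01"))
  }
  if (is.null(ground_truth)) {
    ground_truth <- data.frame(patient_id = unique(visits$patient_id),
                               archetype = NA_character_,
                               true_transition_date = as.Date(NA),
                               recorded_transition_date = as.Date(NA))
  }
  structure(list(patients = patients, visits = visits, relapses = relapses,
                 ground_truth = ground_truth, config = NULL),
            class = "ms_cohort")
}

# A visit row with all optional streams missing.
visit_row <- function(patient_id, visit_date, edss = 2,
                      recorded_course = "RRMS", ...) {
  base <- data.frame(
    patient_id = patient_id, visit_date = as.Date(visit_date), edss = edss,
    recorded_course = recorded_course,
    sdmt = NA_real_, sdmt_date = as.Date(NA),
    t2_count = NA_integer_, t1_gd_brain_count = NA_integer_,
    t1_gd_spinal_count = NA_integer_, mri_date = as.Date(NA),
    msis_physical = NA_real_, msis_psychological = NA_real_,
    msis_date = as.Date(NA),
    treatment_drug = NA_character_, treatment_start_date = as.Date(NA),
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# Bare calibrator around explicit score lists: exercises the rank-counting
# machinery directly, independent of any model.
make_calibrator <- function(scores_rrms, scores_spms = scores_rrms) {
  structure(list(
    scores = list(RRMS = sort(scores_rrms), SPMS = sort(scores_spms)),
    n = c(RRMS = length(scores_rrms), SPMS = length(scores_spms)),
    model = NULL, fingerprint = NULL), class = "mondrian_icp")
}

# Brute-force conformal p-value oracle: explicit loop counting with the test point as its
# own (n+1)-th element, ties counted as >=.
oracle_pvalue <- function(scores, alpha) {
  all_scores <- c(scores, alpha)
  count <- 0
  for (s in all_scores) if (s >= alpha) count <- count + 1
  count / (length(scores) + 1)
}

# Fit the standard pipeline on a synthetic cohort and return the pieces.
fit_pipeline <- function(n_patients, seed, class_separation = 1,
                         delay = list(mean = 3, sd = 1),
                         prune = TRUE, kind = "random_forest") {
  cfg <- sim_config(n_patients = n_patients, seed = seed,
                    class_separation = class_separation,
                    label_delay_years = delay)
  cohort <- clean_cohort(simulate_cohort(cfg))$cohort
  if (prune) cohort <- prune_rrms_tail(cohort)$cohort
  features <- build_features(cohort)
  split <- stratified_patient_split(cohort, seed = seed)
  tr <- feature_matrix(split_features(features, split, "train+valid"))
  cal <- feature_matrix(split_features(features, split, "calibration"))
  te <- feature_matrix(split_features(features, split, "test"))
  model <- train_model(model_spec(kind), tr$X, tr$y,
                       patient_ids = tr$patient_ids,
                       fingerprint = tr$fingerprint)
  icp <- mondrian_icp(model, cal$X, cal$y, patient_ids = cal$patient_ids,
                      fingerprint = cal$fingerprint)
  list(cohort = cohort, features = features, split = split,
       train = tr, cal = cal, test = te, model = model, icp = icp)
}

# Two well-separated Gaussian blobs (linearly separable toy problem).
toy_blobs <- function(n = 200, seed = 1, gap = 6) {
  set.seed(seed)
  half <- n / 2
  X <- rbind(matrix(rnorm(half * 2), ncol = 2),
             matrix(rnorm(half * 2, mean = gap), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("RRMS", "SPMS"), each = half), levels = c("RRMS", "SPMS"))
  list(X = X, y = y)
}
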