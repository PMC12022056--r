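#' Feature schemas
#'
#' Three nested per-visit feature schemas. `no_msis` (the default, 27
#' features) is the working set after dropping the patient-reported MSIS-29
#' subscales; `full` adds them back; `basic_relapse` keeps only demographics,
#' EDSS and relapse-derived features. All missing entries are encoded as -1.
#'
#' @param name one of `"full"`, `"no_msis"`, `"basic_relapse"`.
#' @return list with `name`, ordered `features`, and per-feature `kind`
#'   (`continuous`, `binary`, or `ordinal_bin`).
#' @export
feature_schema <- function(name = c("no_msis", "full", "basic_relapse")) {
  name <- match.arg(name)
  basic <- c(
    edss = "continuous", age_at_visit = "continuous", sex = "binary",
    debut_age = "continuous", age_at_debut_relapse = "continuous",
    disease_duration = "continuous",
    n_relapses_total = "continuous", n_optic_neuritis = "continuous",
    n_monofocal = "continuous", n_multifocal = "continuous",
    n_steroid_treated_relapses = "continuous",
    last_relapse_steroid_treated = "binary", last_relapse_remission = "binary",
    age_at_last_relapse = "continuous", n_visits_to_date = "continuous")
  no_msis <- c(basic, c(
    sdmt_score = "continuous", age_at_sdmt = "continuous",
    current_treatment_category = "ordinal_bin",
    first_line_dmt_flag = "binary", second_line_dmt_flag = "binary",
    stem_cell_flag = "binary", other_drug_flag = "binary",
    age_at_treatment_start = "continuous",
    t2_lesion_bin = "ordinal_bin", t1_gd_brain_bin = "ordinal_bin",
    t1_gd_spinal_bin = "ordinal_bin", age_at_mri = "continuous"))
  full <- c(no_msis, c(
    msis_physical = "continuous", msis_psychological = "continuous",
    age_at_msis = "continuous"))
  kinds <- switch(name, basic_relapse = basic, no_msis = no_msis, full = full)
  list(name = name, features = names(kinds), kinds = unname(kinds))
}

# -- cleaning -----------------------------------------------------------------

#' Clean a cohort: drop duplicates and visits missing essential fields
#'
#' Exact-duplicate visit rows are dropped, then visits missing the EDSS score
#' or course label, and all visits of patients missing their birth date or
#' debut date. Patients left without visits are removed. Visits are returned
#' sorted by patient and date.
#'
#' @param cohort an `ms_cohort`.
#' @return list with elements `cohort` (cleaned) and `report` (named counts
#'   of each removal reason plus removed patient ids).
#' @export
clean_cohort <- function(cohort) {
  v <- cohort$visits
  p <- cohort$patients
  report <- list(duplicate_rows = 0L, missing_edss = 0L, missing_course = 0L,
                 missing_birth_date = 0L, missing_debut_date = 0L,
                 patients_removed = character(0))

  dup <- duplicated(v)
  report$duplicate_rows <- sum(dup)
  v <- v[!dup, , drop = FALSE]

  bad_edss <- is.na(v$edss)
  report$missing_edss <- sum(bad_edss)
  v <- v[!bad_edss, , drop = FALSE]

  bad_course <- is.na(v$recorded_course) | !(v$recorded_course %in% CLASS_LEVELS)
  report$missing_course <- sum(bad_course)
  v <- v[!bad_course, , drop = FALSE]

  no_birth <- p$patient_id[is.na(p$birth_date)]
  no_debut <- p$patient_id[is.na(p$debut_date)]
  report$missing_birth_date <- sum(v$patient_id %in% no_birth)
  report$missing_debut_date <-
    sum(v$patient_id %in% setdiff(no_debut, no_birth))
  v <- v[!(v$patient_id %in% c(no_birth, no_debut)), , drop = FALSE]

  kept <- unique(v$patient_id)
  report$patients_removed <- setdiff(p$patient_id, kept)

  v <- v[order(v$patient_id, v$visit_date), , drop = FALSE]
  rownames(v) <- NULL
  out <- cohort
  out$visits <- v
  out$patients <- p[p$patient_id %in% kept, , drop = FALSE]
  out$relapses <- cohort$relapses[cohort$relapses$patient_id %in% kept, , drop = FALSE]
  out$ground_truth <- cohort$ground_truth[
    cohort$ground_truth$patient_id %in% kept, , drop = FALSE]
  list(cohort = out, report = report)
}

#' Remove the undetermined tail of RRMS-only patients
#'
#' For patients whose every visit carries an RRMS course label, the clinical
#' endpoint at recent visits is not yet known (a transition may simply not
#' have been recorded yet), so all visits dated within `window_years` of that
#' patient's last visit are removed - including the anchoring last visit
#' itself. Patients with any SPMS visit are untouched. Patients left without
#' visits are dropped and logged.
#'
#' @param cohort an `ms_cohort` (cleaned).
#' @param window_years width of the pruned tail window in years.
#' @return list with `cohort` and `report` (visits removed, patients dropped).
#' @export
prune_rrms_tail <- function(cohort, window_years = 2) {
  v <- cohort$visits
  spms_pat <- unique(v$patient_id[v$recorded_course == "SPMS"])
  rrms_only <- setdiff(unique(v$patient_id), spms_pat)
  drop <- rep(FALSE, nrow(v))
  for (pid in rrms_only) {
    idx <- which(v$patient_id == pid)
    last <- max(v$visit_date[idx])
    cutoff <- last - round(window_years * DAYS_PER_YEAR)
    drop[idx[v$visit_date[idx] >= cutoff]] <- TRUE
  }
  removed <- sum(drop)
  v <- v[!drop, , drop = FALSE]
  kept <- unique(v$patient_id)
  dropped_patients <- setdiff(rrms_only, kept)
  out <- cohort
  out$visits <- v
  out$patients <- cohort$patients[cohort$patients$patient_id %in% kept, , drop = FALSE]
  out$relapses <- cohort$relapses[cohort$relapses$patient_id %in% kept, , drop = FALSE]
  out$ground_truth <- cohort$ground_truth[
    cohort$ground_truth$patient_id %in% kept, , drop = FALSE]
  list(cohort = out,
       report = list(visits_removed = removed,
                     patients_dropped = dropped_patients))
}

# -- derivation rules ---------------------------------------------------------

#' Bin an MRI lesion count into three ordinal groups
#'
#' Counts of 0-9 map to bin 1, 10-20 to bin 2, 21 and above to bin 3;
#' missing counts map to -1.
#'
#' @param count non-negative integer vector (NAs allowed).
#' @return integer vector of bins in `{-1, 1, 2, 3}`.
#' @export
#' @examples
#' bin_lesions(c(0, 9, 10, 20, 21, NA))
bin_lesions <- function(count) {
  if (any(count < 0, na.rm = TRUE)) {
    stop("lesion counts must be non-negative", call. = FALSE)
  }
  out <- rep(-1L, length(count))
  ok <- !is.na(count)
  out[ok] <- ifelse(count[ok] <= 9, 1L, ifelse(count[ok] <= 20, 2L, 3L))
  out
}

TREATMENT_CATEGORIES <- c(first_line = 1L, second_line = 2L, relapse_drug = 3L,
                          stem_cell = 4L, other = 5L)

#' Drug-to-category lookup table
#'
#' Reads the editable lookup shipped in `inst/extdata/drug_categories.csv`
#' mapping drug names to treatment categories (first-line DMT, second-line
#' DMT, relapse treatment, stem cell treatment, other).
#'
#' @return data frame with columns `drug` and `category`.
#' @export
drug_lookup <- function() {
  path <- system.file("extdata", "drug_categories.csv", package = "mscourse")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Categorize a treatment drug
#'
#' Case-insensitive lookup; unknown drugs fall back to `"other"` with a
#' warning so the lookup table can be extended.
#'
#' @param drug_name character vector of drug names (NAs allowed).
#' @param lookup lookup table as from [drug_lookup()].
#' @return character vector of categories (`NA` where `drug_name` is `NA`).
#' @export
categorize_treatment <- function(drug_name, lookup = drug_lookup()) {
  idx <- match(tolower(drug_name), tolower(lookup$drug))
  out <- lookup$category[idx]
  unknown <- !is.na(drug_name) & is.na(out)
  if (any(unknown)) {
    warning("unknown drug(s) mapped to 'other': ",
            paste(unique(drug_name[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "other"
  }
  out
}

#' Cumulative relapse counts up to a visit date
#'
#' Counts relapse events per category with event date on or before each visit
#' date ("until the day of the hospital visit"), plus binary flags for the
#' last relapse's steroid treatment and remission (both -1 when no relapse
#' has occurred yet).
#'
#' @param relapses data frame of one patient's relapse events
#'   (`relapse_date`, `category`, `steroid_treated`, `remission`).
#' @param visit_dates Date vector (need not be sorted).
#' @return data frame with one row per visit date: per-category counts,
#'   total, steroid-treated count, last-relapse flags and last relapse date.
#' @export
cumulate_relapses <- function(relapses, visit_dates) {
  nv <- length(visit_dates)
  ord <- order(relapses$relapse_date)
  relapses <- relapses[ord, , drop = FALSE]
  rd <- as.numeric(relapses$relapse_date)
  vd <- as.numeric(as.Date(visit_dates))
  count_upto <- function(dates) findInterval(vd, sort(dates))
  counts <- sapply(RELAPSE_CATEGORIES, function(cat) {
    count_upto(rd[relapses$category == cat])
  })
  if (nv == 1) counts <- matrix(counts, nrow = 1,
                                dimnames = list(NULL, RELAPSE_CATEGORIES))
  n_total <- count_upto(rd)
  n_steroid <- count_upto(rd[relapses$steroid_treated == 1])
  last_idx <- findInterval(vd, rd)
  has_last <- last_idx >= 1
  data.frame(
    n_relapses_total = n_total,
    n_optic_neuritis = counts[, "optic_neuritis"],
    n_monofocal = counts[, "monofocal"],
    n_multifocal = counts[, "multifocal"],
    n_steroid_treated_relapses = n_steroid,
    last_relapse_steroid_treated =
      ifelse(has_last, relapses$steroid_treated[pmax(last_idx, 1)], -1L),
    last_relapse_remission =
      ifelse(has_last, relapses$remission[pmax(last_idx, 1)], -1L),
    last_relapse_date = as.Date(
      ifelse(has_last, rd[pmax(last_idx, 1)], NA), origin = "1970-01-01")
  )
}

#' Per-visit feature vectors for one patient (carry-forward)
#'
#' Each visit's vector uses the most recent prior-or-same-day observation of
#' every measurement stream (SDMT, MRI, MSIS-29, treatment), together with
#' the patient's age at that measurement; streams never observed up to a
#' visit are encoded -1. Relapse features are cumulative counts to the visit
#' date. Visits must be chronologically sorted (clean_cohort's contract).
#'
#' @param patient one-row data frame of patient-level fields.
#' @param visits this patient's visits, sorted by date.
#' @param relapses this patient's relapse events.
#' @param schema a [feature_schema()].
#' @param lookup drug lookup table.
#' @return data frame: `patient_id`, `visit_date`, `recorded_course` plus the
#'   schema's feature columns.
#' @export
carry_forward_features <- function(patient, visits, relapses,
                                   schema = feature_schema("no_msis"),
                                   lookup = drug_lookup()) {
  if (is.unsorted(visits$visit_date)) {
    stop("visits must be sorted by date; run clean_cohort first", call. = FALSE)
  }
  nv <- nrow(visits)
  birth <- patient$birth_date
  m1 <- function(x) ifelse(is.na(x), -1, x)

  rel <- cumulate_relapses(relapses, visits$visit_date)

  sdmt <- locf(visits$sdmt)
  sdmt_date <- as.Date(locf(as.numeric(visits$sdmt_date)), origin = "1970-01-01")
  t2 <- locf(visits$t2_count)
  gdb <- locf(visits$t1_gd_brain_count)
  gds <- locf(visits$t1_gd_spinal_count)
  mri_date <- as.Date(locf(as.numeric(visits$mri_date)), origin = "1970-01-01")
  msis_p <- locf(visits$msis_physical)
  msis_q <- locf(visits$msis_psychological)
  msis_date <- as.Date(locf(as.numeric(visits$msis_date)), origin = "1970-01-01")

  treat_cat <- categorize_treatment(visits$treatment_drug, lookup)
  cur_cat <- locf(treat_cat)
  treat_start <- as.Date(locf(as.numeric(visits$treatment_start_date)),
                         origin = "1970-01-01")
  ever_flag <- function(cat) {
    as.integer(cumsum(!is.na(treat_cat) & treat_cat == cat) > 0)
  }

  out <- data.frame(
    patient_id = visits$patient_id,
    visit_date = visits$visit_date,
    recorded_course = visits$recorded_course,
    edss = visits$edss,
    age_at_visit = age_at(birth, visits$visit_date),
    sex = as.integer(patient$sex == "F"),
    debut_age = age_at(birth, patient$debut_date),
    age_at_debut_relapse = age_at(birth, patient$debut_relapse_date),
    disease_duration = round(years_between(patient$debut_date, visits$visit_date), 1),
    sdmt_score = m1(sdmt),
    age_at_sdmt = age_at(birth, sdmt_date),
    current_treatment_category =
      m1(unname(TREATMENT_CATEGORIES[cur_cat])),
    first_line_dmt_flag = ever_flag("first_line"),
    second_line_dmt_flag = ever_flag("second_line"),
    stem_cell_flag = ever_flag("stem_cell"),
    other_drug_flag = as.integer(
      (cumsum(!is.na(treat_cat) & treat_cat %in% c("other", "relapse_drug"))) > 0),
    age_at_treatment_start = age_at(birth, treat_start),
    n_relapses_total = rel$n_relapses_total,
    n_optic_neuritis = rel$n_optic_neuritis,
    n_monofocal = rel$n_monofocal,
    n_multifocal = rel$n_multifocal,
    n_steroid_treated_relapses = rel$n_steroid_treated_relapses,
    last_relapse_steroid_treated = rel$last_relapse_steroid_treated,
    last_relapse_remission = rel$last_relapse_remission,
    age_at_last_relapse = age_at(birth, rel$last_relapse_date),
    t2_lesion_bin = bin_lesions(t2),
    t1_gd_brain_bin = bin_lesions(gdb),
    t1_gd_spinal_bin = bin_lesions(gds),
    age_at_mri = age_at(birth, mri_date),
    n_visits_to_date = seq_len(nv),
    msis_physical = m1(msis_p),
    msis_psychological = m1(msis_q),
    age_at_msis = age_at(birth, msis_date),
    stringsAsFactors = FALSE
  )
  out[, c("patient_id", "visit_date", "recorded_course", schema$features)]
}

#' Build the per-visit feature matrix for a whole cohort
#'
#' Applies [carry_forward_features()] patient by patient and stacks the
#' results. The returned data frame carries the schema as an attribute and a
#' schema fingerprint used to guard model/data mismatches.
#'
#' @param cohort an `ms_cohort` (cleaned).
#' @param schema schema name or a [feature_schema()] object.
#' @return data frame of per-visit feature vectors with attributes `schema`
#'   and `fingerprint`.
#' @export
build_features <- function(cohort, schema = "no_msis") {
  if (is.character(schema)) schema <- feature_schema(schema)
  lookup <- drug_lookup()
  ids <- unique(cohort$visits$patient_id)
  vsplit <- split(cohort$visits, cohort$visits$patient_id)
  rsplit <- split(cohort$relapses, cohort$relapses$patient_id)
  psplit <- split(cohort$patients, cohort$patients$patient_id)
  empty_rel <- cohort$relapses[0, , drop = FALSE]
  rows <- lapply(ids, function(pid) {
    carry_forward_features(psplit[[pid]], vsplit[[pid]],
                           if (pid %in% names(rsplit)) rsplit[[pid]] else empty_rel,
                           schema, lookup)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schema") <- schema
  attr(out, "fingerprint") <- schema_fingerprint(schema)
  out
}

#' @keywords internal
schema_fingerprint <- function(schema) {
  paste(schema$name, paste(schema$features, collapse = ","), sep = "|")
}

# -- splitting ----------------------------------------------------------------

#' Archetype of each patient from its recorded course labels
#'
#' @param visits visits data frame with `patient_id` and `recorded_course`.
#' @return named character vector patient_id -> archetype.
#' @export
patient_archetypes <- function(visits) {
  f <- function(lab) {
    if (all(lab == "RRMS")) "rrms_only"
    else if (all(lab == "SPMS")) "spms_only"
    else "transitioning"
  }
  vapply(split(visits$recorded_course, visits$patient_id), f, character(1))
}

#' Stratified patient-level split into train / valid / calibration / test
#'
#' Patients (never individual visits) are allocated to the four sets, within
#' each archetype stratum, by a seeded shuffle followed by largest-remainder
#' rounding of the fractions, so every archetype's share of each set is
#' within one patient of its proportional allocation.
#'
#' @param cohort an `ms_cohort`.
#' @param fractions numeric vector of four fractions summing to 1
#'   (train, valid, calibration, test).
#' @param seed integer seed for the within-stratum shuffle.
#' @return object of class `cohort_split`: list of patient-id vectors
#'   `train`, `valid`, `calibration`, `test`, plus `fractions`, `seed` and a
#'   `fingerprint`.
#' @export
stratified_patient_split <- function(cohort,
                                     fractions = c(train = 0.65, valid = 0.05,
                                                   calibration = 0.05, test = 0.25),
                                     seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 4) {
    stop("fractions must be four numbers summing to 1", call. = FALSE)
  }
  arch <- patient_archetypes(cohort$visits)
  sets <- list(train = character(0), valid = character(0),
               calibration = character(0), test = character(0))
  set.seed(seed)
  for (a in unique(arch)) {
    ids <- sample(names(arch)[arch == a])
    counts <- largest_remainder(length(ids), fractions)
    stops <- cumsum(counts)
    starts <- c(1, head(stops, -1) + 1)
    for (k in 1:4) {
      if (counts[k] > 0) {
        sets[[k]] <- c(sets[[k]], ids[starts[k]:stops[k]])
      }
    }
  }
  sets <- lapply(sets, sort)
  structure(c(sets, list(fractions = fractions, seed = seed,
                         fingerprint = fnv1a_hash(sets))),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("Patient-level cohort split (seed", x$seed, "):\n")
  for (s in c("train", "valid", "calibration", "test")) {
    cat(sprintf("  %-12s %d patients\n", s, length(x[[s]])))
  }
  invisible(x)
}

#' Extract the feature rows of one split set
#'
#' @param features feature data frame from [build_features()].
#' @param split a `cohort_split`.
#' @param set one of `"train"`, `"valid"`, `"calibration"`, `"test"`; or
#'   `"train+valid"` for the merged training set used by the classical models.
#' @return the subset of `features` (attributes preserved).
#' @export
split_features <- function(features, split, set) {
  ids <- if (set == "train+valid") c(split$train, split$valid) else split[[set]]
  out <- features[features$patient_id %in% ids, , drop = FALSE]
  attr(out, "schema") <- attr(features, "schema")
  attr(out, "fingerprint") <- attr(features, "fingerprint")
  out
}

#' Numeric feature matrix and label vector from a feature data frame
#'
#' @param features feature data frame (possibly subset by [split_features()]).
#' @return list with matrix `X`, factor `y` (levels RRMS, SPMS), character
#'   `patient_ids`, Date `visit_dates`, and the schema `fingerprint`.
#' @export
feature_matrix <- function(features) {
  meta <- c("patient_id", "visit_date", "recorded_course")
  X <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X,
       y = factor(features$recorded_course, levels = CLASS_LEVELS),
       patient_ids = features$patient_id,
       visit_dates = features$visit_date,
       fingerprint = attr(features, "fingerprint"))
}
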