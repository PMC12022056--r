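#' Simulation configuration for a registry-like MS cohort
#'
#' Builds a validated configuration for [simulate_cohort()]. The defaults
#' describe a cohort with three patient archetypes at the proportions seen in
#' real registry test splits (68% relapsing-remitting throughout, 19%
#' secondary progressive throughout, 13% transitioning during observation),
#' irregular visit spacing, per-stream missingness, and a clinician labelling
#' delay averaging three years after the true transition.
#'
#' @param n_patients number of patients to simulate.
#' @param frac_rrms_only,frac_spms_only,frac_transitioning archetype
#'   proportions; must be in `[0, 1]` and sum to 1 (tolerance 1e-9).
#' @param mean_visits_per_patient Poisson mean of per-patient visit counts
#'   (floored at 2 visits).
#' @param visit_interval_months list with `mean` (months between visits) and
#'   gamma `shape` controlling jitter.
#' @param transition_hazard list with `base`, `age_coef`, `duration_coef`:
#'   relative per-interval transition weights increase with age and disease
#'   duration (only relative weights matter; the transition is conditioned to
#'   fall inside the observation window for transitioning patients).
#' @param edss_dynamics list: `baseline_mean`, `spike` (EDSS jump at a
#'   relapse), `recovery` (fraction of the spike that resolves),
#'   `recovery_tau_years` (transient decay scale), `drift_rrms`, `drift_spms`
#'   (EDSS points/year of initial progressive drift per state), and
#'   `drift_ceiling` (maximum progressive accumulation; the drift saturates
#'   exponentially toward it because the EDSS scale is bounded and
#'   progression decelerates at high scores).
#' @param relapse_rate_rrms,relapse_rate_spms relapse events per year in each
#'   true state.
#' @param label_delay_years list with `mean` and `sd` of the truncated-at-zero
#'   normal clinician labelling delay (years) applied to the recorded course
#'   label only.
#' @param missingness named vector of per-visit probabilities that a stream
#'   (`sdmt`, `mri`, `msis`) is *not* measured at a visit.
#' @param class_separation scalar scaling how strongly the relapse rates and
#'   EDSS/SDMT drifts differ between the two true states. At 0 both states
#'   share the average dynamics (increments are identically distributed); 1
#'   gives the nominal difference; larger values exaggerate it.
#' @param seed integer RNG seed; per-patient sub-streams are derived from it
#'   so cohorts are reproducible patient-by-patient.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 7)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_patients = 1000,
                       frac_rrms_only = 0.68,
                       frac_spms_only = 0.19,
                       frac_transitioning = 0.13,
                       mean_visits_per_patient = 9,
                       visit_interval_months = list(mean = 9, shape = 4),
                       transition_hazard = list(base = 0.05, age_coef = 0.004,
                                                duration_coef = 0.008),
                       edss_dynamics = list(baseline_mean = 1.5, spike = 1.5,
                                            recovery = 0.8,
                                            recovery_tau_years = 0.15,
                                            drift_rrms = 0.05,
                                            drift_spms = 0.45,
                                            drift_ceiling = 4.5),
                       relapse_rate_rrms = 0.45,
                       relapse_rate_spms = 0.12,
                       label_delay_years = list(mean = 3, sd = 1),
                       missingness = c(sdmt = 0.5, mri = 0.6, msis = 0.5),
                       class_separation = 1,
                       seed = 1L) {
  fracs <- c(frac_rrms_only, frac_spms_only, frac_transitioning)
  if (any(fracs < 0) || any(fracs > 1) || abs(sum(fracs) - 1) > 1e-9) {
    stop("archetype proportions must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (relapse_rate_rrms < 0 || relapse_rate_spms < 0) {
    stop("relapse rates must be non-negative", call. = FALSE)
  }
  if (label_delay_years$mean < 0 || label_delay_years$sd < 0) {
    stop("label delay parameters must be non-negative", call. = FALSE)
  }
  if (class_separation < 0) stop("class_separation must be >= 0", call. = FALSE)
  stopifnot(all(c("sdmt", "mri", "msis") %in% names(missingness)),
            all(missingness >= 0 & missingness <= 1))
  structure(list(
    n_patients = as.integer(n_patients),
    fracs = fracs,
    mean_visits_per_patient = mean_visits_per_patient,
    visit_interval_months = visit_interval_months,
    transition_hazard = transition_hazard,
    edss_dynamics = edss_dynamics,
    relapse_rate_rrms = relapse_rate_rrms,
    relapse_rate_spms = relapse_rate_spms,
    label_delay_years = label_delay_years,
    missingness = missingness,
    class_separation = class_separation,
    seed = as.integer(seed)
  ), class = "sim_config")
}

ARCHETYPES <- c("rrms_only", "spms_only", "transitioning")

RELAPSE_CATEGORIES <- c("optic_neuritis", "monofocal", "multifocal", "other")

# State-specific parameter after mixing toward the between-state average by
# class_separation s: s = 0 collapses both states onto the average, s = 1 is
# the nominal difference, s > 1 exaggerates it.
mix_param <- function(value_state, value_other, s, floor = 0) {
  avg <- (value_state + value_other) / 2
  pmax(floor, avg + s * (value_state - avg))
}

#' Simulate a registry-like longitudinal MS cohort
#'
#' Generates `n_patients` synthetic patients with longitudinal hospital
#' visits. True disease state follows the archetype: relapsing-remitting
#' throughout, secondary progressive throughout (transition before the first
#' visit), or transitioning inside the observation window (latent transition
#' drawn with a hazard increasing in age and disease duration). EDSS follows
#' relapse-spike-and-partial-recovery dynamics in RRMS and progressive drift
#' in SPMS; SDMT, MRI lesion counts, MSIS-29 subscales and treatment events
#' are generated per visit with per-stream missingness. The *recorded* course
#' label switches to SPMS only after a truncated-normal clinician delay.
#'
#' @param config a [sim_config()].
#' @return an object of class `ms_cohort`: a list with data frames
#'   `patients` (one row per patient), `visits` (one row per visit),
#'   `relapses` (one row per relapse event), `ground_truth` (patient_id,
#'   archetype, true/recorded transition dates), plus the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- largest_remainder(config$n_patients, config$fracs)
  archetypes <- rep(ARCHETYPES, times = counts)
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    patients[[i]] <- simulate_patient(
      archetype = archetypes[i],
      config = config,
      patient_id = sprintf("P%05d", i),
      seed = derive_seed(config$seed, i)
    )
  }
  cohort <- structure(list(
    patients = do.call(rbind, lapply(patients, `[[`, "patient")),
    visits = do.call(rbind, lapply(patients, `[[`, "visits")),
    relapses = do.call(rbind, lapply(patients, `[[`, "relapses")),
    ground_truth = do.call(rbind, lapply(patients, `[[`, "ground_truth")),
    config = config
  ), class = "ms_cohort")
  rownames(cohort$visits) <- NULL
  rownames(cohort$relapses) <- NULL
  rownames(cohort$patients) <- NULL
  rownames(cohort$ground_truth) <- NULL
  cohort
}

#' Simulate a single patient
#'
#' Workhorse behind [simulate_cohort()]; exposed so the per-archetype
#' dynamics can be tested in isolation.
#'
#' @param archetype one of `"rrms_only"`, `"spms_only"`, `"transitioning"`.
#' @param config a [sim_config()].
#' @param patient_id identifier string.
#' @param seed per-patient sub-seed.
#' @return list with data frames `patient`, `visits`, `relapses`,
#'   `ground_truth` for this patient.
#' @export
simulate_patient <- function(archetype, config, patient_id = "P00001",
                             seed = 1L) {
  archetype <- match.arg(archetype, ARCHETYPES)
  set.seed(seed)
  s <- config$class_separation
  ed <- config$edss_dynamics

  sex <- if (stats::runif(1) < 0.71) "F" else "M"
  debut_age <- min(55, max(15, stats::rnorm(1, 30, 8)))
  debut_date <- as.Date("1995-01-01") + floor(stats::runif(1, 0, 7300))
  birth_date <- add_years(debut_date, -debut_age)

  # visit schedule: observation starts some years into the disease (patients
  # recorded SPMS throughout enter follow-up late, typically after more than
  # a decade of disease, mirroring the longer duration and higher disability
  # of progressive patients), then gamma-jittered visit intervals
  n_visits <- max(2L, stats::rpois(1, config$mean_visits_per_patient))
  if (archetype == "transitioning") n_visits <- max(3L, n_visits)
  vim <- config$visit_interval_months
  spms_tt_years <- stats::rgamma(1, shape = 4, scale = 2.5)  # onset->SPMS
  first_gap <- switch(archetype,  # months from debut to first recorded visit
    rrms_only = 12 * stats::rgamma(1, shape = 2, scale = 2),
    transitioning = 12 * stats::rgamma(1, shape = 2, scale = 1),
    spms_only = 12 * (spms_tt_years +
                        rtruncnorm0(1, config$label_delay_years$mean,
                                    config$label_delay_years$sd)))
  gaps <- stats::rgamma(n_visits - 1, shape = vim$shape,
                        scale = vim$mean / vim$shape)
  visit_months <- first_gap + c(0, cumsum(gaps))
  visit_dates <- add_months(debut_date, visit_months)

  # latent transition
  true_transition <- as.Date(NA)
  if (archetype == "spms_only") {
    # transitioned before observation started
    true_transition <- add_years(debut_date, spms_tt_years)
  } else if (archetype == "transitioning") {
    # pick the interval in which the transition falls, weighted by a hazard
    # increasing with age and disease duration
    th <- config$transition_hazard
    mid_ages <- debut_age + (visit_months[-n_visits] + visit_months[-1]) / 24
    mid_dur <- (visit_months[-n_visits] + visit_months[-1]) / 24
    w <- pmax(1e-6, th$base + th$age_coef * (mid_ages - 30) +
                th$duration_coef * mid_dur)
    k <- sample.int(n_visits - 1, 1, prob = w)
    u <- stats::runif(1)
    true_transition <- visit_dates[k] +
      floor(u * as.numeric(visit_dates[k + 1] - visit_dates[k]))
    # delayed clinician label; extend the schedule until it is recorded
    delay <- rtruncnorm0(1, config$label_delay_years$mean,
                         config$label_delay_years$sd)
    recorded_transition <- add_years(true_transition, delay)
    while (visit_dates[length(visit_dates)] < recorded_transition) {
      gap <- stats::rgamma(1, shape = vim$shape, scale = vim$mean / vim$shape)
      visit_dates <- c(visit_dates, add_months(visit_dates[length(visit_dates)], gap))
    }
    n_visits <- length(visit_dates)
    visit_months <- as.numeric(visit_dates - debut_date) / DAYS_PER_MONTH
  }

  recorded_transition <- switch(archetype,
    rrms_only = as.Date(NA),
    spms_only = visit_dates[1],
    transitioning = recorded_transition)

  t_trans_years <- if (is.na(true_transition)) Inf else
    years_between(debut_date, true_transition)

  # effective (class_separation-mixed) state dynamics
  rate_rrms <- mix_param(config$relapse_rate_rrms, config$relapse_rate_spms, s)
  rate_spms <- mix_param(config$relapse_rate_spms, config$relapse_rate_rrms, s)
  drift_rrms <- mix_param(ed$drift_rrms, ed$drift_spms, s, floor = -0.1)
  drift_spms <- mix_param(ed$drift_spms, ed$drift_rrms, s, floor = -0.1)
  sdmt_drift_rrms <- -mix_param(0.3, 1.8, s)
  sdmt_drift_spms <- -mix_param(1.8, 0.3, s)
  gad_brain_rrms <- mix_param(0.6, 0.1, s)
  gad_brain_spms <- mix_param(0.1, 0.6, s)
  gad_spinal_rrms <- mix_param(0.20, 0.05, s)
  gad_spinal_spms <- mix_param(0.05, 0.20, s)

  horizon <- visit_months[n_visits] / 12
  seg_rrms <- max(0, min(t_trans_years, horizon))
  seg_spms <- max(0, horizon - seg_rrms)

  # relapse events (debut relapse always present at the debut date)
  n_rel_r <- stats::rpois(1, rate_rrms * seg_rrms)
  n_rel_s <- stats::rpois(1, rate_spms * seg_spms)
  rel_times <- sort(c(0, stats::runif(n_rel_r, 0, seg_rrms),
                      stats::runif(n_rel_s, seg_rrms, horizon)))
  n_rel <- length(rel_times)
  rel_cat <- sample(RELAPSE_CATEGORIES, n_rel, replace = TRUE,
                    prob = c(0.25, 0.35, 0.25, 0.15))
  rel_steroid <- stats::rbinom(n_rel, 1, ifelse(rel_cat == "multifocal", 0.65, 0.45))
  rel_in_spms <- rel_times > t_trans_years
  rel_remission <- stats::rbinom(n_rel, 1, ifelse(rel_in_spms, 0.4, 0.85))
  rel_dates <- add_years(debut_date, rel_times)

  relapses <- data.frame(
    patient_id = rep(patient_id, n_rel),
    relapse_date = rel_dates,
    category = rel_cat,
    steroid_treated = as.integer(rel_steroid),
    remission = as.integer(rel_remission),
    stringsAsFactors = FALSE
  )

  # EDSS at visit times: baseline + state drift + relapse residuals and
  # decaying transients
  baseline <- max(0, min(4, stats::rnorm(1, ed$baseline_mean, 0.7)))
  t_vis <- visit_months / 12
  # progressive disability accrues with a state-dependent slope but saturates
  # (the EDSS scale is bounded and progression decelerates at high scores)
  raw_int <- drift_rrms * pmin(t_vis, t_trans_years) +
    drift_spms * pmax(0, t_vis - t_trans_years)
  dmax <- ed$drift_ceiling
  drift_int <- dmax * (1 - exp(-raw_int / dmax))
  relapse_effect <- vapply(t_vis, function(tv) {
    past <- rel_times[rel_times <= tv]
    if (!length(past)) return(0)
    dt <- tv - past
    sum(ed$spike * ((1 - ed$recovery) +
                      ed$recovery * exp(-dt / ed$recovery_tau_years)))
  }, numeric(1))
  edss <- snap_edss(baseline + drift_int + relapse_effect +
                      stats::rnorm(n_visits, 0, 0.25))

  # ancillary streams with per-visit missingness
  miss <- config$missingness
  sdmt_base <- stats::rnorm(1, 55, 8)
  sdmt_drift_int <- sdmt_drift_rrms * pmin(t_vis, t_trans_years) +
    sdmt_drift_spms * pmax(0, t_vis - t_trans_years)
  sdmt_val <- pmax(0, round(sdmt_base + sdmt_drift_int +
                              stats::rnorm(n_visits, 0, 2)))
  sdmt_obs <- stats::runif(n_visits) >= miss["sdmt"]

  in_spms <- t_vis > t_trans_years
  t2_base <- stats::rpois(1, 6)
  n_rel_to_visit <- vapply(t_vis, function(tv) sum(rel_times <= tv), integer(1))
  t2_count <- t2_base + n_rel_to_visit +
    stats::rpois(n_visits, 0.3 * pmax(0, t_vis))
  gd_brain <- stats::rpois(n_visits, ifelse(in_spms, gad_brain_spms, gad_brain_rrms))
  gd_spinal <- stats::rpois(n_visits, ifelse(in_spms, gad_spinal_spms, gad_spinal_rrms))
  mri_obs <- stats::runif(n_visits) >= miss["mri"]

  msis_phys <- pmin(100, pmax(0, round(10 + 7 * edss + stats::rnorm(n_visits, 0, 5))))
  msis_psych <- pmin(100, pmax(0, round(20 + 2.5 * edss + stats::rnorm(n_visits, 0, 8))))
  msis_obs <- stats::runif(n_visits) >= miss["msis"]

  # treatment events: first-line at the first visit for most patients, a
  # possible escalation to second line after repeated relapses, and symptom
  # drugs once the disease is truly progressive. The clinician labelling
  # delay never enters here: treatment behaviour follows the true state, the
  # delay applies to the recorded course label only.
  treat_drug <- rep(NA_character_, n_visits)
  treat_date <- rep(as.Date(NA), n_visits)
  on_second <- FALSE
  started <- FALSE
  for (v in seq_len(n_visits)) {
    if (!started && stats::runif(1) < 0.8) {
      treat_drug[v] <- sample(c("interferon beta", "glatiramer acetate",
                                "dimethyl fumarate", "teriflunomide"), 1)
      treat_date[v] <- visit_dates[v]
      started <- TRUE
    } else if (started && !on_second && !in_spms[v] &&
               n_rel_to_visit[v] >= 3 && stats::runif(1) < 0.5) {
      treat_drug[v] <- sample(c("natalizumab", "fingolimod", "rituximab"), 1)
      treat_date[v] <- visit_dates[v]
      on_second <- TRUE
    } else if (in_spms[v] && stats::runif(1) < 0.1) {
      treat_drug[v] <- sample(c("baclofen", "fampridine"), 1)
      treat_date[v] <- visit_dates[v]
    }
  }

  recorded_course <- ifelse(
    !is.na(recorded_transition) & visit_dates >= recorded_transition,
    "SPMS", "RRMS")

  visits <- data.frame(
    patient_id = rep(patient_id, n_visits),
    visit_date = visit_dates,
    edss = edss,
    recorded_course = recorded_course,
    sdmt = ifelse(sdmt_obs, sdmt_val, NA_real_),
    sdmt_date = as.Date(ifelse(sdmt_obs, visit_dates, NA), origin = "1970-01-01"),
    t2_count = ifelse(mri_obs, t2_count, NA_integer_),
    t1_gd_brain_count = ifelse(mri_obs, gd_brain, NA_integer_),
    t1_gd_spinal_count = ifelse(mri_obs, gd_spinal, NA_integer_),
    mri_date = as.Date(ifelse(mri_obs, visit_dates, NA), origin = "1970-01-01"),
    msis_physical = ifelse(msis_obs, msis_phys, NA_real_),
    msis_psychological = ifelse(msis_obs, msis_psych, NA_real_),
    msis_date = as.Date(ifelse(msis_obs, visit_dates, NA), origin = "1970-01-01"),
    treatment_drug = treat_drug,
    treatment_start_date = treat_date,
    stringsAsFactors = FALSE
  )

  patient <- data.frame(
    patient_id = patient_id,
    sex = sex,
    birth_date = birth_date,
    debut_date = debut_date,
    debut_relapse_date = debut_date,
    stringsAsFactors = FALSE
  )

  ground_truth <- data.frame(
    patient_id = patient_id,
    archetype = archetype,
    true_transition_date = true_transition,
    recorded_transition_date = recorded_transition,
    stringsAsFactors = FALSE
  )

  list(patient = patient, visits = visits, relapses = relapses,
       ground_truth = ground_truth)
}

#' @export
print.ms_cohort <- function(x, ...) {
  tab <- table(x$ground_truth$archetype)
  cat("Synthetic MS cohort:", nrow(x$patients), "patients,",
      nrow(x$visits), "visits\n")
  cat("  archetypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write / read a cohort as a directory of plain CSV files
#'
#' The cohort round-trips through four CSVs (`visits.csv` one row per visit,
#' `patients.csv`, `relapses.csv` one row per relapse event,
#' `ground_truth.csv`). Dates are ISO-8601.
#'
#' @param cohort an `ms_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$relapses, file.path(dir, "relapses.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  date_cols <- function(df, cols) {
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
    df
  }
  visits <- date_cols(
    utils::read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE),
    c("visit_date", "sdmt_date", "mri_date", "msis_date", "treatment_start_date"))
  patients <- date_cols(
    utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE),
    c("birth_date", "debut_date", "debut_relapse_date"))
  relapses <- date_cols(
    utils::read.csv(file.path(dir, "relapses.csv"), stringsAsFactors = FALSE),
    "relapse_date")
  gt <- date_cols(
    utils::read.csv(file.path(dir, "ground_truth.csv"), stringsAsFactors = FALSE),
    c("true_transition_date", "recorded_transition_date"))
  structure(list(patients = patients, visits = visits, relapses = relapses,
                 ground_truth = gt, config = NULL), class = "ms_cohort")
}
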