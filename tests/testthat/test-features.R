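test_that("lesion counts bin at the printed boundaries", {
  expect_identical(bin_lesions(c(0, 9, 10, 20, 21, 100)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(bin_lesions(NA), -1L)
  expect_error(bin_lesions(-1), "non-negative")
})

test_that("treatment categorization uses the lookup and falls back to other", {
  expect_identical(categorize_treatment("interferon beta"), "first_line")
  expect_identical(categorize_treatment("Natalizumab"), "second_line")
  expect_identical(categorize_treatment("ahsct"), "stem_cell")
  expect_warning(out <- categorize_treatment("drugX"), "drugX")
  expect_identical(out, "other")
  expect_identical(categorize_treatment(NA_character_), NA_character_)
})

test_that("relapse cumulation counts events up to and including the visit day", {
  rel <- data.frame(
    patient_id = "P1",
    relapse_date = as.Date(c("2001-01-01", "2003-01-01")),
    category = c("optic_neuritis", "multifocal"),
    steroid_treated = c(0L, 1L), remission = c(1L, 0L))
  out <- cumulate_relapses(rel, as.Date(c("2002-01-01", "2003-01-01",
                                          "2000-06-01")))
  # visit between the events
  expect_equal(out$n_optic_neuritis[1], 1)
  expect_equal(out$n_multifocal[1], 0)
  expect_equal(out$n_steroid_treated_relapses[1], 0)
  # visit on the relapse day: included
  expect_equal(out$n_multifocal[2], 1)
  expect_equal(out$n_steroid_treated_relapses[2], 1)
  expect_equal(out$last_relapse_steroid_treated[2], 1)
  # visit before any event: zero counts, -1 flags
  expect_equal(out$n_relapses_total[3], 0)
  expect_equal(out$last_relapse_steroid_treated[3], -1)
  expect_equal(out$last_relapse_remission[3], -1)
})

test_that("carry-forward fills streams from the most recent observation", {
  v <- rbind(
    visit_row("P1", "2001-03-01", edss = 2, t2_count = 12L,
              t1_gd_brain_count = 0L, t1_gd_spinal_count = 0L,
              mri_date = as.Date("2001-03-01")),
    visit_row("P1", "2002-03-01", edss = 2.5),
    visit_row("P1", "2003-03-01", edss = 3))
  co <- manual_cohort(v)
  f <- build_features(co)
  # visit 3 inherits the visit-1 MRI: count 12 -> bin 2, age at the MRI date
  expect_equal(f$t2_lesion_bin, c(2L, 2L, 2L))
  expect_equal(f$age_at_mri[3], 31.2)
  # never-observed streams are -1 everywhere
  expect_true(all(f$sdmt_score == -1))
  expect_true(all(f$age_at_sdmt == -1))
  expect_true(all(f$current_treatment_category == -1))
  expect_equal(f$n_visits_to_date, 1:3)
})

test_that("first visit with nothing but EDSS gets -1 history features", {
  f <- build_features(manual_cohort(visit_row("P1", "2001-06-01", edss = 1.5)))
  history <- c("sdmt_score", "age_at_sdmt", "current_treatment_category",
               "age_at_treatment_start", "t2_lesion_bin", "t1_gd_brain_bin",
               "t1_gd_spinal_bin", "age_at_mri",
               "last_relapse_steroid_treated", "last_relapse_remission",
               "age_at_last_relapse")
  expect_true(all(f[1, history] == -1))
  expect_equal(f$edss, 1.5)
  # same-day measurement is used for that visit
  f2 <- build_features(manual_cohort(
    visit_row("P1", "2001-06-01", edss = 1.5, sdmt = 52,
              sdmt_date = as.Date("2001-06-01"))))
  expect_equal(f2$sdmt_score, 52)
})

test_that("feature matrices never contain missing markers other than -1", {
  co <- simulate_cohort(sim_config(n_patients = 80, seed = 31))
  f <- build_features(clean_cohort(co)$cohort, "full")
  vals <- as.matrix(f[, setdiff(names(f),
                                c("patient_id", "visit_date",
                                  "recorded_course"))])
  expect_false(anyNA(vals))
  # cumulative relapse counts never decrease within a patient
  for (pid in unique(f$patient_id)[1:20]) {
    expect_true(all(diff(f$n_relapses_total[f$patient_id == pid]) >= 0))
  }
})

test_that("schemas nest: basic_relapse within no_msis within full", {
  b <- feature_schema("basic_relapse")
  n <- feature_schema("no_msis")
  fu <- feature_schema("full")
  expect_length(n$features, 27)
  expect_true(all(b$features %in% n$features))
  expect_true(all(n$features %in% fu$features))
})

test_that("cleaning drops duplicates and visits missing essentials", {
  v <- rbind(visit_row("P1", "2001-01-01"),
             visit_row("P1", "2001-01-01"),              # exact duplicate
             visit_row("P1", "2002-01-01", edss = NA),   # missing EDSS
             visit_row("P2", "2001-05-01"))
  v$recorded_course[4] <- NA
  co <- manual_cohort(v)
  out <- clean_cohort(co)
  expect_equal(out$report$duplicate_rows, 1L)
  expect_equal(out$report$missing_edss, 1L)
  expect_equal(out$report$missing_course, 1L)
  expect_equal(nrow(out$cohort$visits), 1L)
  expect_identical(out$report$patients_removed, "P2")
  # fully valid cohort comes back unchanged with an empty report
  ok <- clean_cohort(manual_cohort(visit_row("P1", "2001-01-01")))
  expect_equal(ok$report$duplicate_rows, 0L)
  expect_equal(nrow(ok$cohort$visits), 1L)
})

test_that("RRMS tail pruning removes the final two years including the anchor", {
  base <- as.Date("2000-01-01")
  yrs <- c(0, 5, 8.5, 9.3, 10)
  v <- do.call(rbind, lapply(yrs, function(y)
    visit_row("P1", base + round(y * 365.25))))
  co <- manual_cohort(v)
  out <- prune_rrms_tail(co)
  kept_years <- round(as.numeric(out$cohort$visits$visit_date - base) / 365.25, 1)
  expect_equal(kept_years, c(0, 5))
  expect_equal(out$report$visits_removed, 3L)

  # transitioning patient untouched
  v2 <- rbind(visit_row("P2", base), visit_row("P2", base + 400),
              visit_row("P2", base + 800, recorded_course = "SPMS"))
  out2 <- prune_rrms_tail(manual_cohort(v2))
  expect_equal(nrow(out2$cohort$visits), 3L)

  # single-visit RRMS patient: whole window, patient dropped and logged
  out3 <- prune_rrms_tail(manual_cohort(visit_row("P3", base)))
  expect_equal(nrow(out3$cohort$visits), 0L)
  expect_identical(out3$report$patients_dropped, "P3")
})

test_that("stratified split is disjoint, proportional and seed-stable", {
  co <- simulate_cohort(sim_config(n_patients = 100, seed = 41))
  sp <- stratified_patient_split(co, seed = 9)
  ids <- c(sp$train, sp$valid, sp$calibration, sp$test)
  expect_equal(sort(ids), sort(unique(co$visits$patient_id)))
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(abs(length(sp$train) - 65) <= 1)
  # archetype shares in train within 1 of the proportional allocation
  arch <- patient_archetypes(co$visits)
  for (a in unique(arch)) {
    n_a <- sum(arch == a)
    in_train <- sum(arch[sp$train] == a)
    expect_lte(abs(in_train - n_a * 0.65), 1)
  }
  expect_identical(sp, stratified_patient_split(co, seed = 9))
  sp2 <- stratified_patient_split(co, seed = 10)
  expect_false(identical(sp$train, sp2$train))
  expect_error(stratified_patient_split(co, fractions = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("featurization is deterministic given the cohort", {
  co <- simulate_cohort(sim_config(n_patients = 30, seed = 43))
  cl <- clean_cohort(co)$cohort
  expect_identical(build_features(cl), build_features(cl))
})
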