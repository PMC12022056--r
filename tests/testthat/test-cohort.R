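test_that("same seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_patients = 60, seed = 7)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("archetype counts follow largest-remainder allocation", {
  co <- simulate_cohort(sim_config(n_patients = 100, seed = 3))
  tab <- table(co$ground_truth$archetype)
  expect_equal(unname(tab[c("rrms_only", "spms_only", "transitioning")]),
               c(68L, 19L, 13L), ignore_attr = TRUE)
  # non-exact products still sum to n and stay within 1 of the product
  co2 <- simulate_cohort(sim_config(n_patients = 37, seed = 3))
  tab2 <- table(factor(co2$ground_truth$archetype,
                       c("rrms_only", "spms_only", "transitioning")))
  expect_equal(sum(tab2), 37)
  expect_true(all(abs(tab2 - 37 * c(0.68, 0.19, 0.13)) < 1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_rrms_only = 0.9, frac_spms_only = 0.2,
                          frac_transitioning = 0.1), "sum to 1")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(relapse_rate_rrms = -1), "non-negative")
})

test_that("recorded labels match archetypes and never revert", {
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 5))
  arch <- setNames(co$ground_truth$archetype, co$ground_truth$patient_id)
  for (pid in names(arch)) {
    lab <- co$visits$recorded_course[co$visits$patient_id == pid]
    if (arch[pid] == "rrms_only") expect_false(any(lab == "SPMS"))
    if (arch[pid] == "spms_only") expect_true(all(lab == "SPMS"))
    is_spms <- lab == "SPMS"
    expect_true(all(diff(is_spms) >= 0))  # monotone
  }
  # transitioning: RRMS first, SPMS last, true transition before recorded
  gt <- co$ground_truth[co$ground_truth$archetype == "transitioning", ]
  for (pid in gt$patient_id) {
    lab <- co$visits$recorded_course[co$visits$patient_id == pid]
    expect_identical(lab[1], "RRMS")
    expect_identical(lab[length(lab)], "SPMS")
  }
  expect_true(all(gt$recorded_transition_date >= gt$true_transition_date))
})

test_that("dates are internally consistent", {
  co <- simulate_cohort(sim_config(n_patients = 100, seed = 11))
  v <- merge(co$visits, co$patients, by = "patient_id")
  expect_true(all(v$debut_date <= v$visit_date))
  expect_true(all(is.na(v$sdmt_date) | v$sdmt_date <= v$visit_date))
  expect_true(all(is.na(v$mri_date) | v$mri_date <= v$visit_date))
  for (pid in unique(co$visits$patient_id)) {
    d <- co$visits$visit_date[co$visits$patient_id == pid]
    expect_true(all(diff(as.numeric(d)) > 0))
  }
})

test_that("clinician labelling delay averages close to its 3-year mean", {
  cfg <- sim_config(n_patients = 250, frac_rrms_only = 0, frac_spms_only = 0,
                    frac_transitioning = 1, seed = 13)
  gt <- simulate_cohort(cfg)$ground_truth
  delay <- as.numeric(gt$recorded_transition_date - gt$true_transition_date) /
    365.25
  expect_gte(length(delay), 200)
  expect_gt(mean(delay), 2.5)
  expect_lt(mean(delay), 3.5)
})

test_that("zero class separation equalizes EDSS increment distributions", {
  cfg <- sim_config(n_patients = 700, class_separation = 0, seed = 17)
  co <- simulate_cohort(cfg)
  v <- co$visits
  inc <- unlist(lapply(split(v, v$patient_id), function(pv) {
    d <- diff(pv$edss) / diff(as.numeric(pv$visit_date) / 365.25)
    split(d, pv$recorded_course[-1])
  }), recursive = FALSE)
  # pool increments by the state label of the destination visit
  by_state <- split(
    unlist(lapply(split(v, v$patient_id), function(pv) diff(pv$edss))),
    unlist(lapply(split(v, v$patient_id),
                  function(pv) pv$recorded_course[-1])))
  expect_gte(min(lengths(by_state)), 1000)
  ks <- suppressWarnings(ks.test(by_state$RRMS, by_state$SPMS))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort CSV round trip preserves the data", {
  co <- simulate_cohort(sim_config(n_patients = 20, seed = 23))
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$visits$edss, co$visits$edss)
  expect_equal(back$visits$visit_date, co$visits$visit_date)
  expect_equal(back$relapses$category, co$relapses$category)
  expect_equal(back$ground_truth$true_transition_date,
               co$ground_truth$true_transition_date)
})
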