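traj_from_sets <- function(sets, gap_months = 12, p_spms = NULL) {
  n <- length(sets)
  p_s <- if (is.null(p_spms)) ifelse(sets %in% c("SPMS", "both"), 0.5, 0.01)
         else p_spms
  p_r <- ifelse(sets %in% c("RRMS", "both"), 0.5, 0.01)
  dates <- as.Date("2000-01-01") + round(cumsum(c(0, rep(gap_months * 30.4375,
                                                         n - 1))))
  build_trajectory(data.frame(p_rrms = p_r, p_spms = p_s), dates,
                   ifelse(seq_len(n) > n / 2, "SPMS", "RRMS"), eps = 0.07)
}

test_that("trajectories assemble in input order with consistent sets", {
  fit <- fit_pipeline(80, seed = 51)
  pid <- fit$test$patient_ids[1]
  sel <- fit$test$patient_ids == pid
  pred <- predict(fit$icp, fit$test$X[sel, , drop = FALSE])
  tr <- build_trajectory(pred, fit$test$visit_dates[sel],
                         as.character(fit$test$y[sel]), eps = 0.07,
                         patient_id = pid)
  expect_length(tr$times, sum(sel))
  expect_equal(tr$times[1], 0)
  expect_true(all(diff(tr$times) > 0))
  # set series recomputable from the p series
  expect_equal(tr$sets, prediction_sets(tr$p_rrms, tr$p_spms, 0.07))
  # single-visit patient: length-1 series
  tr1 <- build_trajectory(pred[1, , drop = FALSE],
                          fit$test$visit_dates[sel][1], "RRMS")
  expect_length(tr1$times, 1)
})

test_that("predicted transition is the first sustained SPMS visit", {
  expect_equal(predicted_transition(c("RRMS", "RRMS", "SPMS", "SPMS", "SPMS")), 3L)
  expect_equal(predicted_transition(c("RRMS", "SPMS", "RRMS", "SPMS", "SPMS")), 4L)
  expect_true(is.na(predicted_transition(rep("RRMS", 5))))
  # multiple-label visits may extend the tail but cannot start it
  expect_equal(predicted_transition(c("RRMS", "SPMS", "both", "SPMS")), 2L)
  expect_true(is.na(predicted_transition(c("RRMS", "both", "both", "both"))))
  # tail shorter than the sustain requirement does not count
  expect_true(is.na(predicted_transition(c("RRMS", "RRMS", "SPMS"), sustain = 2)))
})

test_that("recorded transition is the first SPMS label; reversals error", {
  expect_equal(recorded_transition(c("RRMS", "RRMS", "SPMS")), 3L)
  expect_equal(recorded_transition(rep("SPMS", 4)), 1L)
  expect_true(is.na(recorded_transition(rep("RRMS", 4))))
  expect_error(recorded_transition(c("SPMS", "RRMS")), "revert")
})

test_that("offsets carry the sign convention (negative = model earlier)", {
  times <- 0:9
  off <- transition_offset(4, 6, times)
  expect_equal(off$offset_visits, -2L)
  expect_equal(off$offset_years, -2)
  expect_equal(transition_offset(5, 5, times)$offset_years, 0)
  expect_equal(transition_offset(7, 6, times)$offset_visits, 1L)
  absent <- transition_offset(NA, 6, times)
  expect_true(is.na(absent$offset_visits) && is.na(absent$offset_years))
})

test_that("alternation needs a sustained SPMS run followed by RRMS", {
  expect_true(detect_alternation(
    traj_from_sets(c("RRMS", "SPMS", "SPMS", "RRMS"), gap_months = 4))$flag)
  expect_false(detect_alternation(
    traj_from_sets(c("RRMS", "SPMS", "SPMS", "SPMS"), gap_months = 4))$flag)
  expect_false(detect_alternation(
    traj_from_sets(c("RRMS", "SPMS", "RRMS"), gap_months = 4))$flag)
  # gaps at or below the minimum do not qualify
  expect_false(detect_alternation(
    traj_from_sets(c("RRMS", "SPMS", "SPMS", "RRMS"), gap_months = 2))$flag)
})

test_that("alternation is impossible for monotone set sequences", {
  for (n in 2:8) {
    for (k in 0:n) {
      sets <- c(rep("RRMS", k), rep("SPMS", n - k))
      expect_false(detect_alternation(traj_from_sets(sets, 6))$flag,
                   info = paste(n, k))
    }
  }
})

test_that("misclassification categories follow the codified heuristics", {
  # rising from an elevated start: category 1
  t1 <- traj_from_sets(rep("SPMS", 4), p_spms = c(0.3, 0.5, 0.7, 0.9))
  expect_equal(categorize_misclassified(t1)$label, "cat1")
  # low start, inflection, rise: category 2 with the inflection located
  t2 <- traj_from_sets(c("RRMS", "RRMS", "RRMS", "SPMS", "SPMS"),
                       p_spms = c(0.02, 0.02, 0.02, 0.4, 0.8))
  c2 <- categorize_misclassified(t2)
  expect_equal(c2$label, "cat2")
  expect_equal(c2$inflection, 4L)
  # rise then plateau: category 3
  t3 <- traj_from_sets(rep(c("RRMS", "SPMS"), c(2, 4)),
                       p_spms = c(0.02, 0.03, 0.40, 0.40, 0.40, 0.40))
  expect_equal(categorize_misclassified(t3)$label, "cat3")
  # fluctuating single labels: category 4
  t4 <- traj_from_sets(c("RRMS", "SPMS", "RRMS", "SPMS", "RRMS"))
  expect_equal(categorize_misclassified(t4)$label, "cat4")
  # series too short to categorize
  t5 <- traj_from_sets(c("RRMS", "SPMS"))
  expect_equal(categorize_misclassified(t5)$label, "misc")
})

test_that("raising the confidence never reduces multiple-label visits", {
  fit <- fit_pipeline(150, seed = 53)
  pred <- predict(fit$icp, fit$test$X, fingerprint = fit$test$fingerprint)
  s93 <- prediction_sets(pred$p_rrms, pred$p_spms, 0.07)
  s99 <- prediction_sets(pred$p_rrms, pred$p_spms, 0.01)
  for (pid in unique(fit$test$patient_ids)) {
    sel <- fit$test$patient_ids == pid
    expect_gte(sum(s99[sel] == "both"), sum(s93[sel] == "both"))
  }
})

test_that("frequently misclassified patients are flagged by count or fraction", {
  sets <- factor(c(rep("SPMS", 5), rep("RRMS", 5), "SPMS", "RRMS"),
                 levels = c("RRMS", "SPMS", "both", "empty"))
  truths <- c(rep("RRMS", 5), rep("RRMS", 5), "RRMS", "RRMS")
  ids <- c(rep("A", 5), rep("B", 5), "C", "C")
  flagged <- frequently_misclassified(sets, truths, ids)
  expect_true("A" %in% flagged)   # 5 errors
  expect_true("C" %in% flagged)   # 1/2 of visits erroneous
  expect_false("B" %in% flagged)  # no errors
})
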