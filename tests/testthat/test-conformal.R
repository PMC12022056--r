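test_that("nonconformity is one minus the hypothesized-label probability", {
  prob <- cbind(RRMS = c(0.9, 0.9, 0.5), SPMS = c(0.1, 0.1, 0.5))
  expect_equal(nonconformity(prob, c("RRMS", "SPMS", "RRMS")),
               c(0.1, 0.9, 0.5))
  expect_equal(nonconformity(prob[3, , drop = FALSE], "SPMS"), 0.5)
  expect_error(nonconformity(prob, "PPMS"), "RRMS or SPMS")
})

test_that("p-values rank against the class's calibration scores", {
  calib <- make_calibrator(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(cp_pvalue(calib, "RRMS", 0.25), 0.6)   # (2 + 1) / 5
  expect_equal(cp_pvalue(calib, "RRMS", 0.2), 0.8)    # tie counted as >=
  expect_equal(cp_pvalue(calib, "RRMS", 0.99), 0.2)   # 1 / (n + 1)
  expect_equal(cp_pvalue(calib, "RRMS", 0.05), 1.0)   # below all scores
  expect_equal(cp_pvalue(calib, "RRMS", c(0.25, 0.2)), c(0.6, 0.8))
})

test_that("p-values agree exactly with the brute-force oracle, ties included", {
  set.seed(10)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    scores <- round(runif(n), 1)  # coarse grid forces frequent ties
    a <- round(runif(1), 1)
    calib <- make_calibrator(scores)
    expect_identical(cp_pvalue(calib, "SPMS", a), oracle_pvalue(scores, a))
  }
})

test_that("smoothed p-values split tie mass and stay within (0, 1]", {
  calib <- make_calibrator(c(0.2, 0.2, 0.5))
  set.seed(11)
  p <- replicate(500, cp_pvalue(calib, "RRMS", 0.2, smoothed = TRUE))
  # n_gt = 1; ties = 2; p = (1 + tau * 3) / 4 ranges over (0.25, 1)
  expect_true(all(p > 0.25 & p < 1))
  expect_equal(mean(p), (1 + 0.5 * 3) / 4, tolerance = 0.05)
  # explicit tau makes it deterministic
  expect_equal(cp_pvalue(calib, "RRMS", 0.2, smoothed = TRUE, tau = 0.5),
               (1 + 0.5 * 3) / 4)
})

test_that("calibration is class-conditional, counted, and reproducible", {
  toy <- toy_blobs(120, seed = 12, gap = 3)
  m <- train_model(model_spec("random_forest"), toy$X, toy$y)
  cal <- toy_blobs(60, seed = 13, gap = 3)
  sel <- c(which(cal$y == "RRMS")[1:10], which(cal$y == "SPMS")[1:5])
  icp <- mondrian_icp(m, cal$X[sel, ], cal$y[sel])
  expect_equal(unname(icp$n), c(10L, 5L))
  icp2 <- mondrian_icp(m, cal$X[sel, ], cal$y[sel])
  expect_identical(icp$scores, icp2$scores)
  expect_error(mondrian_icp(m, cal$X[1:5, ], rep("RRMS", 5)), "both classes")
})

test_that("calibration rejects patients seen in training", {
  toy <- toy_blobs(100, seed = 14)
  m <- train_model(model_spec("random_forest"), toy$X, toy$y,
                   patient_ids = rep(sprintf("P%02d", 1:50), 2))
  mixed <- c(1:10, 91:100)  # both classes present
  expect_error(
    mondrian_icp(m, toy$X[mixed, ], toy$y[mixed],
                 patient_ids = c("P01", rep("Q", 19))),
    "overlap")
})

test_that("prediction sets apply the threshold and respect nestedness", {
  expect_equal(as.character(prediction_sets(0.60, 0.02, 0.07)), "RRMS")
  expect_equal(as.character(prediction_sets(0.10, 0.08, 0.07)), "both")
  expect_equal(as.character(prediction_sets(0.03, 0.05, 0.07)), "empty")
  # nestedness: the set at a smaller significance contains the larger one
  set.seed(15)
  p_r <- runif(400)
  p_s <- runif(400)
  eps <- sort(runif(6, 0.01, 0.6))
  sets <- lapply(eps, function(e) prediction_sets(p_r, p_s, e))
  in_set <- function(s) cbind(s %in% c("RRMS", "both"), s %in% c("SPMS", "both"))
  for (k in 1:(length(eps) - 1)) {
    expect_true(all(in_set(sets[[k]]) >= in_set(sets[[k + 1]])))
  }
})

test_that("returned p-values never fall below 1/(n_class + 1)", {
  fit <- fit_pipeline(120, seed = 16)
  pred <- predict(fit$icp, fit$test$X, fingerprint = fit$test$fingerprint)
  expect_true(all(pred$p_rrms >= 1 / (fit$icp$n["RRMS"] + 1)))
  expect_true(all(pred$p_spms >= 1 / (fit$icp$n["SPMS"] + 1)))
  expect_true(all(pred$p_rrms <= 1 & pred$p_spms <= 1))
})

test_that("non-smoothed true-class p-values stochastically dominate uniform", {
  fit <- fit_pipeline(400, seed = 17)
  pred <- predict(fit$icp, fit$test$X, fingerprint = fit$test$fingerprint)
  p_true <- ifelse(fit$test$y == "RRMS", pred$p_rrms, pred$p_spms)
  n <- length(p_true)
  for (t in c(0.05, 0.1, 0.25, 0.5, 0.75)) {
    expect_lte(mean(p_true <= t), t + 3 * sqrt(t * (1 - t) / n))
  }
})

test_that("calibrator refuses mismatched feature schemas", {
  toy <- toy_blobs(100, seed = 18)
  m <- train_model(model_spec("random_forest"), toy$X, toy$y,
                   fingerprint = "schemaA")
  icp <- mondrian_icp(m, toy$X, toy$y, fingerprint = "schemaA")
  expect_error(predict(icp, toy$X, fingerprint = "schemaB"), "fingerprint")
})
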