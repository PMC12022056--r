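#' Nonconformity score
#'
#' The default nonconformity of a visit under a hypothesized label is one
#' minus the model's estimated probability of that label: visits the model
#' finds unlikely under the label score high.
#'
#' @param prob matrix of class probabilities with columns `RRMS`, `SPMS`
#'   (rows sum to 1), or a single such row.
#' @param label character vector (recycled) of hypothesized labels.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' nonconformity(cbind(RRMS = 0.9, SPMS = 0.1), "RRMS")  # 0.1
nonconformity <- function(prob, label) {
  prob <- rbind(prob)
  if (!all(label %in% CLASS_LEVELS)) {
    stop("label must be RRMS or SPMS", call. = FALSE)
  }
  label <- rep_len(as.character(label), nrow(prob))
  1 - prob[cbind(seq_len(nrow(prob)), match(label, colnames(prob)))]
}

#' Fit a Mondrian inductive conformal predictor
#'
#' Calibrates the classifier class-conditionally: nonconformity scores of the
#' calibration visits are computed under their *true* labels and kept in one
#' sorted list per class (the Mondrian taxonomy is the true class label), so
#' the tolerated error rate holds within each class rather than only on the
#' population. Calibration patients must be disjoint from training patients;
#' this is checked when patient ids are available on both sides.
#'
#' @param model a fitted `ms_classifier` (see [train_model()]).
#' @param X_cal calibration feature matrix.
#' @param y_cal calibration labels (both classes must be present).
#' @param patient_ids optional calibration patient ids for the leakage guard.
#' @param fingerprint optional schema fingerprint of `X_cal`.
#' @return object of class `mondrian_icp` with per-class sorted score lists,
#'   per-class calibration sizes `n`, and the wrapped model.
#' @export
mondrian_icp <- function(model, X_cal, y_cal, patient_ids = NULL,
                         fingerprint = NULL) {
  stopifnot(inherits(model, "ms_classifier"))
  y_cal <- factor(y_cal, levels = CLASS_LEVELS)
  if (!is.null(patient_ids) && length(model$train_patient_ids) &&
      any(patient_ids %in% model$train_patient_ids)) {
    stop("calibration patients overlap the training patients; ",
         "inductive conformal calibration requires disjoint sets",
         call. = FALSE)
  }
  if (any(table(y_cal) == 0)) {
    stop("both classes must be present in the calibration set", call. = FALSE)
  }
  prob <- predict_proba(model, X_cal, fingerprint = fingerprint)
  alpha <- nonconformity(prob, as.character(y_cal))
  scores <- lapply(stats::setNames(CLASS_LEVELS, CLASS_LEVELS),
                   function(cl) sort(alpha[y_cal == cl]))
  structure(list(scores = scores,
                 n = vapply(scores, length, integer(1)),
                 model = model,
                 fingerprint = if (is.null(fingerprint)) model$fingerprint
                               else fingerprint),
            class = "mondrian_icp")
}

#' Conformal p-value against a class's calibration scores
#'
#' Ranks the test score among the class's calibration scores with the test
#' point counted as its own (n+1)-th element:
#' `p = (count(alpha_j >= alpha_test) + 1) / (n + 1)`, ties counted as `>=`.
#' The smoothed variant replaces the tie mass by a uniform draw,
#' `p = (count(alpha_j > a) + tau * (ties + 1)) / (n + 1)`, making true-label
#' p-values exactly uniform; it is off by default for determinism.
#'
#' @param calibrator a `mondrian_icp`.
#' @param class `"RRMS"` or `"SPMS"`.
#' @param alpha numeric vector of test nonconformity scores.
#' @param smoothed logical; use the randomized tie-breaking variant.
#' @param tau optional uniform draws (recycled) for the smoothed variant;
#'   drawn from the current RNG when missing.
#' @return numeric vector of p-values in `(0, 1]`, each at least
#'   `1 / (n_class + 1)` in the non-smoothed case.
#' @export
cp_pvalue <- function(calibrator, class, alpha, smoothed = FALSE, tau = NULL) {
  stopifnot(inherits(calibrator, "mondrian_icp"))
  class <- match.arg(class, CLASS_LEVELS)
  sc <- calibrator$scores[[class]]
  n <- length(sc)
  n_le <- findInterval(alpha, sc)                    # { <= alpha }
  n_lt <- findInterval(alpha, sc, left.open = TRUE)  # { <  alpha }
  n_ge <- n - n_lt
  if (!smoothed) {
    return((n_ge + 1) / (n + 1))
  }
  n_gt <- n - n_le
  ties <- n_le - n_lt
  if (is.null(tau)) tau <- stats::runif(length(alpha))
  (n_gt + rep_len(tau, length(alpha)) * (ties + 1)) / (n + 1)
}

#' Prediction sets at a significance level
#'
#' A label enters the set when its conformal p-value is at least the
#' significance `eps`; the four possible outcomes are a single label, both
#' labels (the model cannot separate them), or the empty set (the visit is
#' unlike the calibration data under either label).
#'
#' @param p_rrms,p_spms numeric vectors of per-visit p-values.
#' @param eps significance level in `(0, 1)` (confidence is `1 - eps`).
#' @return factor with levels `"RRMS"`, `"SPMS"`, `"both"`, `"empty"`.
#' @export
prediction_sets <- function(p_rrms, p_spms, eps) {
  stopifnot(eps > 0, eps < 1)
  in_r <- p_rrms >= eps
  in_s <- p_spms >= eps
  out <- ifelse(in_r & in_s, "both",
                ifelse(in_r, "RRMS", ifelse(in_s, "SPMS", "empty")))
  factor(out, levels = c("RRMS", "SPMS", "both", "empty"))
}

#' Predict conformal p-values and label sets for new visits
#'
#' @param object a `mondrian_icp`.
#' @param X feature matrix of new visits.
#' @param confidence confidence level in percent (default 93); used to set
#'   the significance `eps = 1 - confidence/100` unless `eps` is given.
#' @param eps significance level, overriding `confidence`.
#' @param smoothed logical; smoothed p-values (randomized tie-breaking).
#' @param fingerprint optional schema fingerprint of `X` to check.
#' @param ... unused.
#' @return data frame with columns `p_rrms`, `p_spms`, `set`.
#' @export
predict.mondrian_icp <- function(object, X, confidence = 93, eps = NULL,
                                 smoothed = FALSE, fingerprint = NULL, ...) {
  if (is.null(eps)) eps <- confidence_to_eps(confidence)
  if (!is.null(fingerprint) && !is.null(object$fingerprint) &&
      !identical(fingerprint, object$fingerprint)) {
    stop("feature schema fingerprint does not match the calibrator's",
         call. = FALSE)
  }
  prob <- predict_proba(object$model, X)
  p_rrms <- cp_pvalue(object, "RRMS", nonconformity(prob, "RRMS"),
                      smoothed = smoothed)
  p_spms <- cp_pvalue(object, "SPMS", nonconformity(prob, "SPMS"),
                      smoothed = smoothed)
  data.frame(p_rrms = p_rrms, p_spms = p_spms,
             set = prediction_sets(p_rrms, p_spms, eps))
}

#' @export
print.mondrian_icp <- function(x, ...) {
  cat("Mondrian inductive conformal predictor\n")
  cat("  underlying model:", x$model$kind, "\n")
  cat(sprintf("  calibration scores: RRMS n=%d, SPMS n=%d\n",
              x$n["RRMS"], x$n["SPMS"]))
  cat(sprintf("  minimum attainable p-values: %.4f (RRMS), %.4f (SPMS)\n",
              1 / (x$n["RRMS"] + 1), 1 / (x$n["SPMS"] + 1)))
  invisible(x)
}

#' @export
summary.mondrian_icp <- function(object, ...) {
  cat("Mondrian ICP calibration score summaries\n")
  for (cl in CLASS_LEVELS) {
    s <- object$scores[[cl]]
    cat(sprintf("  %s (n=%d): ", cl, length(s)))
    print(round(stats::quantile(s), 4))
  }
  invisible(object)
}
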