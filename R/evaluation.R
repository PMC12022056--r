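# Evaluation surfaces for a conformal predictor: calibration and efficiency
# curves over a significance grid, the peak-confidence operating point,
# confusion tables at a confidence, and error-concentration analysis.

# Outcome of each visit's prediction set once the truth is attached.
#' @keywords internal
set_outcomes <- function(sets, truths) {
  truths <- as.character(truths)
  sets <- as.character(sets)
  ifelse(sets == "both", "multiple",
         ifelse(sets == "empty", "empty",
                ifelse(sets == truths, "single_correct", "single_incorrect")))
}

#' Calibration curve: observed error against significance
#'
#' The observed error at significance `eps` is the fraction of visits whose
#' prediction set at `eps` excludes the true label (empty sets count as
#' errors; multiple-label sets never do). For a valid conformal predictor the
#' curve tracks the diagonal.
#'
#' @param p_pairs data frame with `p_rrms`, `p_spms` (one row per visit).
#' @param truths true labels.
#' @param eps_grid significance levels (default 0.01 to 0.50 by 0.01).
#' @return data frame with columns `epsilon`, `error`.
#' @export
calibration_curve <- function(p_pairs, truths, eps_grid = seq(0.01, 0.5, 0.01)) {
  if (nrow(p_pairs) == 0) stop("no predictions supplied", call. = FALSE)
  p_true <- ifelse(truths == "RRMS", p_pairs$p_rrms, p_pairs$p_spms)
  data.frame(epsilon = eps_grid,
             error = vapply(eps_grid, function(e) mean(p_true < e), numeric(1)))
}

#' Efficiency curve: outcome fractions against significance
#'
#' For every significance on the grid, the fractions of correct single-label,
#' incorrect single-label, multiple-label and empty predictions (these
#' partition the visits, so they sum to 1), plus the observed error
#' (incorrect single + empty).
#'
#' @inheritParams calibration_curve
#' @return object of class `efficiency_curve`: a data frame with columns
#'   `epsilon`, `correct_single`, `incorrect_single`, `multiple`, `empty`,
#'   `error`.
#' @export
efficiency_curve <- function(p_pairs, truths, eps_grid = seq(0.01, 0.5, 0.01)) {
  rows <- lapply(eps_grid, function(e) {
    out <- set_outcomes(prediction_sets(p_pairs$p_rrms, p_pairs$p_spms, e), truths)
    data.frame(epsilon = e,
               correct_single = mean(out == "single_correct"),
               incorrect_single = mean(out == "single_incorrect"),
               multiple = mean(out == "multiple"),
               empty = mean(out == "empty"))
  })
  curve <- do.call(rbind, rows)
  curve$error <- curve$incorrect_single + curve$empty
  structure(curve, class = c("efficiency_curve", "data.frame"))
}

#' Peak-confidence operating point
#'
#' The significance level on the curve's grid that maximizes the fraction of
#' correct single-label predictions; ties are broken toward the smaller
#' significance (higher confidence).
#'
#' @param curve an [efficiency_curve()].
#' @return the selected significance level (scalar).
#' @export
peak_confidence <- function(curve) {
  if (nrow(curve) == 0) stop("empty efficiency curve", call. = FALSE)
  curve$epsilon[order(-curve$correct_single, curve$epsilon)][1]
}

#' Confusion table at a confidence level
#'
#' Counts of predicted outcome (RRMS, SPMS, empty, multiple) by true class,
#' either over all visits or at each patient's final visit. Percentages are
#' per true-class column, reported to one decimal (columns may not sum to
#' exactly 100 because of rounding). Overall efficiency is the single-label
#' fraction.
#'
#' @param p_pairs data frame with `p_rrms`, `p_spms`.
#' @param truths true labels per visit.
#' @param confidence confidence level in percent.
#' @param patient_ids patient id per visit; required for
#'   `mode = "patient_final"`.
#' @param mode `"visit"` (all visits) or `"patient_final"` (each patient's
#'   chronologically last visit; rows are assumed in visit order within
#'   patient).
#' @return object of class `cp_confusion` with the count matrix, percentage
#'   matrix, confidence and efficiency.
#' @export
confusion_at <- function(p_pairs, truths, confidence = 93, patient_ids = NULL,
                         mode = c("visit", "patient_final")) {
  mode <- match.arg(mode)
  if (mode == "patient_final") {
    if (is.null(patient_ids)) {
      stop("patient_ids required for patient_final mode", call. = FALSE)
    }
    keep <- !duplicated(patient_ids, fromLast = TRUE)
    p_pairs <- p_pairs[keep, , drop = FALSE]
    truths <- truths[keep]
  }
  eps <- confidence_to_eps(confidence)
  sets <- prediction_sets(p_pairs$p_rrms, p_pairs$p_spms, eps)
  pred <- factor(ifelse(sets == "both", "multiple", as.character(sets)),
                 levels = c("RRMS", "SPMS", "empty", "multiple"))
  counts <- table(prediction = pred, truth = factor(truths, CLASS_LEVELS))
  pct <- round(100 * prop.table(counts, margin = 2), 1)
  structure(list(confidence = confidence, mode = mode,
                 counts = unclass(counts), percent = unclass(pct),
                 efficiency = mean(sets %in% CLASS_LEVELS)),
            class = "cp_confusion")
}

#' @export
print.cp_confusion <- function(x, ...) {
  cat(sprintf("Conformal prediction at %g%% confidence (%s mode)\n",
              x$confidence, x$mode))
  cat(sprintf("Overall efficiency (single-label fraction): %.1f%%\n",
              100 * x$efficiency))
  m <- matrix(sprintf("%d (%.1f%%)", x$counts, x$percent), nrow = nrow(x$counts),
              dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  cat("Percentages may not sum to 100 due to rounding.\n")
  invisible(x)
}

#' Error concentration across patients
#'
#' Splits single-label errors by direction (true RRMS predicted SPMS, and the
#' converse), sorts patients by descending error count within each direction,
#' and reports the minimal number of patients whose cumulative errors reach
#' at least half of that direction's errors, together with the cumulative
#' share curve. Directions with no errors are reported as not applicable.
#'
#' @param sets factor of prediction sets per visit (from [prediction_sets()]).
#' @param truths true labels per visit.
#' @param patient_ids patient id per visit.
#' @return list with one element per direction (`spms_errors`: true RRMS
#'   predicted SPMS; `rrms_errors`: true SPMS predicted RRMS), each holding
#'   `n_errors`, `n_patients`, `patients_for_50pct`, and `cum_share`.
#' @export
error_concentration <- function(sets, truths, patient_ids) {
  directions <- list(
    spms_errors = truths == "RRMS" & sets == "SPMS",
    rrms_errors = truths == "SPMS" & sets == "RRMS")
  lapply(directions, function(is_err) {
    total <- sum(is_err)
    if (total == 0) {
      return(list(n_errors = 0L, n_patients = 0L,
                  patients_for_50pct = NA_integer_, cum_share = numeric(0)))
    }
    per_patient <- sort(table(patient_ids[is_err]), decreasing = TRUE)
    cum_share <- cumsum(as.numeric(per_patient)) / total
    list(n_errors = total,
         n_patients = length(per_patient),
         patients_for_50pct = which(cum_share >= 0.5)[1],
         cum_share = cum_share)
  })
}

#' Plot calibration or efficiency curves
#'
#' @param x an `efficiency_curve`.
#' @param which `"efficiency"` for the stacked outcome fractions,
#'   `"calibration"` for observed error against the diagonal.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.efficiency_curve <- function(x, which = c("efficiency", "calibration"), ...) {
  which <- match.arg(which)
  if (which == "calibration") {
    graphics::plot(x$epsilon, x$error, type = "l", xlab = "significance",
                   ylab = "observed error", ...)
    graphics::abline(0, 1, lty = 2, col = "grey50")
  } else {
    cols <- c("forestgreen", "firebrick", "orange", "grey40")
    graphics::matplot(x$epsilon,
                      cbind(x$correct_single, x$incorrect_single,
                            x$multiple, x$empty),
                      type = "l", lty = 1, col = cols,
                      xlab = "significance", ylab = "fraction of visits", ...)
    graphics::legend("right", c("correct single", "incorrect single",
                                "multiple", "empty"),
                     col = cols, lty = 1, bty = "n")
  }
  invisible(x)
}
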