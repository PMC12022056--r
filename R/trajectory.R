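# Per-patient disease-course analytics: p-value time series, transition-point
# estimation against the recorded diagnosis, alternation detection, and a
# codified taxonomy of frequently misclassified trajectories.

#' Assemble a disease-course trajectory for one patient
#'
#' @param pred data frame with this patient's per-visit `p_rrms`, `p_spms`
#'   (chronological order).
#' @param visit_dates this patient's visit dates.
#' @param recorded this patient's recorded course labels.
#' @param eps significance level for the set series.
#' @param patient_id identifier carried on the object.
#' @return object of class `course_trajectory`: times in years from the first
#'   visit, both p-value series, the set series at `eps`, and the recorded
#'   labels.
#' @export
build_trajectory <- function(pred, visit_dates, recorded, eps = 0.07,
                             patient_id = NA_character_) {
  stopifnot(nrow(pred) >= 1, nrow(pred) == length(visit_dates))
  times <- years_between(visit_dates[1], visit_dates)
  structure(list(
    patient_id = patient_id,
    times = times,
    visit_dates = as.Date(visit_dates),
    p_rrms = pred$p_rrms,
    p_spms = pred$p_spms,
    eps = eps,
    sets = prediction_sets(pred$p_rrms, pred$p_spms, eps),
    recorded = as.character(recorded)
  ), class = "course_trajectory")
}

#' @export
print.course_trajectory <- function(x, ...) {
  cat(sprintf("Disease-course trajectory %s: %d visits over %.1f years (eps=%g)\n",
              x$patient_id, length(x$times), max(x$times), x$eps))
  invisible(x)
}

#' Plot a disease-course trajectory
#'
#' Two stacked panels in the style of a disease-course plot: the prediction
#' set / recorded label sequence on top, and the two conformal p-value series
#' below, with the recorded transition (if any) marked.
#'
#' @param x a `course_trajectory`.
#' @param ... unused.
#' @export
plot.course_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  code <- match(as.character(x$sets), c("RRMS", "SPMS", "both", "empty"))
  graphics::plot(x$times, code, type = "p", pch = 15, yaxt = "n",
                 ylim = c(0.5, 4.5), xlab = "", ylab = "prediction",
                 main = paste("patient", x$patient_id))
  graphics::axis(2, at = 1:4, labels = c("RRMS", "SPMS", "both", "empty"),
                 las = 1, cex.axis = 0.8)
  rec_idx <- recorded_transition(x$recorded)
  if (!is.na(rec_idx)) graphics::abline(v = x$times[rec_idx], lty = 3)
  graphics::matplot(x$times, cbind(x$p_rrms, x$p_spms), type = "b", pch = 16,
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "years from first visit", ylab = "conformal p-value")
  graphics::abline(h = x$eps, lty = 2, col = "grey50")
  graphics::legend("topright", c("RRMS", "SPMS"), col = c("steelblue", "firebrick"),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Predicted transition visit
#'
#' The first visit whose single-label prediction is SPMS, from which the set
#' series stays SPMS or multiple-label through to the end of follow-up, with
#' at least `sustain` visits in that stable tail. Isolated SPMS flips do not
#' count. Returns `NA` when no such visit exists.
#'
#' @param traj a `course_trajectory` (or a factor/character set series).
#' @param sustain minimum number of visits in the stable tail.
#' @return 1-based visit index or `NA`.
#' @export
predicted_transition <- function(traj, sustain = 2) {
  sets <- as.character(if (inherits(traj, "course_trajectory")) traj$sets else traj)
  n <- length(sets)
  spms_like <- sets %in% c("SPMS", "both")
  for (i in seq_len(n)) {
    if (sets[i] == "SPMS" && (n - i + 1) >= sustain && all(spms_like[i:n])) {
      return(i)
    }
  }
  NA_integer_
}

#' Recorded transition visit
#'
#' First visit whose recorded course label is SPMS; `NA` for patients
#' recorded RRMS throughout. Labels must be monotone (no SPMS-to-RRMS
#' reversal).
#'
#' @param recorded character vector of recorded labels (or a
#'   `course_trajectory`).
#' @return 1-based visit index or `NA`.
#' @export
recorded_transition <- function(recorded) {
  if (inherits(recorded, "course_trajectory")) recorded <- recorded$recorded
  is_spms <- recorded == "SPMS"
  if (any(diff(is_spms) < 0)) {
    stop("recorded labels revert from SPMS to RRMS", call. = FALSE)
  }
  if (!any(is_spms)) return(NA_integer_)
  which(is_spms)[1]
}

#' Offset between predicted and recorded transitions
#'
#' Negative offsets mean the model places the transition earlier than the
#' recorded diagnosis.
#'
#' @param predicted,recorded 1-based visit indices (either may be `NA`).
#' @param times visit times in years from the first visit.
#' @return object of class `transition_estimate`: both indices plus
#'   `offset_visits` and `offset_years` (NA unless both indices are present).
#' @export
transition_offset <- function(predicted, recorded, times) {
  both <- !is.na(predicted) && !is.na(recorded)
  structure(list(
    predicted = predicted,
    recorded = recorded,
    offset_visits = if (both) predicted - recorded else NA_integer_,
    offset_years = if (both) times[predicted] - times[recorded] else NA_real_
  ), class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat("Transition estimate: predicted visit", x$predicted,
      "recorded visit", x$recorded, "\n")
  if (!is.na(x$offset_visits)) {
    cat(sprintf("  offset: %+d visits, %+.2f years (negative = model earlier)\n",
                x$offset_visits, x$offset_years))
  }
  invisible(x)
}

#' Detect alternating (unreliable) SPMS predictions
#'
#' Flags a trajectory when at least two consecutive single-label SPMS visits,
#' each pair separated by more than `min_gap_months`, are later followed by a
#' single-label RRMS visit - a reversal that is clinically not considered
#' possible and therefore marks unreliable predictions.
#'
#' @param traj a `course_trajectory`.
#' @param min_gap_months minimum gap between the consecutive SPMS visits.
#' @return list with `flag` (logical) and `visits` (indices of the SPMS run
#'   that triggered the flag; empty when not flagged).
#' @export
detect_alternation <- function(traj, min_gap_months = 3) {
  sets <- as.character(traj$sets)
  n <- length(sets)
  if (n < 3) return(list(flag = FALSE, visits = integer(0)))
  gap_months <- diff(traj$times) * 12
  is_spms <- sets == "SPMS"
  is_rrms <- sets == "RRMS"
  for (i in seq_len(n - 2)) {
    if (!is_spms[i]) next
    j <- i
    while (j + 1 <= n && is_spms[j + 1] && gap_months[j] > min_gap_months) j <- j + 1
    if (j > i && j < n && any(is_rrms[(j + 1):n])) {
      return(list(flag = TRUE, visits = i:j))
    }
  }
  list(flag = FALSE, visits = integer(0))
}

#' Categorize a frequently misclassified trajectory
#'
#' Codifies the qualitative taxonomy of frequently misclassified patients
#' into a deterministic heuristic on the SPMS p-value series:
#' \describe{
#'   \item{cat4}{the single-label sequence flips between RRMS and SPMS at
#'     least `fluctuation_min` times (fluctuating classification);}
#'   \item{cat1}{SPMS p-values already elevated at the first visit
#'     (`p >= elevated_p`) with a positive robust (Theil-Sen) trend from the
#'     start;}
#'   \item{cat2}{a change point after at least two visits with SPMS p-values
#'     below `low_p`, with a rising trend after it (the inflection point);}
#'   \item{cat3}{an initial rise that plateaus: late-window Theil-Sen slope
#'     within `plateau_slope` per visit;}
#'   \item{misc}{anything else, including series shorter than 3 visits.}
#' }
#'
#' @param traj a `course_trajectory`.
#' @param low_p threshold below which an SPMS p-value counts as low.
#' @param elevated_p threshold above which the starting p-value counts as
#'   elevated.
#' @param plateau_slope absolute per-visit slope bound defining a plateau.
#' @param fluctuation_min minimum number of single-label sign changes for
#'   cat4.
#' @return object of class `misclass_category`: `label` in
#'   `c("cat1","cat2","cat3","cat4","misc")` plus supporting statistics
#'   (`inflection`, `slope`, `fluctuations`).
#' @export
categorize_misclassified <- function(traj, low_p = 0.1, elevated_p = 0.1,
                                     plateau_slope = 0.01, fluctuation_min = 3) {
  p <- traj$p_spms
  n <- length(p)
  sets <- as.character(traj$sets)
  singles <- sets[sets %in% CLASS_LEVELS]
  fluct <- if (length(singles) > 1) sum(singles[-1] != singles[-length(singles)]) else 0L

  make <- function(label, inflection = NA_integer_, slope = NA_real_) {
    structure(list(label = label, inflection = inflection, slope = slope,
                   fluctuations = fluct), class = "misclass_category")
  }
  if (n < 3) return(make("misc"))
  if (fluct >= fluctuation_min) return(make("cat4"))

  idx <- seq_len(n)
  slope_all <- theil_sen_slope(idx, p)
  if (p[1] >= elevated_p && !is.na(slope_all) && slope_all > 0) {
    return(make("cat1", slope = slope_all))
  }

  # change point: candidate split maximizing the two-sample contrast
  # (mean(after) - mean(before), scaled by the usual sqrt(n1*n2/n) factor so
  # one-point tails do not dominate), requiring >= 2 low-p visits before it
  # and a rising trend after it
  if (n >= 4) {
    cands <- 3:n
    gain <- vapply(cands, function(k) {
      n1 <- k - 1
      n2 <- n - k + 1
      (mean(p[k:n]) - mean(p[1:(k - 1)])) * sqrt(n1 * n2 / n)
    }, numeric(1))
    k <- cands[which.max(gain)]
    pre_low <- sum(p[1:(k - 1)] < low_p) >= 2
    post_slope <- if (n - k + 1 >= 2) theil_sen_slope(k:n, p[k:n]) else NA_real_
    rising_into <- p[k] > p[k - 1]
    if (pre_low && max(gain) > 0 && rising_into &&
        !is.na(post_slope) && post_slope > plateau_slope) {
      return(make("cat2", inflection = k, slope = post_slope))
    }
  }

  # plateau: early rise, then a flat late window (second half of the series)
  late <- seq(max(1, ceiling(n / 2)), n)
  late_slope <- theil_sen_slope(late, p[late])
  early_slope <- theil_sen_slope(seq_len(max(2, floor(n / 2))),
                                 p[seq_len(max(2, floor(n / 2)))])
  if (!is.na(late_slope) && abs(late_slope) <= plateau_slope &&
      !is.na(early_slope) && early_slope > 0) {
    return(make("cat3", slope = late_slope))
  }
  make("misc")
}

#' @export
print.misclass_category <- function(x, ...) {
  cat("Misclassification category:", x$label, "\n")
  if (!is.na(x$inflection)) cat("  inflection at visit", x$inflection, "\n")
  if (!is.na(x$slope)) cat("  slope:", signif(x$slope, 3), "per visit\n")
  cat("  single-label fluctuations:", x$fluctuations, "\n")
  invisible(x)
}

#' Identify frequently misclassified patients
#'
#' A patient is flagged when at least `min_errors` visits carry a single-label
#' error, or at least `min_frac` of the patient's visits do.
#'
#' @param sets prediction sets per visit.
#' @param truths true labels per visit.
#' @param patient_ids patient id per visit.
#' @param min_errors,min_frac flag thresholds.
#' @return character vector of flagged patient ids.
#' @export
frequently_misclassified <- function(sets, truths, patient_ids,
                                     min_errors = 5, min_frac = 0.5) {
  err <- set_outcomes(sets, truths) == "single_incorrect"
  n_err <- tapply(err, patient_ids, sum)
  n_vis <- tapply(err, patient_ids, length)
  names(n_err)[n_err >= min_errors | (n_err / n_vis) >= min_frac]
}

#' Transition-timing analysis over a cohort's transitioning patients
#'
#' Builds trajectories for all patients with both a recorded and a predicted
#' transition and collects the offsets.
#'
#' @param pred data frame of per-visit `p_rrms`, `p_spms` for many patients.
#' @param visit_dates,recorded,patient_ids per-visit metadata aligned with
#'   `pred` (chronological within patient).
#' @param eps significance level.
#' @param sustain sustained-tail length for [predicted_transition()].
#' @return data frame with one row per patient: indices, `offset_visits`,
#'   `offset_years`, and an `alternation` flag.
#' @export
transition_analysis <- function(pred, visit_dates, recorded, patient_ids,
                                eps = 0.07, sustain = 2) {
  ids <- unique(patient_ids)
  rows <- lapply(ids, function(pid) {
    sel <- patient_ids == pid
    traj <- build_trajectory(pred[sel, , drop = FALSE], visit_dates[sel],
                             recorded[sel], eps = eps, patient_id = pid)
    p_idx <- predicted_transition(traj, sustain = sustain)
    r_idx <- recorded_transition(traj)
    off <- transition_offset(p_idx, r_idx, traj$times)
    alt <- detect_alternation(traj)
    data.frame(patient_id = pid, predicted = p_idx, recorded = r_idx,
               offset_visits = off$offset_visits,
               offset_years = off$offset_years,
               alternation = alt$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
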