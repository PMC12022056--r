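# Internal helpers shared across modules.

CLASS_LEVELS <- c("RRMS", "SPMS")
DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.4375

#' @keywords internal
years_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / DAYS_PER_YEAR
}

#' @keywords internal
add_years <- function(date, years) {
  as.Date(date) + round(years * DAYS_PER_YEAR)
}

#' @keywords internal
add_months <- function(date, months) {
  as.Date(date) + round(months * DAYS_PER_MONTH)
}

# Age in years at 0.1-year resolution; -1 when the reference date is missing.
#' @keywords internal
age_at <- function(birth_date, date) {
  out <- round(years_between(birth_date, date), 1)
  out[is.na(out)] <- -1
  out
}

# Snap a continuous disability value to the 0-10 half-point EDSS grid.
#' @keywords internal
snap_edss <- function(x) {
  pmin(10, pmax(0, round(x * 2) / 2))
}

# Deterministic per-patient sub-seed below 2^31, derived from the cohort seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

# Largest-remainder allocation of n items to proportions p (sums to n).
#' @keywords internal
largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    # ties broken by position order
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Truncated-at-zero normal draw (rejection; falls back to 0 for degenerate sd).
#' @keywords internal
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0
  }
  out
}

# Theil-Sen slope: median of pairwise slopes. Robust trend for short
# p-value series; NA for fewer than 2 distinct x.
#' @keywords internal
theil_sen_slope <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) return(NA_real_)
  stats::median(dy[keep] / dx[keep])
}

# FNV-1a hash of a deparsed object, hex string. Used to fingerprint configs
# and splits so mismatched artifacts refuse to combine.
#' @keywords internal
fnv1a_hash <- function(obj) {
  bytes <- utf8ToInt(paste(deparse(obj), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Significance from a confidence in percent, rounded to kill FP noise.
#' @keywords internal
confidence_to_eps <- function(confidence) {
  stopifnot(confidence > 0, confidence < 100)
  round(1 - confidence / 100, 12)
}

# Last-observation-carried-forward that tolerates leading NAs.
#' @keywords internal
locf <- function(x) zoo::na.locf(x, na.rm = FALSE)
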