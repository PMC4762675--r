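#' CKD-EPI estimated glomerular filtration rate (2009 creatinine equation)
#'
#' Computes eGFR (ml/min/1.73m\eqn{^2}) from serum creatinine, age, sex and
#' race using the abbreviated 4-variable CKD-EPI equation:
#' \deqn{141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{age}
#'       \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{black}]}
#' with \eqn{\kappa = 0.7} (female) / \eqn{0.9} (male) and
#' \eqn{\alpha = -0.329} (female) / \eqn{-0.411} (male).
#'
#' @param scr serum creatinine in mg/dL (positive).
#' @param age age in years (positive).
#' @param female logical; TRUE for female.
#' @param black logical; TRUE for black race.
#' @return eGFR in ml/min/1.73m^2. All arguments are vectorized and recycled.
#' @examples
#' ckd_epi_egfr(1.2, 70, female = FALSE, black = FALSE)
#' @export
ckd_epi_egfr <- function(scr, age, female, black) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stopf("'scr' must be positive and finite")
  if (any(!is.finite(age)) || any(age <= 0)) stopf("'age' must be positive and finite")
  female <- as.logical(female)
  black <- as.logical(black)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- scr / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Invert the CKD-EPI equation to a serum creatinine value
#'
#' Given a target eGFR and demographics, returns the unique creatinine
#' producing that eGFR under [ckd_epi_egfr()] (the equation is strictly
#' decreasing in creatinine). Used by the synthetic-data generator's
#' creatinine-emitting mode so that the eGFR computation path is exercised
#' end-to-end.
#'
#' @param egfr target eGFR in ml/min/1.73m^2 (positive).
#' @inheritParams ckd_epi_egfr
#' @return serum creatinine in mg/dL.
#' @export
ckd_epi_inverse <- function(egfr, age, female, black) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) stopf("'egfr' must be positive and finite")
  female <- as.logical(female)
  black <- as.logical(black)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  # eGFR at scr == kappa: the knot separating the two power branches
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
  ifelse(egfr >= base,
         kappa * (egfr / base)^(1 / alpha),
         kappa * (egfr / base)^(1 / -1.209))
}

#' Annual percentage change in eGFR between the initial and T0 measurements
#'
#' \code{((t0_egfr - initial_egfr) / initial_egfr) /
#'   ((t0_date - initial_date) / 365.25) * 100}
#'
#' @param initial_egfr,t0_egfr eGFR at the initial and T0 measurements.
#' @param initial_date,t0_date their dates (`Date`); `t0_date` must be later.
#' @return percent change per year.
#' @export
annual_pct_egfr_change <- function(initial_egfr, t0_egfr, initial_date, t0_date) {
  if (any(initial_egfr <= 0)) stopf("'initial_egfr' must be positive")
  dt <- years_between(as.Date(initial_date), as.Date(t0_date))
  if (any(dt <= 0)) stopf("t0_date must be after initial_date")
  ((t0_egfr - initial_egfr) / initial_egfr) / dt * 100
}

#' Annual percentage change in weight from a pre-T0 weight series
#'
#' Difference of the first and last weight divided by the elapsed time in
#' years and by the first weight, times 100. Patients with fewer than two
#' weights at distinct dates get `NA` (they are retained in the cohort; n
#' shrinks only in weight-adjusted models).
#'
#' @param dates measurement dates (`Date`).
#' @param weights weights (lb), same length as `dates`.
#' @return percent change per year, or `NA_real_`.
#' @export
annual_pct_weight_change <- function(dates, weights) {
  keep <- !is.na(weights) & !is.na(dates)
  dates <- as.Date(dates[keep]); weights <- weights[keep]
  if (length(weights) < 2L) return(NA_real_)
  o <- order(dates)
  dates <- dates[o]; weights <- weights[o]
  dt <- years_between(dates[1L], dates[length(dates)])
  if (dt <= 0) return(NA_real_)
  100 * (weights[length(weights)] - weights[1L]) / weights[1L] / dt
}

#' Categorize a urine micro-albumin/creatinine ratio
#'
#' <20 mg/g is normal, 20-300 mg/g microalbuminuria (closed interval: both
#' boundaries fall in the middle category), >300 mg/g albuminuria.
#'
#' @param uacr ratio in mg/g (non-negative); vectorized, `NA` passes through.
#' @return factor with levels normal, microalbuminuria, albuminuria.
#' @export
albuminuria_category <- function(uacr) {
  if (any(uacr < 0, na.rm = TRUE)) stopf("'uacr' must be non-negative")
  lab <- ifelse(uacr < 20, "normal",
         ifelse(uacr <= 300, "microalbuminuria", "albuminuria"))
  factor(lab, levels = c("normal", "microalbuminuria", "albuminuria"))
}

#' Annual-average eGFR series after cohort entry
#'
#' Bins each patient's post-T0 eGFR measurements into follow-up years
#' (half-open intervals `[T0 + k yr, T0 + (k+1) yr)`, year length 365.25
#' days, `k = 0..n_years-1`) and returns the arithmetic mean and count per
#' occupied year. Years without measurements are absent (missing, not zero);
#' the count column feeds the trajectory model's measurement-frequency
#' covariate.
#'
#' @param points data.frame with columns `patient_id`, `date`, `egfr`.
#' @param t0 either a single `Date` applied to all patients or a data.frame
#'   with columns `patient_id`, `t0_date`.
#' @param n_years length of follow-up in years (default 9).
#' @return data.frame with columns `patient_id`, `year_index`, `mean_egfr`,
#'   `n_measurements`.
#' @export
annualize_egfr <- function(points, t0, n_years = 9L) {
  if (nrow(points) == 0L) {
    return(data.frame(patient_id = character(), year_index = integer(),
                      mean_egfr = numeric(), n_measurements = integer(),
                      stringsAsFactors = FALSE))
  }
  if (inherits(t0, "Date") || is.character(t0)) {
    t0_of <- rep(as.Date(t0), nrow(points))
  } else {
    idx <- match(points$patient_id, t0$patient_id)
    if (anyNA(idx)) stopf("t0 date missing for patient(s): %s",
                          paste(unique(points$patient_id[is.na(idx)]), collapse = ", "))
    t0_of <- as.Date(t0$t0_date)[idx]
  }
  yrs <- years_between(t0_of, as.Date(points$date))
  keep <- yrs >= 0 & yrs < n_years
  if (!any(keep)) {
    return(data.frame(patient_id = character(), year_index = integer(),
                      mean_egfr = numeric(), n_measurements = integer(),
                      stringsAsFactors = FALSE))
  }
  pid <- as.character(points$patient_id[keep])
  yi <- as.integer(floor(yrs[keep]))
  y <- points$egfr[keep]
  key <- paste(pid, yi, sep = "\r")
  mean_egfr <- tapply(y, key, mean)
  n_meas <- tapply(y, key, length)
  parts <- strsplit(names(mean_egfr), "\r", fixed = TRUE)
  out <- data.frame(
    patient_id = vapply(parts, `[`, "", 1L),
    year_index = as.integer(vapply(parts, `[`, "", 2L)),
    mean_egfr = as.numeric(mean_egfr),
    n_measurements = as.integer(n_meas),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$year_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
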