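# internal helpers shared across modules

# Study calendar anchors: slope-assessment window and trajectory/follow-up
# window used throughout (cohort entry T0 = last eGFR on or before the
# cutover date).
default_windows <- function() {
  list(
    slope_start = as.Date("1999-10-01"),
    slope_end   = as.Date("2004-09-30"),
    traj_start  = as.Date("2004-10-01"),
    traj_end    = as.Date("2013-09-30"),
    # enrollment requires one eGFR in the first sub-window and another in
    # the final pre-cutover year
    enroll_first_end = as.Date("2003-09-30")
  )
}

years_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / DAYS_PER_YEAR
}

add_years <- function(date, years) {
  date + round(years * DAYS_PER_YEAR)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("'%s' must be positive", name)
  invisible(x)
}

# effective sample size of an MCMC draw vector via the initial positive
# sequence estimator (sums of adjacent autocorrelation pairs until negative)
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  max_lag <- min(n - 1L, 200L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

mcse <- function(x) stats::sd(x) / sqrt(ess(x))
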