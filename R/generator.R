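# Synthetic longitudinal cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# irregularly timed eGFR series with bivariate-normal random intercepts and
# slopes, residual variance proportional to the mean eGFR level, latent
# slope classes (improved / stable / declining), latent post-entry
# trajectory groups for the improved class, comorbidity prevalences linked
# to class, informative dropout (measurement series truncated by death,
# with a terminal eGFR decline in the year preceding death), and
# proportional-hazards survival whose log-hazard depends on slope class and
# trajectory group. Ground truth is retained in a separate block for
# recovery tests and never enters the analysis-facing tables.

#' Default class-conditional comorbidity prevalences
#'
#' Baseline comorbidity probabilities per latent slope class used by the
#' generator; rows improved/stable/declining, one column per flag.
#' @return a 3 x 10 matrix of probabilities.
#' @export
default_comorbidity_prevalences <- function() {
  m <- rbind(
    improved  = c(0.354, 0.847, 0.478, 0.714, 0.052, 0.010, 0.273, 0.020, 0.072, 0.053),
    stable    = c(0.311, 0.828, 0.448, 0.718, 0.040, 0.008, 0.214, 0.011, 0.051, 0.039),
    declining = c(0.501, 0.920, 0.589, 0.760, 0.086, 0.016, 0.286, 0.019, 0.075, 0.057)
  )
  colnames(m) <- COMORBIDITY_FLAGS
  m
}

#' Default latent post-entry trajectory groups for the improved class
#'
#' Four archetypes (high level/positive, intermediate/mild negative,
#' low/fast negative, high/fast negative slope) with membership
#' probabilities, post-entry eGFR level and slope, and mortality
#' log-hazard-ratios; the high-positive group carries the largest hazard.
#' @return data.frame(group, prob, level, slope, log_hr).
#' @export
default_trajectory_groups <- function() {
  # Post-entry latent groups for the improved class, shaped like the four
  # clinical archetypes (high level / positive, intermediate / mild
  # negative, low / fast negative, high / fast negative). The mortality
  # log-hazard-ratio places the highest hazard on the high-positive group.
  data.frame(
    group = c("high_positive", "intermediate_mild", "low_fast", "high_fast"),
    prob = c(0.12, 0.60, 0.23, 0.05),
    level = c(85, 64, 56, 78),
    slope = c(1.0, -1.0, -3.5, -6.0),
    log_hr = c(1.40, 0.10, 0.35, 0.50),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the analysis is designed for: class
#' mix 0.20/0.55/0.25 with mean pre-entry slopes +4.0/-0.4/-4.8
#' ml/min/1.73m^2/yr, intercepts near the low-50s eGFR band, residual
#' variance proportional to the mean eGFR (dispersion `phi`), Poisson visit
#' process calibrated to a median of 7-8 pre-entry measurements, calendar
#' anchoring to the Oct 1999 - Sep 2004 slope window and Oct 2004 - Sep 2013
#' follow-up window, and death hazard linked to slope class and trajectory
#' group (the informative-dropout mechanism).
#'
#' @param n_patients number of patients to generate.
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @param slope_class_mix named probabilities over improved/stable/declining
#'   (must sum to 1 within 1e-9).
#' @param slope_means_by_class mean latent slope per class (ml/min/1.73m^2/yr).
#' @param intercept_mean mean latent eGFR intercept at the first measurement.
#' @param random_effect_cov 2x2 covariance of (intercept, slope) random
#'   effects around the class mean.
#' @param noise_dispersion proportionality constant phi: residual variance is
#'   `phi * max(mu, variance_floor)`.
#' @param variance_floor lower clip for the mean entering the variance
#'   (ml/min/1.73m^2); keeps the variance positive when the latent line runs
#'   low.
#' @param visits_per_year_rate Poisson rate of eGFR measurement times.
#' @param post_slope_by_class post-cutover slope continuation for stable and
#'   declining patients (the improved class follows its trajectory group).
#' @param trajectory_groups data.frame(group, prob, level, slope, log_hr)
#'   of latent post-entry groups for improved patients.
#' @param group_level_sd SD of the patient-level offset around the group level.
#' @param dropout_link list with `baseline_hazard` (events/yr from the
#'   cutover date) and `class_log_hr` (named by class); group log-HRs come
#'   from `trajectory_groups$log_hr`. Setting all log-HRs to 0 removes the
#'   informative-missingness link.
#' @param terminal_decline eGFR offset (ml/min/1.73m^2) applied to
#'   measurements within one year before death; this is the planted
#'   pattern-mixture effect.
#' @param covariate_prevalences class-by-flag matrix of comorbidity
#'   prevalences (rows improved/stable/declining).
#' @param age_mean_by_class,age_sd age at first measurement by class.
#' @param female_prob,race_probs demographics.
#' @param albuminuria_probs class-by-category (normal/micro/macro) matrix;
#'   `uacr_available_prob` fraction of patients with a UACR measurement.
#' @param uacr_available_prob see above.
#' @param weight_available_prob fraction with weight data;
#'   `weight_change_mean_by_class` lb/yr drift and `weight_rate` visits/yr.
#' @param weight_change_mean_by_class,weight_rate see above.
#' @param emit `"egfr"` to write eGFR rows directly, `"creatinine"` to write
#'   serum creatinine obtained by inverting the CKD-EPI equation (exercises
#'   the eGFR computation path end-to-end).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 500L,
                             seed = 1L,
                             slope_class_mix = c(improved = 0.20, stable = 0.55, declining = 0.25),
                             slope_means_by_class = c(improved = 4.0, stable = -0.4, declining = -4.8),
                             intercept_mean = 53,
                             random_effect_cov = matrix(c(16, -0.6, -0.6, 2.25), 2, 2),
                             noise_dispersion = 0.3,
                             variance_floor = 5,
                             visits_per_year_rate = 2.2,
                             post_slope_by_class = c(stable = -1.0, declining = -2.5),
                             trajectory_groups = default_trajectory_groups(),
                             group_level_sd = 3,
                             dropout_link = list(
                               baseline_hazard = 0.045,
                               class_log_hr = c(improved = 0.25, stable = 0, declining = 0.55)
                             ),
                             terminal_decline = -5,
                             covariate_prevalences = default_comorbidity_prevalences(),
                             age_mean_by_class = c(improved = 69.5, stable = 71.1, declining = 71.7),
                             age_sd = 7.8,
                             female_prob = 0.045,
                             race_probs = c(white = 0.876, black = 0.107, other = 0.017),
                             albuminuria_probs = rbind(
                               improved  = c(0.603, 0.348, 0.049),
                               stable    = c(0.590, 0.356, 0.054),
                               declining = c(0.474, 0.417, 0.109)
                             ),
                             uacr_available_prob = 0.31,
                             weight_available_prob = 0.91,
                             weight_change_mean_by_class = c(improved = -1.2, stable = -0.45, declining = -0.4),
                             weight_rate = 1.5,
                             emit = c("egfr", "creatinine")) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0 ||
      n_patients != round(n_patients))
    stopf("'n_patients' must be a non-negative integer")
  if (abs(sum(slope_class_mix) - 1) > 1e-9)
    stopf("'slope_class_mix' must sum to 1 (got %.12f)", sum(slope_class_mix))
  if (any(slope_class_mix < 0)) stopf("'slope_class_mix' must be non-negative")
  if (!setequal(names(slope_class_mix), SLOPE_CLASSES))
    stopf("'slope_class_mix' must be named improved/stable/declining")
  assert_scalar_number(noise_dispersion, "noise_dispersion")
  if (noise_dispersion < 0) stopf("'noise_dispersion' must be non-negative")
  assert_scalar_number(visits_per_year_rate, "visits_per_year_rate", positive = TRUE)
  assert_scalar_number(variance_floor, "variance_floor", positive = TRUE)
  if (!is.matrix(random_effect_cov) || !isTRUE(all.equal(dim(random_effect_cov), c(2L, 2L))) ||
      any(diag(random_effect_cov) < 0))
    stopf("'random_effect_cov' must be a 2x2 covariance matrix")
  if (abs(sum(trajectory_groups$prob) - 1) > 1e-9)
    stopf("trajectory group probabilities must sum to 1")
  if (dropout_link$baseline_hazard < 0) stopf("baseline hazard must be non-negative")
  emit <- match.arg(emit)
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    slope_class_mix = slope_class_mix[SLOPE_CLASSES],
    slope_means_by_class = slope_means_by_class[SLOPE_CLASSES],
    intercept_mean = intercept_mean,
    random_effect_cov = random_effect_cov,
    noise_dispersion = noise_dispersion,
    variance_floor = variance_floor,
    visits_per_year_rate = visits_per_year_rate,
    post_slope_by_class = post_slope_by_class,
    trajectory_groups = trajectory_groups,
    group_level_sd = group_level_sd,
    dropout_link = dropout_link,
    terminal_decline = terminal_decline,
    covariate_prevalences = covariate_prevalences,
    age_mean_by_class = age_mean_by_class, age_sd = age_sd,
    female_prob = female_prob, race_probs = race_probs,
    albuminuria_probs = albuminuria_probs,
    uacr_available_prob = uacr_available_prob,
    weight_available_prob = weight_available_prob,
    weight_change_mean_by_class = weight_change_mean_by_class,
    weight_rate = weight_rate,
    emit = emit,
    windows = default_windows()
  )
  class(cfg) <- "generator_config"
  cfg
}

# latent mean eGFR for one patient at times t (years since initial date);
# piecewise linear with a break at the calendar cutover
latent_mean_egfr <- function(t, t_cut, a, b, cls, post_slope, group_level, group_slope) {
  pre <- a + b * pmin(t, t_cut)
  if (cls == "improved") {
    post_level <- group_level
    mu <- ifelse(t <= t_cut, pre, post_level + group_slope * (t - t_cut))
  } else {
    mu <- ifelse(t <= t_cut, pre, (a + b * t_cut) + post_slope * (t - t_cut))
  }
  pmax(mu, 5)
}

#' Generate a synthetic longitudinal cohort
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: a list with analysis-facing
#'   `measurements` (patient_id, date, analyte, value) and `patients`
#'   (patient_id, birth_date, sex, race, death_date, comorbidity flags),
#'   plus a `truth` block (true_class, true_intercept, true_slope,
#'   true_group) used only by recovery tests, and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) stopf("'config' must be a generator_config")
  set.seed(config$seed)
  w <- config$windows
  n <- config$n_patients
  empty <- function() {
    list(measurements = data.frame(patient_id = character(), date = as.Date(character()),
                                   analyte = character(), value = numeric(),
                                   stringsAsFactors = FALSE),
         patients = data.frame(patient_id = character(), stringsAsFactors = FALSE),
         truth = data.frame(patient_id = character(), stringsAsFactors = FALSE),
         config = config)
  }
  if (n == 0L) {
    out <- empty(); class(out) <- "synthetic_cohort"; return(out)
  }

  ids <- sprintf("P%05d", seq_len(n))
  cls <- sample(SLOPE_CLASSES, n, replace = TRUE, prob = config$slope_class_mix)
  re <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = config$random_effect_cov)
  if (n == 1L) re <- matrix(re, nrow = 1L)
  a <- config$intercept_mean + re[, 1L]
  b <- config$slope_means_by_class[cls] + re[, 2L]

  # trajectory group (improved only)
  tg <- config$trajectory_groups
  grp <- ifelse(cls == "improved",
                sample(tg$group, n, replace = TRUE, prob = tg$prob), "none")
  gi <- match(grp, tg$group)
  group_level <- ifelse(is.na(gi), NA_real_, tg$level[gi]) +
    stats::rnorm(n, 0, config$group_level_sd)
  group_slope <- ifelse(is.na(gi), NA_real_, tg$slope[gi])
  group_lhr <- ifelse(is.na(gi), 0, tg$log_hr[gi])

  # demographics and comorbidities, class-linked
  age <- pmin(pmax(stats::rnorm(n, config$age_mean_by_class[cls], config$age_sd), 40), 100)
  female <- stats::runif(n) < config$female_prob
  race <- sample(names(config$race_probs), n, replace = TRUE, prob = config$race_probs)
  flags <- sapply(COMORBIDITY_FLAGS, function(f)
    as.integer(stats::runif(n) < config$covariate_prevalences[cls, f]))
  if (n == 1L) flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, COMORBIDITY_FLAGS))

  # entry date uniform over the first enrollment sub-window
  span1 <- as.integer(w$enroll_first_end - w$slope_start)
  initial_date <- w$slope_start + sample.int(span1 + 1L, n, replace = TRUE) - 1L
  t_cut <- years_between(initial_date, w$slope_end)   # years from initial to cutover
  t_end <- years_between(initial_date, w$traj_end)

  # survival: exponential from the cutover date, PH in class and group
  lhr <- config$dropout_link$class_log_hr[cls] + group_lhr
  rate <- config$dropout_link$baseline_hazard * exp(lhr)
  death_after_cut <- if (all(rate > 0)) stats::rexp(n, rate) else
    ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-12)), Inf)
  post_span <- years_between(w$traj_start, w$traj_end)
  died <- death_after_cut <= post_span
  death_date <- as.Date(ifelse(died, w$slope_end + round(death_after_cut * DAYS_PER_YEAR),
                               NA_real_), origin = "1970-01-01")
  t_death <- ifelse(died, t_cut + death_after_cut, Inf)

  birth_date <- initial_date - round(age * DAYS_PER_YEAR)

  meas_list <- vector("list", n)
  post_slope_cfg <- config$post_slope_by_class
  for (i in seq_len(n)) {
    horizon <- min(t_end[i], t_death[i])
    n_vis <- stats::rpois(1L, config$visits_per_year_rate * horizon)
    tvis <- c(0, stats::runif(1L, 0.3, min(1.2, max(0.4, t_cut[i]))),
              stats::runif(n_vis, 0, horizon))
    # snap visit times to whole days so the latent value matches the
    # recorded date exactly
    tday <- sort(unique(round(tvis * DAYS_PER_YEAR)))
    tvis <- tday / DAYS_PER_YEAR
    keep_t <- tvis <= horizon
    tday <- tday[keep_t]; tvis <- tvis[keep_t]
    mu <- latent_mean_egfr(tvis, t_cut[i], a[i], b[i], cls[i],
                           post_slope = unname(post_slope_cfg[cls[i]]),
                           group_level = group_level[i], group_slope = group_slope[i])
    # terminal decline in the year preceding death (pattern-mixture signal)
    if (is.finite(t_death[i]))
      mu <- mu + ifelse(tvis > t_death[i] - 1, config$terminal_decline, 0)
    sd_e <- sqrt(config$noise_dispersion * pmax(mu, config$variance_floor))
    y <- pmax(mu + stats::rnorm(length(mu), 0, sd_e), 1)
    egfr_df <- data.frame(patient_id = ids[i], date = initial_date[i] + tday,
                          analyte = "egfr", value = y,
                          stringsAsFactors = FALSE)

    # weight series over the pre-cutover span
    wt_df <- NULL
    if (stats::runif(1L) < config$weight_available_prob) {
      n_w <- stats::rpois(1L, config$weight_rate * t_cut[i]) + 2L
      tw <- sort(stats::runif(n_w, 0, min(t_cut[i], horizon)))
      w0 <- stats::rnorm(1L, 195, 25)
      wt <- w0 + config$weight_change_mean_by_class[cls[i]] * tw +
        stats::rnorm(n_w, 0, 3)
      dw <- initial_date[i] + round(tw * DAYS_PER_YEAR)
      kw <- !duplicated(dw)
      wt_df <- data.frame(patient_id = ids[i], date = dw[kw],
                          analyte = "weight_lb", value = pmax(wt[kw], 80),
                          stringsAsFactors = FALSE)
    }

    # one UACR measurement for a subset of patients
    ua_df <- NULL
    if (stats::runif(1L) < config$uacr_available_prob) {
      cat3 <- sample(1:3, 1L, prob = config$albuminuria_probs[cls[i], ])
      val <- switch(cat3, stats::runif(1L, 1, 19.9), stats::runif(1L, 20, 300),
                    stats::runif(1L, 301, 1200))
      du <- initial_date[i] + round(stats::runif(1L, 0, min(t_cut[i], horizon)) * DAYS_PER_YEAR)
      ua_df <- data.frame(patient_id = ids[i], date = du,
                          analyte = "uacr_mg_g", value = val,
                          stringsAsFactors = FALSE)
    }
    meas_list[[i]] <- rbind(egfr_df, wt_df, ua_df)
  }
  measurements <- do.call(rbind, meas_list)
  rownames(measurements) <- NULL

  if (config$emit == "creatinine") {
    is_e <- measurements$analyte == "egfr"
    idx <- match(measurements$patient_id[is_e], ids)
    age_at <- years_between(birth_date[idx], measurements$date[is_e])
    measurements$value[is_e] <- ckd_epi_inverse(measurements$value[is_e], age_at,
                                                female[idx], race[idx] == "black")
    measurements$analyte[is_e] <- "creatinine_mg_dl"
  }

  patients <- data.frame(
    patient_id = ids,
    birth_date = birth_date,
    sex = ifelse(female, "F", "M"),
    race = race,
    death_date = death_date,
    stringsAsFactors = FALSE
  )
  patients <- cbind(patients, as.data.frame(flags))

  truth <- data.frame(
    patient_id = ids,
    true_class = cls,
    true_intercept = a,
    true_slope = b,
    true_group = grp,
    true_group_level = group_level,
    true_group_slope = group_slope,
    died = died,
    stringsAsFactors = FALSE
  )
  out <- list(measurements = measurements, patients = patients,
              truth = truth, config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d measurement rows\n",
              nrow(x$patients), nrow(x$measurements)))
  invisible(x)
}

#' Export a synthetic cohort to CSV files
#'
#' Writes `measurements.csv` and `patients.csv` (the analysis-facing
#' schemas) and `truth.csv` (latent ground truth, test-only) under `path`.
#' Re-export with the same cohort is byte-identical.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_cohort <- function(cohort, path) {
  if (!inherits(cohort, "synthetic_cohort")) stopf("'cohort' must be a synthetic_cohort")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create directory '%s'", path)
  files <- file.path(path, c("measurements.csv", "patients.csv", "truth.csv"))
  utils::write.csv(cohort$measurements, files[1L], row.names = FALSE)
  utils::write.csv(cohort$patients, files[2L], row.names = FALSE)
  utils::write.csv(cohort$truth, files[3L], row.names = FALSE)
  invisible(files)
}

#' Import a cohort previously written by [export_cohort()]
#'
#' @param path directory containing the CSV files.
#' @param with_truth read `truth.csv` as well (default TRUE when present).
#' @return a `synthetic_cohort`-shaped list (without the generating config).
#' @export
import_cohort <- function(path, with_truth = TRUE) {
  meas <- utils::read.csv(file.path(path, "measurements.csv"),
                          colClasses = c(patient_id = "character"))
  meas$date <- as.Date(meas$date)
  pats <- utils::read.csv(file.path(path, "patients.csv"),
                          colClasses = c(patient_id = "character"))
  pats$birth_date <- as.Date(pats$birth_date)
  pats$death_date <- as.Date(pats$death_date)
  truth <- NULL
  tf <- file.path(path, "truth.csv")
  if (with_truth && file.exists(tf))
    truth <- utils::read.csv(tf, colClasses = c(patient_id = "character"))
  out <- list(measurements = meas, patients = pats, truth = truth, config = NULL)
  class(out) <- "synthetic_cohort"
  out
}

#' Simulate annual-average eGFR data from a planted group-mixture model
#'
#' Draws data directly from the pattern-mixture latent trajectory model:
#' patient i in latent group k has annual means
#' \eqn{y_{it} = \beta_{k0} + \beta_{k1} t + \beta_{k2} t^2 + \gamma x_{it}
#'   + \delta d_i + \epsilon_{it}}, \eqn{\epsilon \sim N(0, \sigma^2)},
#' where `x` is the number of measurements in the year and `d` the
#' death-year-measurement indicator. Used for trajectory-model recovery
#' tests; the full cohort generator plants the same structure through the
#' measurement-level mechanism.
#'
#' @param n number of patients.
#' @param groups data.frame with columns `prob`, `intercept`, `slope` and
#'   optionally `quad` (default 0).
#' @param sigma residual SD.
#' @param gamma coefficient on the measurement-count covariate.
#' @param delta pattern-mixture coefficient on the death-year indicator.
#' @param d_prob probability a patient has `d = 1`.
#' @param years observed year indices (default 0:8).
#' @param obs_prob probability each year is observed.
#' @param seed integer seed.
#' @return list with `annual` (patient_id, year_index, mean_egfr,
#'   n_measurements), `d` (patient_id, d), and `truth` (patient_id, group).
#' @export
simulate_trajectory_data <- function(n, groups, sigma = 3, gamma = 0, delta = 0,
                                     d_prob = 0.3, years = 0:8, obs_prob = 0.9,
                                     seed = 1L) {
  set.seed(seed)
  if (abs(sum(groups$prob) - 1) > 1e-9) stopf("group probabilities must sum to 1")
  quad <- groups$quad %||% rep(0, nrow(groups))
  ids <- sprintf("S%05d", seq_len(n))
  g <- sample(nrow(groups), n, replace = TRUE, prob = groups$prob)
  d <- as.integer(stats::runif(n) < d_prob)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- years[stats::runif(length(years)) < obs_prob]
    if (length(obs) == 0L) obs <- sample(years, 1L)
    x <- stats::rpois(length(obs), 1.5) + 1L
    mu <- groups$intercept[g[i]] + groups$slope[g[i]] * obs + quad[g[i]] * obs^2 +
      gamma * x + delta * d[i]
    rows[[i]] <- data.frame(patient_id = ids[i], year_index = as.integer(obs),
                            mean_egfr = mu + stats::rnorm(length(obs), 0, sigma),
                            n_measurements = x, stringsAsFactors = FALSE)
  }
  list(annual = do.call(rbind, rows),
       d = data.frame(patient_id = ids, d = d, stringsAsFactors = FALSE),
       truth = data.frame(patient_id = ids, group = g, stringsAsFactors = FALSE))
}
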