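# Cohort construction: inclusion/exclusion rules, T0 definition, baseline
# covariate capture. Sensitivity-analysis variants (wider slope window,
# liberalized second-eGFR requirement, washout, minimum measurement count,
# ESRD handling) are configuration, not separate code paths.

#' Cohort-builder configuration
#'
#' @param slope_window Date vector of length 2: period over which the
#'   pre-entry eGFR slope is assessed (default Oct 1 1999 - Sep 30 2004).
#'   Cohort entry T0 is the last eGFR on or before `slope_window[2]`.
#' @param traj_window Date vector of length 2: follow-up period (default
#'   Oct 1 2004 - Sep 30 2013); deaths are ascertained through its end.
#' @param require_second_qualifying_egfr require another eGFR in [45, 60]
#'   at least 90 days after the initial one (default TRUE).
#' @param second_egfr_window optional Date vector of length 2 restricting
#'   where the second qualifying eGFR may fall (stricter enrollment
#'   reading); default NULL = anywhere inside the slope window.
#' @param initial_egfr_range inclusive eGFR range for eligibility
#'   (default c(45, 60), early CKD stage 3).
#' @param washout_exclusion exclude patients with any of `washout_flags`
#'   (column names in `patients`) set, emulating an AKI/hospitalization
#'   washout (default FALSE).
#' @param washout_flags character vector of flag column names.
#' @param min_egfr_measurements_pre_t0 minimum number of eGFR measurements
#'   in the slope window (default 0; sensitivity value 5).
#' @param esrd_handling "keep" (default), "exclude" (drop patients with any
#'   outpatient eGFR < 15 ml/min/1.73m^2), or "censor" (censor follow-up at
#'   the first post-T0 eGFR < 15).
#' @param exclusion_flags column names in `patients` that force exclusion
#'   when set (e.g. prior dialysis or kidney transplant indicators); only
#'   columns actually present are used.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(slope_window = c(as.Date("1999-10-01"), as.Date("2004-09-30")),
                          traj_window = c(as.Date("2004-10-01"), as.Date("2013-09-30")),
                          require_second_qualifying_egfr = TRUE,
                          second_egfr_window = NULL,
                          initial_egfr_range = c(45, 60),
                          washout_exclusion = FALSE,
                          washout_flags = c("aki", "hospitalization"),
                          min_egfr_measurements_pre_t0 = 0L,
                          esrd_handling = c("keep", "exclude", "censor"),
                          exclusion_flags = c("dialysis", "kidney_transplant")) {
  slope_window <- as.Date(slope_window); traj_window <- as.Date(traj_window)
  if (slope_window[1L] >= slope_window[2L] || traj_window[1L] >= traj_window[2L])
    stopf("windows must be ordered date ranges")
  if (traj_window[2L] <= slope_window[1L])
    stopf("trajectory window must extend beyond the slope window")
  structure(list(
    slope_window = slope_window, traj_window = traj_window,
    require_second_qualifying_egfr = isTRUE(require_second_qualifying_egfr),
    second_egfr_window = if (!is.null(second_egfr_window)) as.Date(second_egfr_window),
    initial_egfr_range = initial_egfr_range,
    washout_exclusion = isTRUE(washout_exclusion),
    washout_flags = washout_flags,
    min_egfr_measurements_pre_t0 = as.integer(min_egfr_measurements_pre_t0),
    esrd_handling = match.arg(esrd_handling),
    exclusion_flags = exclusion_flags
  ), class = "cohort_config")
}

# eGFR rows from a measurements table; converts creatinine rows through the
# CKD-EPI equation when no direct eGFR rows exist for a patient set.
egfr_measurements <- function(measurements, patients) {
  m <- measurements
  has_egfr <- m$analyte == "egfr"
  out <- m[has_egfr, c("patient_id", "date", "value")]
  is_cr <- m$analyte == "creatinine_mg_dl"
  if (any(is_cr)) {
    cr <- m[is_cr, , drop = FALSE]
    idx <- match(cr$patient_id, patients$patient_id)
    if (anyNA(idx)) stopf("creatinine rows for unknown patient(s)")
    age <- years_between(as.Date(patients$birth_date)[idx], as.Date(cr$date))
    e <- ckd_epi_egfr(cr$value, age,
                      female = patients$sex[idx] == "F",
                      black = patients$race[idx] == "black")
    out <- rbind(out, data.frame(patient_id = cr$patient_id, date = cr$date,
                                 value = e, stringsAsFactors = FALSE))
  }
  names(out)[3L] <- "egfr"
  out$date <- as.Date(out$date)
  out[order(out$patient_id, out$date), , drop = FALSE]
}

#' Build the analysis cohort
#'
#' Applies the inclusion/exclusion rules in a fixed order and assembles one
#' analysis-ready row per included patient. For each excluded patient the
#' first failing rule is logged; exclusion counts plus the cohort size sum
#' to the number of input patients.
#'
#' Rules, in order: (1) missing birth date; (2) duplicate
#' (patient, date, analyte) rows are an error, not an exclusion; (3) no
#' eGFR in the slope window; (4) initial eGFR (mean of same-day values at
#' the first measurement date in the window) outside the eligibility range;
#' (5) no second qualifying eGFR in range at >= 90 days (if required);
#' (6) exclusion flags (e.g. prior dialysis/transplant); (7) washout flags
#' (if enabled); (8) fewer than the minimum pre-T0 eGFR count; (9) ESRD
#' exclusion (if configured); (10) no follow-up time after T0.
#'
#' @param measurements long table: patient_id, date, analyte
#'   (egfr / creatinine_mg_dl / weight_lb / uacr_mg_g), value.
#' @param patients one row per patient: patient_id, birth_date, sex, race,
#'   death_date (NA for survivors), 0/1 comorbidity flag columns.
#' @param config a [cohort_config()].
#' @param diagnoses optional long table (patient_id, date, condition) of
#'   dated diagnoses; when given, baseline comorbidity flags are derived
#'   from conditions dated within the 5 years before T0 instead of the
#'   static columns.
#' @return list with `cohort` (one row per included patient) and
#'   `exclusions` (patient_id, reason, rule_order).
#' @export
build_cohort <- function(measurements, patients, config = cohort_config(),
                         diagnoses = NULL) {
  stopifnot(is.data.frame(measurements), is.data.frame(patients))
  measurements$date <- as.Date(measurements$date)
  patients$birth_date <- as.Date(patients$birth_date)
  patients$death_date <- as.Date(patients$death_date)

  dup <- duplicated(measurements[c("patient_id", "date", "analyte")])
  if (any(dup))
    stopf("duplicate (patient, date, analyte) measurement rows for patient(s): %s",
          paste(unique(measurements$patient_id[dup]), collapse = ", "))

  eg <- egfr_measurements(measurements, patients)
  sw <- config$slope_window
  rng <- config$initial_egfr_range
  excl <- list()
  note <- function(id, reason, order) {
    excl[[length(excl) + 1L]] <<- data.frame(patient_id = id, reason = reason,
                                             rule_order = order,
                                             stringsAsFactors = FALSE)
  }

  rows <- vector("list", nrow(patients))
  for (j in seq_len(nrow(patients))) {
    p <- patients[j, ]
    id <- p$patient_id
    if (is.na(p$birth_date)) { note(id, "missing birth_date", 1L); next }
    e <- eg[eg$patient_id == id, , drop = FALSE]
    e_win <- e[e$date >= sw[1L] & e$date <= sw[2L], , drop = FALSE]
    if (nrow(e_win) == 0L) { note(id, "no eGFR in slope window", 2L); next }
    # initial eGFR: mean of same-day values at the first date in the window
    d0 <- min(e_win$date)
    initial_egfr <- mean(e_win$egfr[e_win$date == d0])
    if (initial_egfr < rng[1L] || initial_egfr > rng[2L]) {
      note(id, "initial eGFR out of range", 3L); next
    }
    if (config$require_second_qualifying_egfr) {
      cand <- e_win[e_win$date >= d0 + 90L &
                      e_win$egfr >= rng[1L] & e_win$egfr <= rng[2L], , drop = FALSE]
      if (!is.null(config$second_egfr_window))
        cand <- cand[cand$date >= config$second_egfr_window[1L] &
                       cand$date <= config$second_egfr_window[2L], , drop = FALSE]
      if (nrow(cand) == 0L) { note(id, "no second qualifying eGFR", 4L); next }
    }
    ef <- intersect(config$exclusion_flags, names(patients))
    if (length(ef) && any(unlist(p[ef]) == 1, na.rm = TRUE)) {
      note(id, "prior dialysis or transplant", 5L); next
    }
    if (config$washout_exclusion) {
      wf <- intersect(config$washout_flags, names(patients))
      if (length(wf) && any(unlist(p[wf]) == 1, na.rm = TRUE)) {
        note(id, "AKI or hospitalization during washout", 6L); next
      }
    }
    if (nrow(e_win) < config$min_egfr_measurements_pre_t0) {
      note(id, "fewer than minimum pre-T0 eGFR measurements", 7L); next
    }
    if (config$esrd_handling == "exclude" && any(e$egfr < 15)) {
      note(id, "ESRD (eGFR < 15)", 8L); next
    }
    # T0: last eGFR on or before the cutover date
    t0_date <- max(e_win$date)
    t0_egfr <- mean(e_win$egfr[e_win$date == t0_date])
    # follow-up: death dates after the ascertainment window censor at its end
    end_fu <- config$traj_window[2L]
    death <- p$death_date
    if (config$esrd_handling == "censor") {
      esrd_dates <- e$date[e$egfr < 15 & e$date > t0_date]
      if (length(esrd_dates)) end_fu <- min(end_fu, min(esrd_dates))
    }
    if (!is.na(death) && death <= end_fu) {
      death_flag <- 1L; fu_end <- death
    } else {
      death_flag <- 0L; fu_end <- end_fu
    }
    followup_time <- years_between(t0_date, fu_end)
    if (followup_time <= 0) { note(id, "no follow-up after T0", 9L); next }

    base <- capture_baseline(id, t0_date, measurements, p, diagnoses)
    rows[[j]] <- data.frame(
      patient_id = id, t0_date = t0_date,
      initial_date = d0, initial_egfr = initial_egfr, t0_egfr = t0_egfr,
      age_at_t0 = years_between(p$birth_date, t0_date),
      sex = p$sex, race = p$race,
      annual_pct_egfr_change = if (t0_date > d0)
        annual_pct_egfr_change(initial_egfr, t0_egfr, d0, t0_date) else NA_real_,
      n_egfr_pre_t0 = nrow(e_win),
      followup_time = followup_time, death_flag = death_flag,
      stringsAsFactors = FALSE
    ) |> cbind(base)
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(cohort)) cohort <- data.frame(patient_id = character())
  rownames(cohort) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), reason = character(),
               rule_order = integer(), stringsAsFactors = FALSE)
  list(cohort = cohort, exclusions = exclusions)
}

#' Baseline covariate capture for one patient
#'
#' Computes comorbidity flags, annual percent weight change and albuminuria
#' category using only data dated within the 5 years preceding T0 (the
#' baseline window), inclusive of T0. Missing data yield `NA`, not errors.
#'
#' @param patient_id patient identifier.
#' @param t0_date the patient's T0 (`Date`).
#' @param measurements long measurements table (see [build_cohort()]).
#' @param patient_row the patient's row from the patients table.
#' @param diagnoses optional dated diagnoses table.
#' @return one-row data.frame of baseline covariates.
#' @export
capture_baseline <- function(patient_id, t0_date, measurements, patient_row,
                             diagnoses = NULL) {
  t0_date <- as.Date(t0_date)
  win_lo <- add_years(t0_date, -5)
  m <- measurements[measurements$patient_id == patient_id, , drop = FALSE]
  m <- m[as.Date(m$date) >= win_lo & as.Date(m$date) <= t0_date, , drop = FALSE]

  if (!is.null(diagnoses)) {
    dg <- diagnoses[diagnoses$patient_id == patient_id, , drop = FALSE]
    dg <- dg[as.Date(dg$date) >= win_lo & as.Date(dg$date) <= t0_date, , drop = FALSE]
    flags <- as.data.frame(as.list(
      stats::setNames(as.integer(COMORBIDITY_FLAGS %in% dg$condition), COMORBIDITY_FLAGS)))
  } else {
    present <- intersect(COMORBIDITY_FLAGS, names(patient_row))
    flags <- as.data.frame(as.list(
      stats::setNames(vapply(COMORBIDITY_FLAGS, function(f)
        if (f %in% present) as.integer(patient_row[[f]]) else NA_integer_,
        integer(1L)), COMORBIDITY_FLAGS)))
  }

  wt <- m[m$analyte == "weight_lb", , drop = FALSE]
  wchg <- annual_pct_weight_change(wt$date, wt$value)

  ua <- m[m$analyte == "uacr_mg_g", , drop = FALSE]
  acat <- if (nrow(ua)) {
    last <- ua[which.max(as.Date(ua$date)), ]
    as.character(albuminuria_category(last$value))
  } else NA_character_

  cbind(flags, data.frame(annual_pct_weight_change = wchg,
                          albuminuria_category = acat,
                          stringsAsFactors = FALSE))
}
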