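# End-to-end pipeline: synthetic cohort -> eGFR derivations -> cohort
# construction -> Bayesian slope classification -> trajectory modeling of
# the improved subcohort -> phenotype collapsing -> association models ->
# structured report.

# death-year-measurement indicator: 1 if the patient died and has an eGFR
# measurement dated within one year before death
death_year_indicator <- function(egfr_points, patients) {
  death <- as.Date(patients$death_date)
  names(death) <- patients$patient_id
  ids <- unique(egfr_points$patient_id)
  d <- vapply(ids, function(id) {
    dd <- death[[id]]
    if (is.na(dd)) return(0L)
    ds <- as.Date(egfr_points$date[egfr_points$patient_id == id])
    as.integer(any(ds > dd - DAYS_PER_YEAR & ds <= dd))
  }, integer(1L))
  data.frame(patient_id = ids, d = d, stringsAsFactors = FALSE)
}

#' Run the full renal-function-trajectory analysis
#'
#' Generates (or accepts) a longitudinal cohort, builds the analysis table,
#' classifies pre-entry eGFR slopes with the hierarchical Bayesian model,
#' fits Cox mortality models by slope class at the requested horizons and a
#' multinomial membership model, fits the pattern-mixture trajectory model
#' to the improved subcohort, collapses groups into phenotypes, fits
#' phenotype mortality models (reference: stable-slope patients), and
#' assembles the report.
#'
#' @param config a [generator_config()] for synthetic input, or NULL when
#'   `measurements`/`patients` are supplied directly.
#' @param seed integer; overrides the generator seed and seeds the model
#'   fits.
#' @param measurements,patients optional observed input tables (see
#'   [build_cohort()]).
#' @param cohort_cfg a [cohort_config()].
#' @param slope_spec a [slope_model_spec()].
#' @param traj_spec a [trajectory_spec()].
#' @param rule a [phenotype_rule()].
#' @param horizons Cox horizons in years (default c(1, 3, 5, 9)).
#' @param verbose print stage-by-stage sample sizes.
#' @return list with `report` (a `renaltraj_report`), `cohort` (analysis
#'   table with `class` and `phenotype`), `slope_fit`, `trajectory`,
#'   `phenotypes`, `exclusions`, and `truth` when synthetic.
#' @export
run_pipeline <- function(config = generator_config(), seed = NULL,
                         measurements = NULL, patients = NULL,
                         cohort_cfg = cohort_config(),
                         slope_spec = slope_model_spec(),
                         traj_spec = trajectory_spec(),
                         rule = phenotype_rule(),
                         horizons = c(1, 3, 5, 9),
                         verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  truth <- NULL
  if (is.null(measurements)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    syn <- generate_cohort(config)
    measurements <- syn$measurements
    patients <- syn$patients
    truth <- syn$truth
    say("generated %d patients, %d measurement rows", nrow(patients), nrow(measurements))
  }
  if (!is.null(seed)) {
    slope_spec$seed <- as.integer(seed) + 1L
    traj_spec$seed <- as.integer(seed) + 2L
  }

  built <- build_cohort(measurements, patients, cohort_cfg)
  cohort <- built$cohort
  say("cohort: %d included, %d excluded", nrow(cohort), nrow(built$exclusions))
  if (!nrow(cohort)) stopf("no patients satisfied the inclusion rules")

  eg <- egfr_measurements(measurements, patients)
  t0 <- cohort[, c("patient_id", "t0_date")]
  idx <- match(eg$patient_id, cohort$patient_id)
  in_cohort <- !is.na(idx)

  # pre-entry series inside the slope window
  pre <- eg[in_cohort & eg$date >= cohort_cfg$slope_window[1L] &
              eg$date <= cohort$t0_date[idx], , drop = FALSE]
  names(pre)[names(pre) == "egfr"] <- "egfr"
  sfit <- fit_slope_model(pre, slope_spec)
  cohort$class <- sfit$posterior$class[match(cohort$patient_id, sfit$posterior$patient_id)]
  say("slope classes: %s",
      paste(names(table(cohort$class)), table(cohort$class), collapse = ", "))

  cox_class <- stats::setNames(lapply(horizons, function(h)
    fit_cox(cohort, assoc_spec(exposure = "class", reference = "stable", horizon = h))),
    horizons)
  multi <- fit_multinomial(cohort, assoc_spec(exposure = "class", reference = "stable",
                                              covariates = setdiff(DEFAULT_ADJUSTMENT, "t0_egfr")))

  # trajectory stage: improved subcohort, post-entry annual averages
  improved <- cohort[cohort$class == "improved", , drop = FALSE]
  trajectory <- phen <- NULL
  cox_phen <- NULL
  if (nrow(improved) >= 2L) {
    post <- eg[eg$patient_id %in% improved$patient_id &
                 eg$date > cohort_cfg$slope_window[2L] &
                 eg$date <= cohort_cfg$traj_window[2L], , drop = FALSE]
    annual <- annualize_egfr(post, improved[, c("patient_id", "t0_date")])
    with_data <- unique(annual$patient_id)
    say("trajectory stage: %d improved patients, %d with post-entry data",
        nrow(improved), length(with_data))
    if (length(with_data) >= max(traj_spec$k_range) * 2L) {
      dind <- death_year_indicator(eg[eg$patient_id %in% with_data, , drop = FALSE],
                                   patients)
      trajectory <- select_num_groups(annual, dind, traj_spec)
      summ <- summarize_groups(trajectory)
      phen <- map_all_groups(summ, trajectory$memberships, rule)
      cohort$phenotype <- phen$patients$phenotype[
        match(cohort$patient_id, phen$patients$patient_id)]
      # phenotype mortality vs stable-slope reference
      sub <- cohort[cohort$class == "stable" | !is.na(cohort$phenotype), , drop = FALSE]
      sub$phenotype_vs_stable <- ifelse(sub$class == "stable", "stable",
                                        as.character(sub$phenotype))
      sub <- sub[!is.na(sub$phenotype_vs_stable), , drop = FALSE]
      present <- unique(sub$phenotype_vs_stable)
      cox_phen <- stats::setNames(lapply(horizons, function(h)
        fit_cox(sub, assoc_spec(exposure = "phenotype_vs_stable",
                                reference = "stable", horizon = h))),
        horizons)
    }
  }
  if (is.null(trajectory)) say("trajectory stage skipped")

  report <- build_report(cohort,
                         cox_by_horizon = cox_class,
                         multinomial = multi,
                         trajectory = trajectory,
                         phenotype_map = phen,
                         cox_phenotype = cox_phen)
  list(report = report, cohort = cohort, slope_fit = sfit,
       trajectory = trajectory, phenotypes = phen,
       cox_by_class = cox_class, cox_by_phenotype = cox_phen,
       multinomial = multi,
       exclusions = built$exclusions, truth = truth)
}
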