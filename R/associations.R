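# Adjusted association models: Cox proportional hazards for death at fixed
# horizons (administrative censoring at the horizon), multinomial logistic
# regression for slope-class / phenotype membership, and Wald interaction
# tests between the exposure and albuminuria.

#' Association model specification
#'
#' @param exposure column name of the exposure factor (e.g. `class` or
#'   `phenotype`).
#' @param reference reference level of the exposure.
#' @param covariates adjustment covariates (default: age, race, gender, the
#'   ten comorbidity flags, and eGFR at cohort entry). Race enters as
#'   indicators against white; age and eGFR enter linearly.
#' @param horizon follow-up horizon in years for Cox models (deaths after
#'   the horizon are censored at the horizon); default 9.
#' @param ties ties method for the Cox partial likelihood (default
#'   "breslow"; "efron" available).
#' @param interaction_with optional column name whose product terms with
#'   the exposure are added (used by [test_interaction()]).
#' @param alpha significance level for confidence intervals (default 0.05).
#' @return object of class `assoc_spec`.
#' @export
assoc_spec <- function(exposure = "class", reference = "stable",
                       covariates = DEFAULT_ADJUSTMENT,
                       horizon = 9, ties = c("breslow", "efron"),
                       interaction_with = NULL, alpha = 0.05) {
  structure(list(exposure = exposure, reference = reference,
                 covariates = covariates, horizon = horizon,
                 ties = match.arg(ties), interaction_with = interaction_with,
                 alpha = alpha), class = "assoc_spec")
}

prepare_assoc_data <- function(cohort, spec) {
  df <- as.data.frame(cohort)
  df[[spec$exposure]] <- stats::relevel(factor(df[[spec$exposure]]), ref = spec$reference)
  if ("race" %in% names(df)) df$race <- stats::relevel(factor(df$race), ref = "white")
  if ("sex" %in% names(df)) df$sex <- factor(df$sex)
  covs <- intersect(spec$covariates, names(df))
  # drop covariates with a single observed level (no information)
  keep <- vapply(covs, function(v) length(unique(df[[v]][!is.na(df[[v]])])) > 1L, TRUE)
  list(df = df, covariates = covs[keep])
}

result_table <- function(coefs, ses, n, events, converged, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(term = names(coefs), estimate = unname(coefs), se = unname(ses),
             ratio = exp(unname(coefs)),
             ci_low = exp(unname(coefs) - z * unname(ses)),
             ci_high = exp(unname(coefs) + z * unname(ses)),
             p_value = 2 * stats::pnorm(-abs(unname(coefs) / unname(ses))),
             n = n, events = events, converged = converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cox proportional-hazards model of death at a fixed horizon
#'
#' Maximizes the Cox partial likelihood (Breslow ties by default) for time
#' from cohort entry to death, with follow-up administratively truncated at
#' `spec$horizon` years (deaths beyond the horizon count as censored at the
#' horizon). The fitting engine is `survival::coxph`; its estimates are
#' validated against a brute-force partial-likelihood maximization in the
#' package tests.
#'
#' @param cohort analysis table with `followup_time` (years), `death_flag`,
#'   the exposure column and covariates.
#' @param spec an [assoc_spec()].
#' @return list with `result` (term-level table: log-HR, SE, HR, CI, p),
#'   `fit` (the coxph object), `n`, `events`.
#' @export
fit_cox <- function(cohort, spec = assoc_spec()) {
  pd <- prepare_assoc_data(cohort, spec)
  df <- pd$df
  h <- spec$horizon
  df$.time <- pmin(df$followup_time, h)
  df$.event <- as.integer(df$death_flag == 1 & df$followup_time <= h)
  rhs <- c(spec$exposure, pd$covariates)
  if (!is.null(spec$interaction_with))
    rhs <- c(rhs, spec$interaction_with,
             paste(spec$exposure, spec$interaction_with, sep = ":"))
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(rhs, collapse = " + ")))
  use <- stats::complete.cases(df[, c(".time", ".event", spec$exposure, pd$covariates,
                                      spec$interaction_with), drop = FALSE])
  df <- df[use, , drop = FALSE]
  events <- sum(df$.event)
  if (events < 1L) stopf("no death events within the %g-year horizon", h)
  fit <- survival::coxph(form, data = df, ties = spec$ties,
                         control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-14,
                                                           iter.max = 50))
  conv <- is.null(fit$info) && all(is.finite(sqrt(diag(fit$var))))
  res <- result_table(stats::coef(fit), sqrt(diag(fit$var)),
                      n = nrow(df), events = events, converged = conv,
                      alpha = spec$alpha)
  list(result = res, fit = fit, n = nrow(df), events = events)
}

#' Multinomial logistic regression for class or phenotype membership
#'
#' Maximum-likelihood multinomial logit (via `nnet::multinom`, run to a
#' tight tolerance) of the outcome factor on the adjustment covariates;
#' odds ratios are reported per non-reference outcome level. With a
#' two-level outcome the fit coincides with binary logistic regression,
#' which the package tests verify against `glm`.
#'
#' @param cohort analysis table; the outcome is `spec$exposure` and the
#'   reference level `spec$reference`.
#' @param spec an [assoc_spec()].
#' @return list with `result` (term-level table per outcome level, columns
#'   as in [fit_cox()] plus `level`), `fit`, `n`.
#' @export
fit_multinomial <- function(cohort, spec = assoc_spec()) {
  pd <- prepare_assoc_data(cohort, spec)
  df <- pd$df
  rhs <- if (length(pd$covariates)) paste(pd$covariates, collapse = " + ") else "1"
  form <- stats::as.formula(paste(spec$exposure, "~", rhs))
  use <- stats::complete.cases(df[, c(spec$exposure, pd$covariates), drop = FALSE])
  df <- df[use, , drop = FALSE]
  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 1000L,
                        reltol = 1e-14)
  conv <- fit$convergence == 0
  cf <- stats::coef(fit)
  # Wald SEs from the Hessian of the negative log-likelihood
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.matrix(cf)) {
    levels_ <- rownames(cf)
    terms_ <- colnames(cf)
  } else {
    levels_ <- setdiff(levels(df[[spec$exposure]]), spec$reference)
    terms_ <- names(cf)
    cf <- matrix(cf, 1L, dimnames = list(levels_, terms_))
  }
  rows <- lapply(levels_, function(lv) {
    nm <- paste(lv, terms_, sep = ":")
    ses <- if (!is.null(vc)) sqrt(diag(vc)[nm]) else rep(NA_real_, length(terms_))
    out <- result_table(stats::setNames(cf[lv, ], terms_), ses,
                        n = nrow(df), events = NA_integer_, converged = conv,
                        alpha = spec$alpha)
    out$level <- lv
    out
  })
  sep <- vapply(rows, function(r) any(abs(r$estimate) > 15), TRUE)
  if (any(sep))
    warning(sprintf("possible complete separation for level(s): %s",
                    paste(levels_[sep], collapse = ", ")), call. = FALSE)
  list(result = do.call(rbind, rows), fit = fit, n = nrow(df))
}

#' Wald interaction test between the exposure and albuminuria
#'
#' Adds exposure-by-albuminuria product terms to the Cox model and returns
#' the Wald p-value of each product coefficient plus the joint Wald
#' chi-square test across all product terms.
#'
#' @param cohort analysis table; must contain `spec$interaction_with` with
#'   at least two observed levels.
#' @param spec an [assoc_spec()] with `interaction_with` set (default
#'   `albuminuria_category`).
#' @return list with `per_term` (term, estimate, se, p_value), `joint`
#'   (statistic, df, p_value), and the underlying `fit`.
#' @export
test_interaction <- function(cohort, spec = assoc_spec(interaction_with = "albuminuria_category")) {
  if (is.null(spec$interaction_with)) stopf("spec$interaction_with must be set")
  v <- cohort[[spec$interaction_with]]
  if (is.null(v)) stopf("column '%s' not found", spec$interaction_with)
  if (length(unique(v[!is.na(v)])) < 2L)
    stopf("'%s' has a single observed level; interaction not estimable",
          spec$interaction_with)
  if (!is.factor(v)) cohort[[spec$interaction_with]] <- factor(v)
  cf <- fit_cox(cohort, spec)
  beta <- stats::coef(cf$fit)
  V <- cf$fit$var
  is_prod <- grepl(":", names(beta), fixed = TRUE)
  if (!any(is_prod)) stopf("no estimable product terms (empty cell combinations?)")
  b <- beta[is_prod]
  ok <- is.finite(b)
  if (!all(ok))
    warning("some product terms are inestimable (empty cells) and were dropped",
            call. = FALSE)
  b <- b[ok]
  Vb <- V[is_prod, is_prod, drop = FALSE][ok, ok, drop = FALSE]
  se <- sqrt(diag(Vb))
  per_term <- data.frame(term = names(b), estimate = unname(b), se = se,
                         p_value = 2 * stats::pnorm(-abs(b / se)),
                         stringsAsFactors = FALSE, row.names = NULL)
  stat <- tryCatch(as.numeric(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
  joint <- data.frame(statistic = stat, df = length(b),
                      p_value = stats::pchisq(stat, length(b), lower.tail = FALSE))
  list(per_term = per_term, joint = joint, fit = cf$fit)
}

#' Assemble the structured analysis report
#'
#' Collects descriptives by slope class, hazard-ratio grids across
#' horizons, odds-ratio grids, the trajectory-selection ladder and the
#' phenotype map into one list; all entries are plain data.frames traceable
#' to the upstream artifacts, and regeneration from the same inputs is
#' byte-identical.
#'
#' @param cohort analysis table with a `class` column.
#' @param cox_by_horizon named list (horizon -> `fit_cox()` output) for the
#'   slope-class exposure.
#' @param multinomial `fit_multinomial()` output for slope class (optional).
#' @param trajectory selected `trajectory_fit` (optional).
#' @param phenotype_map `map_all_groups()` output (optional).
#' @param cox_phenotype named list (horizon -> `fit_cox()` output) for the
#'   phenotype exposure (optional).
#' @return object of class `renaltraj_report`.
#' @export
build_report <- function(cohort, cox_by_horizon = NULL, multinomial = NULL,
                         trajectory = NULL, phenotype_map = NULL,
                         cox_phenotype = NULL) {
  if (is.null(cohort) || !nrow(cohort)) stopf("missing upstream artifact: cohort")
  cls <- factor(cohort$class, levels = SLOPE_CLASSES)
  desc <- data.frame(
    class = SLOPE_CLASSES,
    n = as.integer(table(cls)),
    share = as.numeric(prop.table(table(cls))),
    deaths = as.integer(tapply(cohort$death_flag, cls, sum)),
    mean_age = as.numeric(tapply(cohort$age_at_t0, cls, mean)),
    mean_t0_egfr = as.numeric(tapply(cohort$t0_egfr, cls, mean)),
    stringsAsFactors = FALSE
  )
  hr_grid <- function(lst) {
    if (is.null(lst)) return(NULL)
    do.call(rbind, lapply(names(lst), function(h) {
      r <- lst[[h]]$result
      r$horizon <- as.numeric(h)
      r
    }))
  }
  rep_ <- list(
    descriptives_by_class = desc,
    hr_by_class = hr_grid(cox_by_horizon),
    or_by_class = if (!is.null(multinomial)) multinomial$result,
    trajectory_selection = if (!is.null(trajectory)) trajectory$selection,
    trajectory_groups = if (!is.null(trajectory)) summarize_groups(trajectory),
    trajectory_skipped = is.null(trajectory),
    phenotype_groups = if (!is.null(phenotype_map)) phenotype_map$groups,
    phenotype_shares = if (!is.null(phenotype_map))
      as.data.frame(phenotype_map$shares, stringsAsFactors = FALSE),
    hr_by_phenotype = hr_grid(cox_phenotype)
  )
  class(rep_) <- "renaltraj_report"
  rep_
}

#' @export
print.renaltraj_report <- function(x, ...) {
  cat("<renaltraj_report>\n")
  cat("Slope-class descriptives:\n")
  print(x$descriptives_by_class, digits = 3)
  if (x$trajectory_skipped) {
    cat("Trajectory stage: skipped (no improved subcohort)\n")
  } else {
    cat("Trajectory selection ladder:\n")
    print(x$trajectory_selection, digits = 4)
    cat("Phenotype groups:\n")
    if (!is.null(x$phenotype_groups)) print(x$phenotype_groups, digits = 3)
  }
  invisible(x)
}
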