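# Collapse fitted trajectory groups into four clinical phenotypes from the
# group intercept level and annual percent eGFR change category.

#' Phenotype rule: intercept and percent-change cut points
#'
#' The intercept axis splits at `intercept_cuts` into low / intermediate /
#' high; the annual percent change axis splits at `pct_change_cuts` into
#' fast negative / mild negative / positive (change >= 0 is positive,
#' change in [-3, 0) mild negative, change < -3 fast negative by default).
#' The four named cells are (high, positive) -> HIPT (High Intercept
#' Positive Trajectory), (intermediate, mild negative) -> IIMNT,
#' (low, fast negative) -> LIFNT, (high, fast negative) -> HIFNT. The
#' default cuts (60 and 70 ml/min/1.73m^2; 0 and -3 %/yr) are the round
#' numbers separating the published seven-group pattern into these four
#' phenotypes; combinations outside the four named cells map to the nearest
#' rule with a warning.
#'
#' @param intercept_cuts two increasing eGFR thresholds (low < cut1 <=
#'   intermediate < cut2 <= high).
#' @param pct_change_cuts two increasing %/yr thresholds
#'   (fast < cut1 <= mild < cut2 <= positive).
#' @return object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(intercept_cuts = c(60, 70), pct_change_cuts = c(-3, 0)) {
  if (diff(intercept_cuts) <= 0 || diff(pct_change_cuts) <= 0)
    stopf("cut points must be strictly increasing")
  structure(list(intercept_cuts = intercept_cuts, pct_change_cuts = pct_change_cuts),
            class = "phenotype_rule")
}

#' Assign a trajectory phenotype from intercept and annual percent change
#'
#' @param intercept model-implied eGFR at entry (ml/min/1.73m^2); vectorized.
#' @param annual_pct_change average annual percent eGFR change (%/yr).
#' @param rule a [phenotype_rule()].
#' @return factor with levels HIPT, IIMNT, LIFNT, HIFNT.
#' @export
assign_phenotype <- function(intercept, annual_pct_change, rule = phenotype_rule()) {
  if (any(!is.finite(intercept)) || any(!is.finite(annual_pct_change)))
    stopf("inputs must be finite")
  # 0 = low/fast, 1 = intermediate/mild, 2 = high/positive
  icat <- findInterval(intercept, rule$intercept_cuts)
  ccat <- findInterval(annual_pct_change, rule$pct_change_cuts)
  cells <- rbind(HIPT = c(2, 2), IIMNT = c(1, 1), LIFNT = c(0, 0), HIFNT = c(2, 0))
  lab <- character(length(icat))
  for (i in seq_along(icat)) {
    dist <- abs(cells[, 1L] - icat[i]) + abs(cells[, 2L] - ccat[i])
    hit <- which(dist == 0L)
    if (length(hit) == 1L) {
      lab[i] <- rownames(cells)[hit]
    } else {
      # off-grid combination: nearest rule, intercept agreement first,
      # ties broken toward the earlier rule in the fixed level order
      best <- which(dist == min(dist))
      if (length(best) > 1L) {
        ia <- best[abs(cells[best, 1L] - icat[i]) == min(abs(cells[best, 1L] - icat[i]))]
        best <- ia
      }
      lab[i] <- rownames(cells)[best[1L]]
      warning(sprintf(
        "combination (intercept %.1f, %%change %.2f) is outside the four named cells; mapped to nearest rule %s",
        intercept[i], annual_pct_change[i], lab[i]), call. = FALSE)
    }
  }
  factor(lab, levels = PHENOTYPE_LEVELS)
}

#' Map all trajectory groups to phenotypes and label patients
#'
#' Every patient inherits the phenotype of their hard-assigned trajectory
#' group.
#'
#' @param summaries output of [summarize_groups()] (columns `group`,
#'   `intercept`, `annual_pct_change`, `size`, `share`).
#' @param memberships per-patient membership table (`patient_id`, `group`),
#'   e.g. `fit$memberships`.
#' @param rule a [phenotype_rule()].
#' @return list with `groups` (group, intercept, pct_change, label) and
#'   `patients` (patient_id, group, phenotype) plus `shares` (phenotype
#'   shares, summing to 1 over labeled patients).
#' @export
map_all_groups <- function(summaries, memberships, rule = phenotype_rule()) {
  labels <- assign_phenotype(summaries$intercept, summaries$annual_pct_change, rule)
  groups <- data.frame(group = summaries$group,
                       intercept = summaries$intercept,
                       pct_change = summaries$annual_pct_change,
                       label = labels, stringsAsFactors = FALSE)
  idx <- match(memberships$group, groups$group)
  patients <- data.frame(patient_id = memberships$patient_id,
                         group = memberships$group,
                         phenotype = groups$label[idx],
                         stringsAsFactors = FALSE)
  shares <- prop.table(table(factor(patients$phenotype, levels = PHENOTYPE_LEVELS)))
  list(groups = groups, patients = patients, shares = shares)
}
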