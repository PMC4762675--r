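test_that("generator validates its configuration and handles the empty case", {
  expect_error(generator_config(n_patients = -1), "non-negative")
  expect_error(generator_config(slope_class_mix = c(improved = 0.3, stable = 0.3,
                                                    declining = 0.3)), "sum to 1")
  empty <- generate_cohort(generator_config(n_patients = 0))
  expect_s3_class(empty, "synthetic_cohort")
  expect_equal(nrow(empty$patients), 0L)
  expect_equal(nrow(empty$measurements), 0L)
})

test_that("noise-free limit with degenerate random effects puts eGFR on the latent line", {
  cfg <- generator_config(
    n_patients = 12, seed = 8,
    slope_class_mix = c(improved = 0, stable = 1, declining = 0),
    noise_dispersion = 0,
    random_effect_cov = matrix(0, 2, 2),
    terminal_decline = 0)
  syn <- generate_cohort(cfg)
  cutover <- as.Date("2004-09-30")
  for (id in syn$patients$patient_id) {
    tr <- syn$truth[syn$truth$patient_id == id, ]
    m <- syn$measurements[syn$measurements$patient_id == id &
                            syn$measurements$analyte == "egfr" &
                            syn$measurements$date <= cutover, ]
    t <- as.numeric(m$date - min(m$date)) / 365.25
    expect_equal(m$value, tr$true_intercept + tr$true_slope * t, tolerance = 1e-8)
    expect_equal(tr$true_slope, -0.4)
  }
})

test_that("per-class slope moments match the configured means within Monte-Carlo error", {
  cfg <- generator_config(n_patients = 2000, seed = 1)
  syn <- generate_cohort(cfg)
  sd_b <- sqrt(cfg$random_effect_cov[2, 2])
  for (cl in c("improved", "stable", "declining")) {
    b <- syn$truth$true_slope[syn$truth$true_class == cl]
    se <- sd_b / sqrt(length(b))
    expect_lt(abs(mean(b) - cfg$slope_means_by_class[[cl]]), 3 * se)
  }
  # realized class mix near the configured mix
  sh <- prop.table(table(syn$truth$true_class))
  for (cl in names(cfg$slope_class_mix)) {
    p <- cfg$slope_class_mix[[cl]]
    expect_lt(abs(sh[[cl]] - p), 3 * sqrt(p * (1 - p) / 2000))
  }
})

test_that("identical config and seed reproduce identical cohorts and exports", {
  cfg <- generator_config(n_patients = 40, seed = 11)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_cohort(s1, d1); export_cohort(s2, d2)
  for (f in c("measurements.csv", "patients.csv", "truth.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 10^7),
                     readBin(file.path(d2, f), "raw", n = 10^7))
  }
})

test_that("export/import round-trips all analysis-facing fields", {
  syn <- generate_cohort(generator_config(n_patients = 25, seed = 14))
  d <- withr::local_tempdir()
  export_cohort(syn, d)
  back <- import_cohort(d)
  expect_equal(back$measurements$value, syn$measurements$value, tolerance = 1e-12)
  expect_identical(back$measurements$patient_id, syn$measurements$patient_id)
  expect_identical(back$measurements$date, syn$measurements$date)
  expect_identical(back$patients$death_date, syn$patients$death_date)
  expect_identical(back$patients$diabetes, syn$patients$diabetes)
  expect_identical(back$truth$true_class, syn$truth$true_class)
  # a one-patient, two-measurement cohort writes two data lines plus a header
  one <- generate_cohort(generator_config(n_patients = 0))
  one$measurements <- data.frame(patient_id = "X", date = as.Date("2000-01-01") + c(0, 30),
                                 analyte = "egfr", value = c(50, 51))
  one$patients <- data.frame(patient_id = "X")
  one$truth <- data.frame(patient_id = "X")
  d2 <- withr::local_tempdir()
  export_cohort(one, d2)
  expect_length(readLines(file.path(d2, "measurements.csv")), 3L)
})

test_that("death-linked dropout creates class-dependent death-year measurement rates", {
  link_on <- generate_cohort(generator_config(n_patients = 2000, seed = 21))
  link_off <- generate_cohort(generator_config(
    n_patients = 2000, seed = 21,
    dropout_link = list(baseline_hazard = 0.045,
                        class_log_hr = c(improved = 0, stable = 0, declining = 0)),
    trajectory_groups = within(default_trajectory_groups(), log_hr <- rep(0, 4))))
  death_year_rate <- function(syn) {
    eg <- syn$measurements[syn$measurements$analyte == "egfr", ]
    d <- renaltraj:::death_year_indicator(eg, syn$patients)
    cls <- syn$truth$true_class[match(d$patient_id, syn$truth$patient_id)]
    tapply(d$d, cls, mean)[c("improved", "stable", "declining")]
  }
  r_on <- death_year_rate(link_on)
  r_off <- death_year_rate(link_off)
  # with the hazard link the improved and declining classes die (and hence
  # have death-year measurements) more often than the stable class
  two_prop_p <- function(r, syn) {
    n2 <- as.numeric(table(syn$truth$true_class)[c("declining", "stable")])
    x2 <- as.numeric(round(r[c("declining", "stable")] * n2))
    prop.test(x2, n2)$p.value
  }
  expect_lt(two_prop_p(r_on, link_on), 0.01)
  # without the link the rates are statistically indistinguishable
  expect_gt(two_prop_p(r_off, link_off), 0.01)
})

test_that("every generated patient has at least two eGFR-bearing dates", {
  syn <- generate_cohort(generator_config(n_patients = 300, seed = 33))
  eg <- syn$measurements[syn$measurements$analyte == "egfr", ]
  counts <- table(eg$patient_id)
  expect_true(all(counts >= 2))
  expect_setequal(names(counts), syn$patients$patient_id)
  # truth never leaks into the analysis-facing tables
  expect_false(any(grepl("true", names(syn$measurements))))
  expect_false(any(grepl("true", names(syn$patients))))
})

test_that("creatinine-emitting mode reproduces the same eGFR through the equation", {
  cfg_e <- generator_config(n_patients = 15, seed = 5, emit = "egfr")
  cfg_c <- generator_config(n_patients = 15, seed = 5, emit = "creatinine")
  syn_e <- generate_cohort(cfg_e)
  syn_c <- generate_cohort(cfg_c)
  eg_direct <- syn_e$measurements[syn_e$measurements$analyte == "egfr", ]
  eg_via_cr <- renaltraj:::egfr_measurements(syn_c$measurements, syn_c$patients)
  expect_equal(eg_via_cr$egfr, eg_direct$value, tolerance = 1e-6)
})
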