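test_that("Cox fit equals brute-force partial-likelihood maximization", {
  df <- hand_cox_data()
  fit <- fit_cox(df, assoc_spec(exposure = "x", reference = "0",
                                covariates = character(), horizon = 10))
  # exposure enters as a factor; its log-HR must match the 1-D maximizer of
  # the hand-written Breslow partial likelihood
  brute <- uniroot(function(b) cox_partial_score(b, df$followup_time, df$death_flag, df$x),
                   interval = c(-10, 10), tol = 1e-12)
  expect_lt(abs(fit$result$estimate[1] - brute$root), 1e-8)
})

test_that("a planted hazard ratio of 2 is recovered", {
  set.seed(61)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_death <- rexp(n, 0.08 * exp(log(2) * x))
  cens <- 9
  df <- data.frame(followup_time = pmin(t_death, cens),
                   death_flag = as.integer(t_death <= cens), x = x)
  fit <- fit_cox(df, assoc_spec(exposure = "x", reference = "0",
                                covariates = character(), horizon = 9))
  expect_gt(fit$result$ratio[1], 1.8)
  expect_lt(fit$result$ratio[1], 2.2)
})

test_that("null-covariate confidence intervals cover at the nominal rate", {
  set.seed(62)
  reps <- 200
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 150
    z <- rnorm(n)
    t_death <- rexp(n, 0.1)
    df <- data.frame(followup_time = pmin(t_death, 8),
                     death_flag = as.integer(t_death <= 8), z = z)
    fit <- survival::coxph(survival::Surv(followup_time, death_flag) ~ z,
                           data = df, ties = "breslow")
    ci <- confint(fit)
    covered[r] <- ci[1] < 0 && ci[2] > 0
  }
  # 3 binomial SEs around 0.95 at 200 replicates
  expect_gt(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  expect_lte(mean(covered), 1)
})

test_that("Cox estimates are invariant to time rescaling and covariate shifts", {
  cohort <- hand_cox_data()
  cohort$age <- c(61, 72, 66, 70, 75, 64)
  spec <- assoc_spec(exposure = "x", reference = "0", covariates = "age", horizon = 10)
  base <- fit_cox(cohort, spec)$result
  days <- cohort; days$followup_time <- days$followup_time * 365.25
  spec_days <- assoc_spec(exposure = "x", reference = "0", covariates = "age",
                          horizon = 10 * 365.25)
  expect_equal(fit_cox(days, spec_days)$result$estimate, base$estimate, tolerance = 1e-8)
  shifted <- cohort; shifted$age <- shifted$age + 1000
  expect_equal(fit_cox(shifted, spec)$result$estimate, base$estimate, tolerance = 1e-6)
})

test_that("event counts at the horizon are non-decreasing in the horizon", {
  syn <- generate_cohort(generator_config(n_patients = 400, seed = 19))
  b <- build_cohort(syn$measurements, syn$patients)
  cohort <- b$cohort
  cohort$class <- syn$truth$true_class[match(cohort$patient_id, syn$truth$patient_id)]
  ev <- vapply(c(1, 3, 5, 9), function(h)
    suppressWarnings(fit_cox(cohort, assoc_spec(horizon = h))$events), numeric(1))
  expect_true(all(diff(ev) >= 0))
})

test_that("two-level multinomial equals binary logistic regression", {
  set.seed(41)
  n <- 400
  df <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  p <- plogis(-0.3 + 0.8 * df$x1 - 0.5 * df$x2)
  df$y <- ifelse(runif(n) < p, "case", "control")
  fit <- fit_multinomial(df, assoc_spec(exposure = "y", reference = "control",
                                        covariates = c("x1", "x2")))
  glm_fit <- glm(I(y == "case") ~ x1 + x2, data = df, family = binomial(),
                 control = glm.control(epsilon = 1e-12))
  expect_equal(fit$result$estimate, unname(coef(glm_fit)), tolerance = 1e-6)
})

test_that("intercept-plus-factor multinomial reproduces contingency-table odds ratios", {
  # printed 2x3 toy table: rows exposure (0/1), columns outcome levels
  counts <- matrix(c(40, 25, 15,
                     30, 35, 28), nrow = 2, byrow = TRUE,
                   dimnames = list(x = c("0", "1"), y = c("ref", "mid", "high")))
  df <- as.data.frame(as.table(counts))
  df <- df[rep(seq_len(nrow(df)), df$Freq), c("x", "y")]
  fit <- fit_multinomial(df, assoc_spec(exposure = "y", reference = "ref",
                                        covariates = "x"))
  or_mid <- (35 / 30) / (25 / 40)
  or_high <- (28 / 30) / (15 / 40)
  est <- fit$result
  expect_equal(est$ratio[est$level == "mid" & est$term == "x1"], or_mid,
               tolerance = 1e-6)
  expect_equal(est$ratio[est$level == "high" & est$term == "x1"], or_high,
               tolerance = 1e-6)
})

test_that("a class-linked comorbidity odds ratio planted in the generator is recovered", {
  prev <- default_comorbidity_prevalences()
  # diabetes odds: stable 0.4/0.6, declining 0.5/0.5 -> OR exactly 1.5
  prev[, "diabetes"] <- c(0.45, 0.40, 0.50)
  prev[, "hyperlipidemia"] <- 0.7           # flat across classes: null effect
  syn <- generate_cohort(generator_config(n_patients = 5000, seed = 71,
                                          covariate_prevalences = prev))
  df <- data.frame(class = syn$truth$true_class, diabetes = syn$patients$diabetes,
                   hyperlipidemia = syn$patients$hyperlipidemia)
  fit <- fit_multinomial(df, assoc_spec(exposure = "class", reference = "stable",
                                        covariates = c("diabetes", "hyperlipidemia")))
  row <- fit$result[fit$result$level == "declining" & fit$result$term == "diabetes", ]
  expect_lt(abs(row$estimate - log(1.5)), 3 * row$se)
  # a covariate with no planted effect stays near OR 1
  null_row <- fit$result[fit$result$level == "declining" & fit$result$term == "hyperlipidemia", ]
  if (nrow(null_row)) expect_lt(abs(null_row$estimate), 3 * null_row$se)
})

test_that("interaction testing flags contracts and detects planted interactions", {
  df <- hand_cox_data()
  df$albuminuria_category <- "normal"
  expect_error(test_interaction(df, assoc_spec(exposure = "x", reference = "0",
                                               covariates = character(), horizon = 10,
                                               interaction_with = "albuminuria_category")),
               "single observed level")
  # planted multiplicative interaction
  set.seed(55)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  alb <- rbinom(n, 1, 0.4)
  lh <- log(0.08) + 0.5 * x + 0.3 * alb - 0.8 * x * alb
  td <- rexp(n, exp(lh))
  dfi <- data.frame(followup_time = pmin(td, 9), death_flag = as.integer(td <= 9),
                    x = x, albuminuria_category = factor(ifelse(alb == 1, "micro", "normal"),
                                                         levels = c("normal", "micro")))
  ti <- test_interaction(dfi, assoc_spec(exposure = "x", reference = "0",
                                         covariates = character(), horizon = 9,
                                         interaction_with = "albuminuria_category"))
  expect_lt(ti$per_term$p_value[1], 0.05)
  expect_lt(abs(ti$per_term$estimate[1] - (-0.8)), 3 * ti$per_term$se[1])
})

test_that("interaction p-values are uniform under the null", {
  set.seed(66)
  reps <- 60
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 300
    x <- rbinom(n, 1, 0.5)
    alb <- rbinom(n, 1, 0.4)
    td <- rexp(n, 0.1 * exp(0.3 * x + 0.2 * alb))
    dfi <- data.frame(followup_time = pmin(td, 9), death_flag = as.integer(td <= 9),
                      x = x, albuminuria_category = ifelse(alb == 1, "micro", "normal"))
    pvals[r] <- test_interaction(dfi, assoc_spec(exposure = "x", reference = "0",
                                                 covariates = character(), horizon = 9,
                                                 interaction_with = "albuminuria_category"))$joint$p_value
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("reports are regenerable and degrade gracefully without a trajectory stage", {
  syn <- generate_cohort(generator_config(n_patients = 300, seed = 23))
  b <- build_cohort(syn$measurements, syn$patients)
  cohort <- b$cohort
  cohort$class <- syn$truth$true_class[match(cohort$patient_id, syn$truth$patient_id)]
  cox9 <- suppressWarnings(fit_cox(cohort, assoc_spec(horizon = 9)))
  r1 <- build_report(cohort, cox_by_horizon = list("9" = cox9))
  r2 <- build_report(cohort, cox_by_horizon = list("9" = cox9))
  expect_identical(r1, r2)
  expect_true(r1$trajectory_skipped)
  expect_equal(sum(r1$descriptives_by_class$n), nrow(cohort))
  expect_error(build_report(NULL), "missing upstream")
})
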