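test_that("input contracts: degenerate patients and non-finite values are errors", {
  bad <- data.frame(patient_id = c("A", "A", "B", "B"),
                    time = c(0, 0, 0, 1), egfr = c(50, 51, 50, 52))
  expect_error(fit_slope_model(bad, slope_model_spec(n_iterations = 10, burn_in = 5)),
               "distinct.*A")
  nf <- data.frame(patient_id = "A", time = c(0, 1), egfr = c(50, NaN))
  expect_error(fit_slope_model(nf), "non-finite.*A")
  expect_error(ols_slope(data.frame(patient_id = "Z", time = c(1, 1), egfr = c(5, 6))),
               "singular.*Z")
})

test_that("a noise-free cohort pins each patient's slope at its latent value", {
  set.seed(4)
  rows <- lapply(1:20, function(i) {
    a <- runif(1, 45, 60); b <- runif(1, -5, 5)
    t <- seq(0, 4.5, length.out = 10)
    data.frame(patient_id = sprintf("P%02d", i), time = t, egfr = a + b * t)
  })
  rows[[1]] <- data.frame(patient_id = "P01", time = seq(0, 4.5, length.out = 10),
                          egfr = 55 + 4 * seq(0, 4.5, length.out = 10))
  fit <- fit_slope_model(do.call(rbind, rows),
                         slope_model_spec(n_iterations = 2000, burn_in = 500, seed = 2))
  i <- match("P01", fit$posterior$patient_id)
  expect_lt(abs(fit$posterior$posterior_mean_slope[i] - 4), 0.1)
  expect_gt(fit$posterior$p_gt_0[i], 0.99)
})

test_that("MCMC matches the closed-form posterior in the conjugate limit", {
  # homoscedastic known variance + fixed population: the per-patient
  # posterior is exactly normal
  set.seed(31)
  m <- c(50, 0); Sigma <- diag(c(25, 4)); s2 <- 9
  t <- sort(runif(7, 0, 5))
  y <- 51 + 1.2 * t + rnorm(7, 0, 3)
  spec <- slope_model_spec(n_iterations = 6000, burn_in = 1000,
                           variance_model = "fixed", fixed_variance = s2,
                           fix_population = list(m = m, Sigma = Sigma), seed = 6)
  fit <- fit_slope_model(data.frame(patient_id = "A", time = t, egfr = y), spec)
  cf <- closed_form_posterior(t, y, m, Sigma, s2)
  da <- fit$draws_intercept[, 1]; db <- fit$draws_slope[, 1]
  expect_lt(abs(mean(da) - cf$mean[1]), 3 * renaltraj:::mcse(da))
  expect_lt(abs(mean(db) - cf$mean[2]), 3 * renaltraj:::mcse(db))
  expect_lt(abs(sd(db) - sqrt(cf$cov[2, 2])), 3 * sd(db) / sqrt(2 * renaltraj:::ess(db)))
})

test_that("population parameters are recovered from simulated random effects", {
  set.seed(77)
  n <- 200
  re <- MASS::mvrnorm(n, c(53, -0.5), diag(c(16, 4)))
  rows <- lapply(seq_len(n), function(i) {
    t <- sort(c(0, runif(7, 0, 5)))
    mu <- pmax(re[i, 1] + re[i, 2] * t, 5)
    data.frame(patient_id = sprintf("P%03d", i), time = t,
               egfr = pmax(mu + rnorm(8, 0, sqrt(0.3 * pmax(mu, 5))), 1))
  })
  fit <- fit_slope_model(do.call(rbind, rows),
                         slope_model_spec(n_iterations = 3000, burn_in = 800, seed = 9))
  pop <- fit$population$draws
  expect_lt(abs(mean(pop[, "m_intercept"]) - 53), 3 * sd(pop[, "m_intercept"]))
  expect_lt(abs(mean(pop[, "m_slope"]) + 0.5), 3 * sd(pop[, "m_slope"]))
  # dispersion recovered near its generating value
  expect_lt(abs(fit$population$phi - 0.3), 0.1)
  expect_true(all(fit$diagnostics$split_rhat < 1.1, na.rm = TRUE))
})

test_that("classification rule is literal and the dual condition is impossible", {
  spec <- slope_model_spec()
  expect_equal(classify_slope(1.0, 0.0, spec), "improved")
  expect_equal(classify_slope(0.5, 0.5, spec), "stable")
  expect_equal(classify_slope(0.0, 0.96, spec), "declining")
  # "more than 95%" is strict
  expect_equal(classify_slope(0.95, 0.0, spec), "stable")
  expect_error(classify_slope(0.96, 0.96, spec), "internal error")
  expect_error(classify_slope(numeric(0), numeric(0), spec), "empty")
})

test_that("OLS slopes are exact on tiny inputs", {
  two <- data.frame(patient_id = "A", time = c(0, 1), egfr = c(50, 54))
  expect_equal(ols_slope(two)$ols_slope, 4)
  flat <- data.frame(patient_id = "B", time = 0:4, egfr = rep(48, 5))
  expect_equal(ols_slope(flat)$ols_slope, 0)
})

test_that("posterior slopes shrink toward the population mean relative to OLS", {
  cohort <- make_class_cohort(120, visits = 6, seed = 12)
  fit <- fit_slope_model(cohort$points,
                         slope_model_spec(n_iterations = 1500, burn_in = 500, seed = 3))
  o <- ols_slope(cohort$points)
  m_hat <- fit$population$m[2]
  post <- fit$posterior$posterior_mean_slope[match(o$patient_id, fit$posterior$patient_id)]
  expect_lt(mean(abs(post - m_hat)), mean(abs(o$ols_slope - m_hat)))
})

test_that("chains are deterministic given the seed and stable to burn-in choice", {
  cohort <- make_class_cohort(30, visits = 8, seed = 5)
  spec <- slope_model_spec(n_iterations = 800, burn_in = 400, seed = 10)
  f1 <- fit_slope_model(cohort$points, spec)
  f2 <- fit_slope_model(cohort$points, spec)
  expect_identical(f1$draws_slope, f2$draws_slope)
  expect_identical(f1$posterior, f2$posterior)
  # classification of well-separated patients does not depend on burn-in
  f3 <- fit_slope_model(cohort$points,
                        slope_model_spec(n_iterations = 800, burn_in = 900, seed = 10))
  clear <- abs(fit_slope_model(cohort$points, spec)$posterior$posterior_mean_slope) > 2 |
    abs(f3$posterior$posterior_mean_slope) < 0.5
  expect_equal(f1$posterior$class[clear], f3$posterior$class[clear])
})

test_that("P(classified improved) grows to 1 with the number of measurements", {
  frac_improved <- function(n_points, seed) {
    set.seed(seed)
    rows <- lapply(1:25, function(i) {
      t <- sort(c(0, runif(n_points - 1, 0, 5)))
      mu <- pmax(52 + 3 * t, 5)
      data.frame(patient_id = sprintf("P%02d", i), time = t,
                 egfr = pmax(mu + rnorm(n_points, 0, sqrt(0.3 * pmax(mu, 5))), 1))
    })
    fit <- fit_slope_model(do.call(rbind, rows),
                           slope_model_spec(n_iterations = 1200, burn_in = 400, seed = seed))
    mean(fit$posterior$class == "improved")
  }
  f4 <- frac_improved(4, 41)
  f16 <- frac_improved(16, 42)
  f64 <- frac_improved(64, 43)
  expect_lte(f4, f16)
  expect_lte(f16, f64)
  expect_gt(f64, 0.95)
})
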