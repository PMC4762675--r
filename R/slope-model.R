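# Hierarchical Bayesian mixed-effects model for pre-entry eGFR slopes.
#
# Likelihood: y_ij ~ Normal(a_i + b_i t_ij, phi * w_ij) where the variance
# is proportional to the mean eGFR level (w_ij = max(mu_ij, floor), or the
# patient's average observed eGFR, or fixed -- see `variance_model`).
# Random effects (a_i, b_i) ~ BVN(m, Sigma); hyperpriors m ~ product of
# normals, Sigma^-1 ~ Wishart, phi ~ inverse-gamma. Because the mean enters
# the variance, (a_i, b_i) and phi are updated by adaptive random-walk
# Metropolis steps inside a Gibbs scan whose m and Sigma^-1 updates are
# conjugate (Metropolis-within-Gibbs). Patients are conditionally
# independent given (m, Sigma, phi), so the per-patient Metropolis step is
# vectorized across patients.

#' Specification of the Bayesian slope model
#'
#' @param n_iterations kept MCMC draws (default 5000).
#' @param burn_in discarded warm-up draws, additional to the kept draws
#'   (default 1000); proposal scales adapt only during burn-in.
#' @param m0,s0 hyperprior means and SDs for the population (intercept,
#'   slope) mean: m ~ N(m0, diag(s0^2)). Defaults are weakly informative
#'   around the mid-50s eGFR band with a zero-centred slope.
#' @param wishart_df,wishart_scale degrees of freedom (>= 2) and 2x2 scale
#'   of the Wishart prior on Sigma^-1 (parameterized so that
#'   E[Sigma^-1] = df * scale^-1 ... the prior scale names the prior guess
#'   R with Sigma^-1 ~ Wishart(df, R^-1/df scaled); here:
#'   Sigma^-1 ~ W(df, solve(R)) with R = `wishart_scale`).
#' @param dispersion_prior c(shape, rate) of the inverse-gamma prior on phi.
#' @param variance_model "fitted" (variance tracks the fitted mean
#'   a_i + b_i t, the default), "patient_mean" (tracks the patient's average
#'   observed eGFR), or "fixed" (homoscedastic with known
#'   `fixed_variance`; used by the conjugate-limit oracle).
#' @param fixed_variance residual variance when `variance_model = "fixed"`.
#' @param variance_floor lower clip on the mean entering the variance.
#' @param improved_rule,declining_rule lists `list(slope =, prob =)`:
#'   a patient is improved when the posterior probability that the slope
#'   exceeds `improved_rule$slope` strictly exceeds `improved_rule$prob`
#'   (default P(b > 0) > 0.95), declining when
#'   P(b < declining_rule$slope) > declining_rule$prob (default
#'   P(b < -1) > 0.95), otherwise stable.
#' @param fix_population optional list(m =, Sigma =, phi =) holding the
#'   population parameters fixed (no hyperparameter updates); used for
#'   oracle checks against closed-form posteriors.
#' @param seed integer seed for the chain.
#' @return object of class `slope_model_spec`.
#' @export
slope_model_spec <- function(n_iterations = 5000L, burn_in = 1000L,
                             m0 = c(53, 0), s0 = c(20, 5),
                             wishart_df = 3, wishart_scale = diag(c(100, 10)),
                             dispersion_prior = c(shape = 2, rate = 2),
                             variance_model = c("fitted", "patient_mean", "fixed"),
                             fixed_variance = NULL,
                             variance_floor = 5,
                             improved_rule = list(slope = 0, prob = 0.95),
                             declining_rule = list(slope = -1, prob = 0.95),
                             fix_population = NULL,
                             seed = 1L) {
  variance_model <- match.arg(variance_model)
  if (wishart_df < 2) stopf("'wishart_df' must be >= 2")
  if (any(s0 <= 0) || any(diag(wishart_scale) <= 0) || any(dispersion_prior <= 0))
    stopf("all prior scale parameters must be positive")
  if (variance_model == "fixed" && is.null(fix_population) && is.null(fixed_variance))
    stopf("'fixed_variance' required when variance_model = \"fixed\"")
  structure(list(
    n_iterations = as.integer(n_iterations), burn_in = as.integer(burn_in),
    m0 = m0, s0 = s0, wishart_df = wishart_df, wishart_scale = wishart_scale,
    dispersion_prior = dispersion_prior, variance_model = variance_model,
    fixed_variance = fixed_variance, variance_floor = variance_floor,
    improved_rule = improved_rule, declining_rule = declining_rule,
    fix_population = fix_population, seed = as.integer(seed)
  ), class = "slope_model_spec")
}

# years since each patient's first measurement
prepare_slope_data <- function(points) {
  points$date <- as.Date(points$date)
  points <- points[order(points$patient_id, points$date), , drop = FALSE]
  first <- tapply(as.numeric(points$date), points$patient_id, min)
  points$time <- (as.numeric(points$date) - first[points$patient_id]) / DAYS_PER_YEAR
  points
}

split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  ch <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  mns <- colMeans(ch); vars <- apply(ch, 2L, stats::var)
  W <- mean(vars); B <- n * stats::var(mns)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical Bayesian eGFR slope model
#'
#' Runs a Metropolis-within-Gibbs chain of length `burn_in + n_iterations`
#' and returns per-patient posterior draws of the intercept and slope, the
#' posterior classification probabilities, the improved/stable/declining
#' class per the posterior-probability rule, population-parameter draws,
#' and chain diagnostics (acceptance rates, split-Rhat).
#'
#' @param points data.frame with columns `patient_id`, `egfr` and either
#'   `time` (years since the patient's first measurement) or `date`.
#'   Every patient needs >= 2 measurements at distinct times.
#' @param spec a [slope_model_spec()].
#' @return object of class `slope_fit` with elements `patients`,
#'   `posterior` (patient_id, posterior_mean_slope, posterior_mean_intercept,
#'   p_gt_0, p_lt_neg1, class), `draws_slope` / `draws_intercept`
#'   (n_iterations x n matrices), `population` (posterior means of m, Sigma,
#'   phi and their draws), and `diagnostics`.
#' @export
fit_slope_model <- function(points, spec = slope_model_spec()) {
  if (!all(c("patient_id", "egfr") %in% names(points)))
    stopf("'points' needs patient_id and egfr columns")
  if (!"time" %in% names(points)) points <- prepare_slope_data(points)
  if (any(!is.finite(points$egfr)))
    stopf("non-finite eGFR values for patient(s): %s",
          paste(unique(points$patient_id[!is.finite(points$egfr)]), collapse = ", "))
  ids <- unique(points$patient_id)
  n <- length(ids)
  pid <- match(points$patient_id, ids)
  t_ <- points$time
  y <- points$egfr
  nt_distinct <- tapply(t_, pid, function(z) length(unique(z)))
  bad <- which(nt_distinct < 2L)
  if (length(bad))
    stopf("patient(s) without >= 2 distinct measurement times: %s",
          paste(ids[bad], collapse = ", "))

  set.seed(spec$seed)
  n_obs <- length(y)
  cnt <- as.numeric(tabulate(pid, n))
  ybar <- as.numeric(rowsum(y, pid) / cnt)
  floor_ <- spec$variance_floor

  # OLS initialisation per patient
  tbar <- as.numeric(rowsum(t_, pid) / cnt)
  sxx <- as.numeric(rowsum((t_ - tbar[pid])^2, pid))
  sxy <- as.numeric(rowsum((t_ - tbar[pid]) * (y - ybar[pid]), pid))
  b_ols <- sxy / sxx
  a_ols <- ybar - b_ols * tbar
  theta <- cbind(a_ols, b_ols)

  fixed <- spec$fix_population
  if (!is.null(fixed)) {
    m_cur <- fixed$m
    Sigma_cur <- fixed$Sigma
    phi_cur <- if (spec$variance_model == "fixed")
      (fixed$phi %||% spec$fixed_variance) else fixed$phi
  } else {
    m_cur <- colMeans(theta)
    Sigma_cur <- if (n > 1L) stats::cov(theta) + diag(c(1, 0.1)) else diag(c(25, 4))
    phi_cur <- if (spec$variance_model == "fixed") spec$fixed_variance else 0.5
  }
  update_pop <- is.null(fixed)
  update_phi <- update_pop && spec$variance_model != "fixed"

  weights_of <- function(theta) {
    switch(spec$variance_model,
           fitted = pmax(theta[pid, 1L] + theta[pid, 2L] * t_, floor_),
           patient_mean = pmax(ybar[pid], floor_),
           fixed = rep(1, n_obs))
  }
  # per-patient pieces of the log-likelihood given variance weights w:
  # ll_i = -0.5 * (cnt_i log(2 pi phi) + sum log w + sum r^2/w / phi)
  ll_pieces <- function(theta) {
    w <- weights_of(theta)
    r <- y - (theta[pid, 1L] + theta[pid, 2L] * t_)
    list(logw = as.numeric(rowsum(log(w), pid)),
         r2w = as.numeric(rowsum(r * r / w, pid)))
  }
  ll_patient <- function(pieces, phi) {
    -0.5 * (cnt * log(2 * pi * phi) + pieces$logw + pieces$r2w / phi)
  }
  lprior_theta <- function(theta, m, Sig_inv, logdet) {
    d <- cbind(theta[, 1L] - m[1L], theta[, 2L] - m[2L])
    q <- d[, 1L]^2 * Sig_inv[1L, 1L] + 2 * d[, 1L] * d[, 2L] * Sig_inv[1L, 2L] +
      d[, 2L]^2 * Sig_inv[2L, 2L]
    -0.5 * (q + logdet) - log(2 * pi)
  }

  Sig_inv <- solve(Sigma_cur)
  logdet <- determinant(Sigma_cur, logarithm = TRUE)$modulus[1L]
  pieces <- ll_pieces(theta)
  ll_cur <- ll_patient(pieces, phi_cur)
  lp_cur <- lprior_theta(theta, m_cur, Sig_inv, logdet)

  n_keep <- spec$n_iterations
  n_total <- n_keep + spec$burn_in
  log_scale <- rep(log(0.8), n)
  acc_batch <- numeric(n); batch_len <- 50L
  phi_log_scale <- log(0.2); phi_acc <- 0
  acc_total <- numeric(n); phi_acc_total <- 0

  draws_a <- matrix(NA_real_, n_keep, n)
  draws_b <- matrix(NA_real_, n_keep, n)
  pop_draws <- matrix(NA_real_, n_keep, 6L,
                      dimnames = list(NULL, c("m_intercept", "m_slope",
                                              "sigma_aa", "sigma_bb", "sigma_ab", "phi")))
  R_inv <- solve(spec$wishart_scale)
  S0_inv <- diag(1 / spec$s0^2)
  S0_inv_m0 <- S0_inv %*% spec$m0

  for (it in seq_len(n_total)) {
    # --- per-patient (a_i, b_i): vectorized random-walk Metropolis
    sc <- exp(log_scale)
    prop <- theta + cbind(sc * stats::rnorm(n), 0.35 * sc * stats::rnorm(n))
    pieces_p <- ll_pieces(prop)
    ll_prop <- ll_patient(pieces_p, phi_cur)
    lp_prop <- lprior_theta(prop, m_cur, Sig_inv, logdet)
    acc <- log(stats::runif(n)) < (ll_prop + lp_prop - ll_cur - lp_cur)
    if (any(acc)) {
      theta[acc, ] <- prop[acc, , drop = FALSE]
      ll_cur[acc] <- ll_prop[acc]; lp_cur[acc] <- lp_prop[acc]
      pieces$logw[acc] <- pieces_p$logw[acc]; pieces$r2w[acc] <- pieces_p$r2w[acc]
    }
    acc_batch <- acc_batch + acc
    if (it > spec$burn_in) acc_total <- acc_total + acc

    # --- population mean m (conjugate) and Sigma^-1 (Wishart conjugate)
    if (update_pop) {
      sum_theta <- colSums(theta)
      prec <- S0_inv + n * Sig_inv
      V <- solve(prec)
      mu_post <- V %*% (S0_inv_m0 + Sig_inv %*% sum_theta)
      m_cur <- as.numeric(mu_post + t(chol(V)) %*% stats::rnorm(2L))
      d <- sweep(theta, 2L, m_cur)
      S <- crossprod(d)
      prec_draw <- stats::rWishart(1L, spec$wishart_df + n, solve(R_inv + S))[, , 1L]
      Sigma_cur <- solve(prec_draw)
      Sig_inv <- prec_draw
      logdet <- determinant(Sigma_cur, logarithm = TRUE)$modulus[1L]
      lp_cur <- lprior_theta(theta, m_cur, Sig_inv, logdet)
    }

    # --- dispersion phi: Metropolis on log scale (cheap via cached sums)
    if (update_phi) {
      # walk on log(phi), clamped to keep the dispersion finite and positive
      # even in the degenerate noise-free limit
      phi_prop <- exp(min(max(log(phi_cur) + exp(phi_log_scale) * stats::rnorm(1L),
                              -25), 25))
      llsum <- function(phi) -0.5 * (n_obs * log(2 * pi * phi) + sum(pieces$logw) +
                                       sum(pieces$r2w) / phi)
      lpost <- function(phi) llsum(phi) -
        (spec$dispersion_prior[[1L]] + 1) * log(phi) - spec$dispersion_prior[[2L]] / phi +
        log(phi)  # Jacobian of the log transform
      if (log(stats::runif(1L)) < lpost(phi_prop) - lpost(phi_cur)) {
        phi_cur <- phi_prop
        ll_cur <- ll_patient(pieces, phi_cur)
        phi_acc <- phi_acc + 1
        if (it > spec$burn_in) phi_acc_total <- phi_acc_total + 1
      }
    }

    # --- proposal-scale adaptation, frozen after burn-in
    if (it <= spec$burn_in && it %% batch_len == 0L) {
      log_scale <- log_scale + 0.6 * (acc_batch / batch_len - 0.3)
      acc_batch <- numeric(n)
      if (update_phi) {
        phi_log_scale <- phi_log_scale + 0.6 * (phi_acc / batch_len - 0.35)
        phi_acc <- 0
      }
    }

    if (it > spec$burn_in) {
      k <- it - spec$burn_in
      draws_a[k, ] <- theta[, 1L]
      draws_b[k, ] <- theta[, 2L]
      pop_draws[k, ] <- c(m_cur, Sigma_cur[1L, 1L], Sigma_cur[2L, 2L],
                          Sigma_cur[1L, 2L], phi_cur)
    }
  }

  p_gt <- colMeans(draws_b > spec$improved_rule$slope)
  p_lt <- colMeans(draws_b < spec$declining_rule$slope)
  cls <- classify_slope(p_gt, p_lt, spec)
  posterior <- data.frame(
    patient_id = ids,
    posterior_mean_slope = colMeans(draws_b),
    posterior_mean_intercept = colMeans(draws_a),
    p_gt_0 = p_gt, p_lt_neg1 = p_lt,
    class = cls, stringsAsFactors = FALSE
  )
  rhat <- apply(pop_draws, 2L, split_rhat)
  structure(list(
    patients = ids, posterior = posterior,
    draws_slope = draws_b, draws_intercept = draws_a,
    population = list(
      m = colMeans(pop_draws[, 1:2, drop = FALSE]),
      Sigma = matrix(c(mean(pop_draws[, "sigma_aa"]), mean(pop_draws[, "sigma_ab"]),
                       mean(pop_draws[, "sigma_ab"]), mean(pop_draws[, "sigma_bb"])), 2L),
      phi = mean(pop_draws[, "phi"]),
      draws = pop_draws),
    diagnostics = list(
      acceptance_theta = acc_total / n_keep,
      acceptance_phi = if (update_phi) phi_acc_total / n_keep else NA_real_,
      split_rhat = rhat),
    spec = spec
  ), class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> %d patients, %d kept draws\n",
              length(x$patients), nrow(x$draws_slope)))
  print(table(x$posterior$class))
  invisible(x)
}

#' Classify eGFR slopes from posterior probabilities
#'
#' Improved iff the posterior probability of a positive slope strictly
#' exceeds 0.95; declining iff the posterior probability of a slope below
#' -1 ml/min/1.73m^2/yr strictly exceeds 0.95; stable otherwise. The two
#' events are mutually exclusive at these thresholds (their posterior
#' masses cannot both exceed 0.95); a violation is an internal error.
#'
#' @param p_gt_0 posterior probability the slope exceeds the improvement
#'   threshold (vector), or a `slope_fit` (then `p_lt_neg1` is ignored).
#' @param p_lt_neg1 posterior probability the slope is below the decline
#'   threshold.
#' @param spec a [slope_model_spec()] carrying the thresholds.
#' @return character vector in {improved, stable, declining}.
#' @export
classify_slope <- function(p_gt_0, p_lt_neg1 = NULL, spec = slope_model_spec()) {
  if (inherits(p_gt_0, "slope_fit")) {
    fit <- p_gt_0
    return(classify_slope(fit$posterior$p_gt_0, fit$posterior$p_lt_neg1, fit$spec))
  }
  if (length(p_gt_0) == 0L) stopf("empty posterior probability vector")
  imp <- p_gt_0 > spec$improved_rule$prob
  dec <- p_lt_neg1 > spec$declining_rule$prob
  if (any(imp & dec))
    stopf("internal error: a patient satisfies both classification rules")
  ifelse(imp, "improved", ifelse(dec, "declining", "stable"))
}

#' Per-patient ordinary least-squares eGFR slope
#'
#' The OLS comparator: unshrunken per-patient regression of eGFR on time.
#' Against the Bayesian model it demonstrates the overestimation of the
#' positive-slope fraction that the hierarchical model corrects.
#'
#' @inheritParams fit_slope_model
#' @return data.frame with `patient_id`, `ols_slope`, `ols_intercept`.
#' @export
ols_slope <- function(points) {
  if (!"time" %in% names(points)) points <- prepare_slope_data(points)
  ids <- unique(points$patient_id)
  pid <- match(points$patient_id, ids)
  n <- length(ids)
  cnt <- tabulate(pid, n)
  tbar <- as.numeric(rowsum(points$time, pid) / cnt)
  ybar <- as.numeric(rowsum(points$egfr, pid) / cnt)
  sxx <- as.numeric(rowsum((points$time - tbar[pid])^2, pid))
  if (any(sxx == 0))
    stopf("singular design (single distinct time) for patient(s): %s",
          paste(ids[sxx == 0], collapse = ", "))
  sxy <- as.numeric(rowsum((points$time - tbar[pid]) * (points$egfr - ybar[pid]), pid))
  b <- sxy / sxx
  data.frame(patient_id = ids, ols_slope = b, ols_intercept = ybar - b * tbar,
             stringsAsFactors = FALSE)
}
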