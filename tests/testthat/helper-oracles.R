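# Independent oracles and small simulation helpers shared across tests.

# Reference CKD-EPI 2009 implementation, coded independently of the package
# (explicit branches, log-scale arithmetic).
ref_ckd_epi <- function(scr, age, female, black) {
  n <- length(scr)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- if (female[i]) 0.7 else 0.9
    a <- if (female[i]) -0.329 else -0.411
    ratio <- scr[i] / k
    lg <- log(141) + age[i] * log(0.993) +
      (if (ratio < 1) a * log(ratio) else -1.209 * log(ratio))
    if (female[i]) lg <- lg + log(1.018)
    if (black[i]) lg <- lg + log(1.159)
    out[i] <- exp(lg)
  }
  out
}

# Closed-form normal posterior for (a, b) in the homoscedastic known-variance
# linear model with a fixed bivariate-normal prior.
closed_form_posterior <- function(t, y, m, Sigma, sigma2) {
  X <- cbind(1, t)
  V <- solve(solve(Sigma) + crossprod(X) / sigma2)
  mu <- V %*% (solve(Sigma, m) + crossprod(X, y) / sigma2)
  list(mean = as.numeric(mu), cov = V)
}

# Breslow partial log-likelihood and score, written from the definition.
cox_partial_loglik <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Cohort of patients with fixed latent slopes by class, visit times uniform
# over the pre-entry span, heteroscedastic noise var = phi * max(mu, 5).
make_class_cohort <- function(n, slopes = c(improved = 3, stable = 0, declining = -3),
                              mix = c(improved = 0.25, stable = 0.5, declining = 0.25),
                              visits = 8, phi = 0.3, span = 5, seed = 1) {
  set.seed(seed)
  cls <- sample(names(slopes), n, replace = TRUE, prob = mix[names(slopes)])
  a <- rnorm(n, 53, 4)
  rows <- lapply(seq_len(n), function(i) {
    t <- sort(c(0, runif(visits - 1, 0, span)))
    mu <- pmax(a[i] + slopes[cls[i]] * t, 5)
    y <- pmax(mu + rnorm(visits, 0, sqrt(phi * pmax(mu, 5))), 1)
    data.frame(patient_id = sprintf("P%04d", i), time = t, egfr = y,
               stringsAsFactors = FALSE)
  })
  list(points = do.call(rbind, rows),
       truth = data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                          class = cls, stringsAsFactors = FALSE))
}

# three well-separated planted trajectory groups used in recovery tests
planted_groups <- function() {
  data.frame(prob = c(0.30, 0.45, 0.25),
             intercept = c(85, 65, 50),
             slope = c(0.5, -1.5, -4))
}

hand_cox_data <- function() {
  # six subjects, one binary covariate, no ties
  data.frame(patient_id = sprintf("S%d", 1:6),
             followup_time = c(1.1, 2.3, 3.2, 4.8, 5.5, 6.9),
             death_flag = c(1L, 1L, 0L, 1L, 1L, 0L),
             x = c(1, 0, 1, 1, 0, 0))
}


# score (derivative in a single coefficient) of the Breslow partial
# log-likelihood; its root is the maximum-partial-likelihood estimate
cox_partial_score <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    w <- exp(beta * x[risk])
    s <- s + x[i] - sum(x[risk] * w) / sum(w)
  }
  s
}
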