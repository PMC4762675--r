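# Pattern-mixture group-based trajectory model (latent class growth) for
# annual-average eGFR after cohort entry.
#
# Observed-data likelihood: patient i with annual means y_it belongs to a
# latent group k with probability pi_k; within group k,
#   y_it ~ Normal(sum_j beta_kj t^j + gamma * x_it + delta * d_i, sigma^2)
# where x_it is the number of eGFR measurements in year t (measurement
# frequency covariate) and d_i indicates an eGFR measurement in the year of
# death (the pattern-mixture indicator carrying the informative part of the
# missingness). Fit by EM: posterior memberships by Bayes rule across each
# patient's full year-series (E), weighted least squares for beta, gamma,
# delta plus closed-form pi and sigma^2 (M). Multiple restarts guard
# against local optima; groups are canonically ordered by intercept
# (descending).

#' Specification of the latent trajectory model
#'
#' @param k_range candidate numbers of groups (default 1:9).
#' @param polynomial_order per-group polynomial order in years since entry
#'   (default 2).
#' @param include_measurement_count_covariate include the shared coefficient
#'   on the number of measurements per year (default TRUE).
#' @param include_death_year_indicator include the pattern-mixture
#'   death-year-measurement indicator (default TRUE).
#' @param delta_per_group group-specific pattern-mixture coefficients
#'   instead of a single shared delta (default FALSE).
#' @param max_em_iterations,loglik_tolerance EM stopping rule: stop when the
#'   log-likelihood gain falls below `loglik_tolerance * (1 + |loglik|)`.
#' @param n_restarts random restarts per fit (default 10).
#' @param appa_threshold adequacy threshold on the average posterior
#'   probability of assignment (default 0.70).
#' @param seed integer seed controlling restarts.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(k_range = 1:9, polynomial_order = 2L,
                            include_measurement_count_covariate = TRUE,
                            include_death_year_indicator = TRUE,
                            delta_per_group = FALSE,
                            max_em_iterations = 500L, loglik_tolerance = 1e-6,
                            n_restarts = 10L, appa_threshold = 0.70,
                            seed = 1L) {
  if (any(k_range < 1L)) stopf("'k_range' must be positive")
  if (loglik_tolerance <= 0) stopf("'loglik_tolerance' must be positive")
  structure(list(
    k_range = sort(unique(as.integer(k_range))),
    polynomial_order = as.integer(polynomial_order),
    include_x = isTRUE(include_measurement_count_covariate),
    include_d = isTRUE(include_death_year_indicator),
    delta_per_group = isTRUE(delta_per_group),
    max_em_iterations = as.integer(max_em_iterations),
    loglik_tolerance = loglik_tolerance,
    n_restarts = as.integer(n_restarts),
    appa_threshold = appa_threshold,
    seed = as.integer(seed)
  ), class = "trajectory_spec")
}

# canonical internal data layout, ordered by patient then year so results
# are invariant to input row order
traj_data <- function(annual, d, spec) {
  annual <- annual[order(annual$patient_id, annual$year_index), , drop = FALSE]
  ids <- sort(unique(annual$patient_id))
  pid <- match(annual$patient_id, ids)
  if (is.data.frame(d)) d <- setNames(d$d, d$patient_id)
  d_i <- if (spec$include_d) {
    v <- as.numeric(d[ids])
    if (anyNA(v)) stopf("death-year indicator missing for some patients")
    v
  } else numeric(length(ids))
  list(ids = ids, pid = pid, t = as.numeric(annual$year_index),
       y = annual$mean_egfr,
       x = if (spec$include_x) as.numeric(annual$n_measurements) else NULL,
       d = d_i, n = length(ids), n_obs = nrow(annual))
}

#' Fit the pattern-mixture trajectory model for a fixed number of groups
#'
#' @param annual data.frame with `patient_id`, `year_index`, `mean_egfr`,
#'   `n_measurements` (see [annualize_egfr()]); every patient needs at
#'   least one row.
#' @param d per-patient death-year-measurement indicator: data.frame
#'   (`patient_id`, `d`) or named 0/1 vector.
#' @param K number of latent groups.
#' @param spec a [trajectory_spec()].
#' @return object of class `trajectory_fit`: `K`, `beta` (K x (order+1)),
#'   `gamma`, `delta` (scalar or K-vector), `pi`, `sigma2`, `loglik`, `bic`,
#'   `appa` (per group), `memberships` (per-patient posterior probability
#'   matrix plus hard assignment), coefficient standard errors, and a
#'   convergence flag.
#' @export
fit_trajectory_model <- function(annual, d, K, spec = trajectory_spec()) {
  dat <- traj_data(annual, d, spec)
  K <- as.integer(K)
  if (K < 1L) stopf("K must be >= 1")
  if (K > dat$n) stopf("K (%d) exceeds number of patients (%d)", K, dat$n)

  order_ <- spec$polynomial_order
  Tm <- outer(dat$t, 0:order_, `^`)                      # n_obs x (order+1)
  n_beta <- K * (order_ + 1L)
  n_extra <- as.integer(!is.null(dat$x)) +
    if (spec$include_d) (if (spec$delta_per_group) K else 1L) else 0L

  # stacked design: K replicated blocks of the observations
  build_design <- function() {
    X <- matrix(0, dat$n_obs * K, n_beta + n_extra)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * dat$n_obs + seq_len(dat$n_obs)
      X[rows, (k - 1L) * (order_ + 1L) + seq_len(order_ + 1L)] <- Tm
      col <- n_beta
      if (!is.null(dat$x)) { col <- col + 1L; X[rows, col] <- dat$x }
      if (spec$include_d) {
        if (spec$delta_per_group) X[rows, col + k] <- dat$d[dat$pid]
        else X[rows, col + 1L] <- dat$d[dat$pid]
      }
    }
    X
  }
  Xs <- build_design()
  Ys <- rep(dat$y, K)
  pid_s <- rep(dat$pid, K)

  mstep <- function(w) {
    W <- as.numeric(w[cbind(pid_s, rep(seq_len(K), each = dat$n_obs))])
    fit <- stats::lm.wfit(Xs, Ys, pmax(W, 1e-12))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    res <- Ys - Xs %*% coefs
    sigma2 <- sum(W * res^2) / sum(W)
    list(coefs = coefs, sigma2 = max(sigma2, 1e-8), pi = pmax(colMeans(w), 1e-8))
  }
  estep <- function(par) {
    mu <- Xs %*% par$coefs
    llo <- matrix(stats::dnorm(Ys, mu, sqrt(par$sigma2), log = TRUE), dat$n_obs, K)
    ll_ik <- rowsum(llo, dat$pid)                        # n x K
    lg <- sweep(ll_ik, 2L, log(par$pi / sum(par$pi)), `+`)
    mx <- apply(lg, 1L, max)
    w <- exp(lg - mx)
    denom <- rowSums(w)
    list(w = w / denom, loglik = sum(mx + log(denom)))
  }

  run_em <- function(w0) {
    w <- w0
    ll_prev <- -Inf
    converged <- FALSE
    for (iter in seq_len(spec$max_em_iterations)) {
      par <- mstep(w)
      es <- estep(par)
      if (es$loglik < ll_prev - 1e-6 * (1 + abs(ll_prev)))
        stopf("internal error: EM log-likelihood decreased (%.6f -> %.6f)",
              ll_prev, es$loglik)
      w <- es$w
      if (es$loglik - ll_prev < spec$loglik_tolerance * (1 + abs(es$loglik))) {
        converged <- TRUE; ll_prev <- es$loglik; break
      }
      ll_prev <- es$loglik
    }
    list(w = w, par = par, loglik = ll_prev, converged = converged, iter = iter)
  }

  # initial memberships: k-means on per-patient (mean, slope) summaries,
  # then random reassignment jitter on later restarts
  cnt <- tabulate(dat$pid, dat$n)
  ybar_i <- as.numeric(rowsum(dat$y, dat$pid)) / cnt
  tbar_i <- as.numeric(rowsum(dat$t, dat$pid)) / cnt
  sxx <- as.numeric(rowsum((dat$t - tbar_i[dat$pid])^2, dat$pid))
  sxy <- as.numeric(rowsum((dat$t - tbar_i[dat$pid]) * (dat$y - ybar_i[dat$pid]), dat$pid))
  slope_i <- ifelse(sxx > 0, sxy / pmax(sxx, 1e-12), 0)
  summ <- scale(cbind(ybar_i, slope_i))
  summ[!is.finite(summ)] <- 0

  best <- NULL
  set.seed(spec$seed + 1000L * K)
  for (r in seq_len(max(1L, spec$n_restarts))) {
    hard <- if (K == 1L) rep(1L, dat$n)
      else if (r == 1L) stats::kmeans(summ, centers = K, nstart = 5L)$cluster
      else sample.int(K, dat$n, replace = TRUE)
    w0 <- matrix(0.1 / K, dat$n, K)
    w0[cbind(seq_len(dat$n), hard)] <- w0[cbind(seq_len(dat$n), hard)] + 0.9
    res <- tryCatch(run_em(w0), error = function(e)
      if (grepl("internal error", conditionMessage(e))) stop(e) else NULL)
    if (!is.null(res) && (is.null(best) || res$loglik > best$loglik)) best <- res
  }
  if (is.null(best)) stopf("all EM restarts failed")
  if (!best$converged)
    warning(sprintf("trajectory EM did not converge in %d iterations (K = %d)",
                    spec$max_em_iterations, K), call. = FALSE)

  # coefficient covariance from the final weighted least squares
  W <- as.numeric(best$w[cbind(pid_s, rep(seq_len(K), each = dat$n_obs))])
  XtWX <- crossprod(Xs * sqrt(pmax(W, 1e-12)))
  cov_coefs <- tryCatch(best$par$sigma2 * solve(XtWX),
                        error = function(e) matrix(NA_real_, ncol(Xs), ncol(Xs)))
  se <- sqrt(pmax(diag(cov_coefs), 0))

  beta <- matrix(best$par$coefs[seq_len(n_beta)], K, order_ + 1L, byrow = TRUE)
  beta_se <- matrix(se[seq_len(n_beta)], K, order_ + 1L, byrow = TRUE)
  col <- n_beta
  gamma <- gamma_se <- NA_real_
  if (!is.null(dat$x)) { col <- col + 1L; gamma <- best$par$coefs[col]; gamma_se <- se[col] }
  delta <- delta_se <- NULL
  if (spec$include_d) {
    idx <- col + seq_len(if (spec$delta_per_group) K else 1L)
    delta <- best$par$coefs[idx]; delta_se <- se[idx]
  }

  # canonical order: intercept descending
  ord <- order(beta[, 1L], decreasing = TRUE)
  beta <- beta[ord, , drop = FALSE]; beta_se <- beta_se[ord, , drop = FALSE]
  pi_ <- best$par$pi[ord] / sum(best$par$pi)
  w <- best$w[, ord, drop = FALSE]
  if (spec$delta_per_group) { delta <- delta[ord]; delta_se <- delta_se[ord] }

  hard <- max.col(w, ties.method = "first")
  appa <- vapply(seq_len(K), function(k) {
    sel <- hard == k
    if (!any(sel)) NA_real_ else mean(w[sel, k])
  }, numeric(1L))

  p <- n_beta + n_extra + (K - 1L) + 1L
  loglik <- best$loglik
  memberships <- data.frame(patient_id = dat$ids, group = hard,
                            max_posterior = w[cbind(seq_len(dat$n), hard)],
                            stringsAsFactors = FALSE)
  memberships <- cbind(memberships, as.data.frame(w) |>
                         stats::setNames(paste0("p_group_", seq_len(K))))
  structure(list(
    K = K, beta = beta, beta_se = beta_se, gamma = gamma, gamma_se = gamma_se,
    delta = delta, delta_se = delta_se, pi = pi_, sigma2 = best$par$sigma2,
    loglik = loglik, bic = -2 * loglik + p * log(dat$n), n_parameters = p,
    appa = appa, memberships = memberships, w = w,
    n_patients = dat$n, n_obs = dat$n_obs,
    converged = best$converged, em_iterations = best$iter,
    annual = annual, d = dat$d, spec = spec
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> K = %d, loglik = %.2f, BIC = %.2f, min APPA = %.3f\n",
              x$K, x$loglik, x$bic, min(x$appa, na.rm = TRUE)))
  invisible(x)
}

#' Select the number of trajectory groups
#'
#' Fits every candidate K in `spec$k_range` and applies the dual rule:
#' K is accepted when its BIC is below the BIC at K-1 (the smallest
#' candidate is accepted on adequacy alone) AND every group's average
#' posterior probability of assignment exceeds the threshold (0.70 by
#' default). The largest accepted K is returned; if none is accepted a
#' one-group fit is returned with a warning flag.
#'
#' @inheritParams fit_trajectory_model
#' @return the selected `trajectory_fit`, with a `selection` element:
#'   data.frame (K, bic, loglik, min_appa, accepted) and `fallback` flag.
#' @export
select_num_groups <- function(annual, d, spec = trajectory_spec()) {
  ks <- spec$k_range
  fits <- lapply(ks, function(k) fit_trajectory_model(annual, d, k, spec))
  bics <- vapply(fits, `[[`, numeric(1L), "bic")
  min_appa <- vapply(fits, function(f) min(f$appa, na.rm = TRUE), numeric(1L))
  accepted <- logical(length(ks))
  for (i in seq_along(ks)) {
    appa_ok <- min_appa[i] > spec$appa_threshold
    bic_ok <- if (i == 1L) TRUE else bics[i] < bics[i - 1L]
    accepted[i] <- appa_ok && bic_ok
  }
  ladder <- data.frame(K = ks, bic = bics,
                       loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
                       min_appa = min_appa, accepted = accepted)
  if (any(accepted)) {
    sel <- fits[[max(which(accepted))]]
    sel$fallback <- FALSE
  } else {
    warning("no candidate K satisfied the selection criteria; returning K = 1",
            call. = FALSE)
    sel <- if (1L %in% ks) fits[[which(ks == 1L)]] else
      fit_trajectory_model(annual, d, 1L, spec)
    sel$fallback <- TRUE
  }
  sel$selection <- ladder
  sel
}

#' Per-group summaries of a fitted trajectory model
#'
#' Returns, per group: the intercept (model-implied eGFR at entry,
#' `beta_k0`), the average annual eGFR change and average annual percent
#' eGFR change (both computed per patient from the first and last observed
#' annual means and averaged over the group's hard-assigned members), group
#' size and share.
#'
#' @param fit a `trajectory_fit`.
#' @return data.frame with one row per group.
#' @export
summarize_groups <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  annual <- fit$annual[order(fit$annual$patient_id, fit$annual$year_index), ]
  ids <- fit$memberships$patient_id
  pid <- match(annual$patient_id, ids)
  # per-patient first/last annual means
  chg <- pct <- rep(NA_real_, length(ids))
  sp <- split(seq_len(nrow(annual)), pid)
  for (i in seq_along(sp)) {
    rows <- sp[[i]]
    if (length(rows) < 2L) next
    first <- rows[1L]; last <- rows[length(rows)]
    dt <- annual$year_index[last] - annual$year_index[first]
    if (dt <= 0) next
    d_egfr <- (annual$mean_egfr[last] - annual$mean_egfr[first]) / dt
    chg[as.integer(names(sp)[i])] <- d_egfr
    pct[as.integer(names(sp)[i])] <- 100 * d_egfr / annual$mean_egfr[first]
  }
  grp <- fit$memberships$group
  out <- data.frame(
    group = seq_len(fit$K),
    intercept = fit$beta[, 1L],
    annual_change = vapply(seq_len(fit$K), function(k)
      mean(chg[grp == k], na.rm = TRUE), numeric(1L)),
    annual_pct_change = vapply(seq_len(fit$K), function(k)
      mean(pct[grp == k], na.rm = TRUE), numeric(1L)),
    size = as.integer(table(factor(grp, levels = seq_len(fit$K)))),
    stringsAsFactors = FALSE
  )
  if (any(out$size == 0L))
    warning("empty trajectory group(s) in summary", call. = FALSE)
  out$share <- out$size / sum(out$size)
  out
}
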