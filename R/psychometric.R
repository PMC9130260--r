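# Psychometric fitting: cumulative-Gaussian hit-rate functions with lapse,
# MAP estimation, d-prime transform and detection threshold at d' = 1.

#' Summarise a session's Warn/Safe performance
#'
#' Tallies, per tested depth, the number of Warn trials and hits, plus the
#' session's Safe-trial count, false alarms, and false-alarm rate.
#'
#' @param trials A classified trial tibble (single session or several; depths
#'   pooled across sessions if more than one).
#' @return A list of class `session_summary` with `by_depth` (tibble:
#'   `depth_db`, `n`, `hits`, `hit_rate`), `n_safe`, `n_fa`, `fa_rate`.
#' @export
summarize_session <- function(trials) {
  trials <- validate_trials(trials)
  warn <- trials[trials$trial_type == "warn", ]
  safe <- trials[trials$trial_type == "safe", ]
  by_depth <- warn |>
    group_by(depth_db = .data$depth_db) |>
    summarise(n = dplyr::n(), hits = sum(.data$outcome == "hit"),
              .groups = "drop") |>
    mutate(hit_rate = .data$hits / .data$n) |>
    arrange(.data$depth_db)
  n_safe <- nrow(safe)
  n_fa <- sum(safe$outcome == "false_alarm")
  structure(list(by_depth = by_depth, n_safe = n_safe, n_fa = n_fa,
                 fa_rate = if (n_safe > 0) n_fa / n_safe else 0),
            class = "session_summary")
}

# Psychometric curve: p(x) = gamma + (1 - gamma - lambda) * Phi((x - m)/sigma)
psy_curve <- function(x, m, sigma, lambda, gamma) {
  gamma + (1 - gamma - lambda) * pnorm((x - m) / sigma)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-a-posteriori fit of the hit rate versus AM depth,
#' p(x) = gamma + (1 - gamma - lambda) * Phi((x - m) / sigma), with the guess
#' rate gamma pinned to the measured session false-alarm rate (Go/Nogo lower
#' asymptote), the lapse lambda free under a Beta prior concentrated below
#' 0.05, and weakly informative priors on the midpoint m and spread sigma
#' spanning the tested depth range. The fit is deterministic given the data
#' (multi-start box-constrained quasi-Newton optimisation).
#'
#' A fit is flagged non-converged when the optimiser fails, when a parameter
#' lands on its box boundary, or when the fitted curve does not beat a flat
#' (depth-independent) model — e.g. for hit rates that decrease with depth.
#'
#' @param x A trial tibble or a [summarize_session()] result.
#' @param clip Rate clipping used downstream for the d' transform.
#' @return An object of class `psychometric_fit` with elements
#'   `threshold_param_db` (m), `width_db` (sigma), `lapse`, `guess`,
#'   `fa_rate`, `threshold_db` (depth at d' = 1, NA when unattained),
#'   `attained`, `converged`, `objective` (negative log posterior), `data`.
#' @export
fit_psychometric <- function(x, clip = c(0.05, 0.95)) {
  summ <- if (inherits(x, "session_summary")) x else summarize_session(x)
  bd <- summ$by_depth
  if (nrow(bd) < 3) {
    abort("psychometric fitting needs >= 3 distinct depths with warn trials.")
  }
  gamma <- summ$fa_rate
  rng <- range(bd$depth_db)
  span <- max(diff(rng), 3)
  m_prior_mean <- mean(rng)
  m_prior_sd <- span
  logsig_prior_mean <- log(span / 4)
  logsig_prior_sd <- 1
  # lambda ~ Beta(1, 24): mean 0.04, most mass below 0.05
  neg_log_post <- function(par) {
    m <- par[1]; sigma <- exp(par[2]); lambda <- par[3]
    p <- psy_curve(bd$depth_db, m, sigma, lambda, gamma)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    ll <- sum(bd$hits * log(p) + (bd$n - bd$hits) * log1p(-p))
    lp <- dnorm(m, m_prior_mean, m_prior_sd, log = TRUE) +
      dnorm(par[2], logsig_prior_mean, logsig_prior_sd, log = TRUE) +
      stats::dbeta(lambda, 1, 24, log = TRUE)
    -(ll + lp)
  }
  lower <- c(rng[1] - 1.5 * span, log(0.05), 0)
  upper <- c(rng[2] + 1.5 * span, log(3 * span), 0.2)
  starts <- expand.grid(m = unique(c(bd$depth_db, mean(rng))),
                        logsig = log(c(span / 8, span / 4, span / 2)))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(c(starts$m[i], starts$logsig[i], 0.02), neg_log_post,
            method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    return(new_psychometric_fit(NA, NA, NA, gamma, summ, NA, FALSE, FALSE,
                                NA, clip))
  }
  best <- fits[[which.min(vapply(fits, function(f) f$value, double(1)))]]
  par <- best$par
  m <- par[1]; sigma <- exp(par[2]); lambda <- par[3]
  # boundary check on m and sigma only: lambda = 0 is the prior's mode and a
  # perfectly healthy estimate, not a failure
  at_bound <- any(abs(par[1:2] - lower[1:2]) < 1e-6) ||
    any(abs(par[1:2] - upper[1:2]) < 1e-6)
  # flat-model comparison (pure likelihoods): reject fits no better than a
  # depth-independent hit rate
  p_flat <- sum(bd$hits) / sum(bd$n)
  p_flat <- min(max(p_flat, 1e-9), 1 - 1e-9)
  ll_flat <- sum(bd$hits * log(p_flat) + (bd$n - bd$hits) * log1p(-p_flat))
  p_fit <- pmin(pmax(psy_curve(bd$depth_db, m, sigma, lambda, gamma),
                     1e-9), 1 - 1e-9)
  ll_fit <- sum(bd$hits * log(p_fit) + (bd$n - bd$hits) * log1p(-p_fit))
  converged <- best$convergence == 0 && !at_bound && ll_fit >= ll_flat
  thr <- psychometric_threshold_calc(m, sigma, lambda, gamma, clip)
  new_psychometric_fit(m, sigma, lambda, gamma, summ, best$value,
                       converged, converged && thr$attained,
                       if (converged) thr$threshold_db else NA_real_, clip)
}

new_psychometric_fit <- function(m, sigma, lambda, gamma, summ, objective,
                                 converged, attained, threshold_db, clip) {
  structure(list(threshold_param_db = m, width_db = sigma, lapse = lambda,
                 guess = gamma, fa_rate = summ$fa_rate,
                 threshold_db = threshold_db, attained = isTRUE(attained),
                 converged = isTRUE(converged), objective = objective,
                 clip = clip, data = summ),
            class = "psychometric_fit")
}

# Closed-form inversion of the fitted curve at d' = 1 under rate clipping.
psychometric_threshold_calc <- function(m, sigma, lambda, gamma,
                                        clip = c(0.05, 0.95)) {
  z_fa <- qnorm(min(max(gamma, clip[1]), clip[2]))
  max_dprime <- qnorm(clip[2]) - z_fa
  if (max_dprime < 1) return(list(threshold_db = NA_real_, attained = FALSE))
  target_p <- pnorm(1 + z_fa)   # <= clip ceiling by the check above
  q <- (target_p - gamma) / (1 - gamma - lambda)
  # q <= 0: curve sits above the d' = 1 level at every depth, so it never
  # *crosses* the criterion; q >= 1: asymptote below the criterion.
  if (q <= 0 || q >= 1) {
    return(list(threshold_db = NA_real_, attained = FALSE))
  }
  x <- m + sigma * qnorm(q)
  if (x > 0) return(list(threshold_db = NA_real_, attained = FALSE))
  list(threshold_db = x, attained = TRUE)
}

#' Detection threshold of a psychometric fit at d' = 1
#'
#' Transforms the fitted hit-rate curve to d' (with the same rate clipping as
#' [compute_dprime()]) and solves analytically for the depth at which
#' d' = 1. The threshold is flagged unattained when the clipped curve never
#' reaches d' = 1 at any depth <= 0 dB; no extrapolation beyond 0 dB is done.
#'
#' @param fit A `psychometric_fit` object.
#' @return A one-row tibble with `threshold_db` and `attained`.
#' @export
psychometric_threshold <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) {
    return(tibble(threshold_db = NA_real_, attained = FALSE))
  }
  thr <- psychometric_threshold_calc(fit$threshold_param_db, fit$width_db,
                                     fit$lapse, fit$guess, fit$clip)
  tibble(threshold_db = thr$threshold_db, attained = thr$attained)
}

#' Predicted hit rate / d-prime of a psychometric fit
#'
#' @param object A `psychometric_fit`.
#' @param depth_db Depths at which to evaluate.
#' @param type `"prob"` for hit rate, `"dprime"` for the clipped d' transform.
#' @param ... Unused.
#' @export
predict.psychometric_fit <- function(object, depth_db,
                                     type = c("prob", "dprime"), ...) {
  type <- match.arg(type)
  p <- psy_curve(depth_db, object$threshold_param_db, object$width_db,
                 object$lapse, object$guess)
  if (type == "prob") return(p)
  compute_dprime(p, rep(object$guess, length(p)), clip = object$clip)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (cumulative Gaussian, MAP)\n")
  cat(sprintf("  midpoint m: %.2f dB, width sigma: %.2f dB\n",
              x$threshold_param_db, x$width_db))
  cat(sprintf("  lapse: %.3f, guess (= session FA rate): %.3f\n",
              x$lapse, x$guess))
  if (x$attained) {
    cat(sprintf("  threshold at d' = 1: %.2f dB re: 100%%\n", x$threshold_db))
  } else {
    cat("  threshold at d' = 1: unattained\n")
  }
  if (!x$converged) cat("  [fit flagged: not converged]\n")
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble(term = c("threshold_param_db", "width_db", "lapse", "guess"),
         estimate = c(x$threshold_param_db, x$width_db, x$lapse, x$guess))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(threshold_db = x$threshold_db, attained = x$attained,
         converged = x$converged, fa_rate = x$fa_rate,
         objective = x$objective,
         n_warn = sum(x$data$by_depth$n), n_safe = x$data$n_safe)
}
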