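# Per-unit neurometric analysis: firing-rate d-prime by AM depth, logistic
# neurometric fits, AM-responsivity classification, thresholds at d' = 1,
# and phase-locking statistics (vector strength + Rayleigh test).

#' Firing rate over the analysis window
#'
#' Spike count within \[0, window_s) divided by the window duration.
#' Spikes outside the window are excluded with a warning.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param window_s Analysis window (s), > 0 (default 1, the trial duration).
#' @return Rate in spikes/s.
#' @export
firing_rate <- function(spike_times, window_s = 1) {
  check_number(window_s, "window_s", lower = 1e-12)
  inside <- spike_times >= 0 & spike_times < window_s
  if (any(!inside)) {
    warn(sprintf("%d spike(s) outside [0, %g) excluded.",
                 sum(!inside), window_s))
  }
  sum(inside) / window_s
}

#' Per-trial firing rates from a spike table
#'
#' Counts spikes in \[0, window_s) per (unit, trial) and converts to
#' spikes/s. Trials with no spikes are still present with rate 0 when they
#' appear in `trial_table`; otherwise only trials with at least one row in
#' `spikes` are known, so pass the session's trial table when silent trials
#' matter (the simulator's spike tables omit empty trains).
#'
#' @param spikes Spike tibble (`unit_id`, `unit_class`, `trial_id`,
#'   `stimulus`, `spike_time_s`).
#' @param window_s Analysis window (s).
#' @param trial_table Optional tibble of all (trial_id, stimulus) pairs
#'   presented, used to restore zero-spike trials for every unit.
#' @return Tibble: `unit_id`, `unit_class`, `trial_id`, `stimulus`,
#'   `depth_db`, `rate`.
#' @export
unit_firing_rates <- function(spikes, window_s = 1, trial_table = NULL) {
  stopifnot(is.data.frame(spikes))
  check_number(window_s, "window_s", lower = 1e-12)
  inside <- spikes$spike_time_s >= 0 & spikes$spike_time_s < window_s
  counted <- spikes[inside, ] |>
    group_by(.data$unit_id, .data$unit_class, .data$trial_id,
             .data$stimulus) |>
    summarise(n_spikes = dplyr::n(), .groups = "drop")
  units <- distinct(spikes, .data$unit_id, .data$unit_class)
  # A trial table restores zero-spike trials. With a `unit_id` column it
  # scopes trials per unit (needed when units pooled across sessions saw
  # different trials); without one, all units share the same trials.
  if (is.null(trial_table)) {
    trial_table <- distinct(spikes, .data$trial_id, .data$stimulus)
  }
  trial_table <- as_tibble(trial_table)
  if ("unit_id" %in% names(trial_table)) {
    full <- distinct(trial_table, .data$unit_id, .data$trial_id,
                     .data$stimulus) |>
      dplyr::inner_join(units, by = "unit_id")
  } else {
    full <- tidyr::crossing(units,
                            distinct(trial_table, .data$trial_id,
                                     .data$stimulus))
  }
  out <- left_join(full, counted,
                   by = c("unit_id", "unit_class", "trial_id", "stimulus"))
  out$n_spikes[is.na(out$n_spikes)] <- 0L
  out |>
    mutate(depth_db = stimulus_to_depth(.data$stimulus),
           rate = .data$n_spikes / window_s) |>
    select(-"n_spikes") |>
    arrange(.data$unit_id, .data$trial_id)
}

#' Firing-rate d-prime by AM depth for one unit
#'
#' Per-depth neural discriminability computed from firing rates:
#' d'(depth) = (mean rate at depth - mean rate to the unmodulated Safe
#' stimulus) / pooled SD, where the pooled SD is the square root of the
#' degrees-of-freedom-weighted mean of the per-stimulus firing-rate
#' variances over all stimuli (Safe plus every depth).
#'
#' @param rates A per-trial rate tibble for a single unit (columns
#'   `stimulus`, `depth_db`, `rate`), e.g. one unit's rows from
#'   [unit_firing_rates()].
#' @param min_trials Minimum trials per stimulus (stimuli below this are
#'   excluded; variance needs >= 2).
#' @return Tibble: `depth_db`, `n`, `mean_rate`, `dprime`, with attributes
#'   `pooled_sd`, `safe_mean_rate`, `degenerate` (TRUE when pooled SD = 0).
#' @export
neural_dprime_by_depth <- function(rates, min_trials = 2) {
  stopifnot(is.data.frame(rates))
  if ("unit_id" %in% names(rates) &&
      length(unique(rates$unit_id)) > 1) {
    abort("`neural_dprime_by_depth()` expects rates from a single unit.")
  }
  min_trials <- check_count(min_trials, "min_trials", lower = 2)
  by_stim <- rates |>
    group_by(.data$stimulus) |>
    summarise(depth_db = .data$depth_db[1], n = dplyr::n(),
              mean_rate = mean(.data$rate), v = var(.data$rate),
              .groups = "drop") |>
    filter(.data$n >= min_trials)
  if (!"safe" %in% by_stim$stimulus) {
    abort("rates must include the unmodulated \"safe\" stimulus.")
  }
  if (nrow(by_stim) < 2) abort("need safe plus at least one depth.")
  pooled_sd <- sqrt(sum((by_stim$n - 1) * by_stim$v) / sum(by_stim$n - 1))
  safe_mean <- by_stim$mean_rate[by_stim$stimulus == "safe"]
  depths <- by_stim[by_stim$stimulus != "safe", ]
  degenerate <- !is.finite(pooled_sd) || pooled_sd <= 0
  out <- tibble(depth_db = depths$depth_db, n = depths$n,
                mean_rate = depths$mean_rate,
                dprime = if (degenerate) NA_real_
                         else (depths$mean_rate - safe_mean) / pooled_sd) |>
    arrange(.data$depth_db)
  attr(out, "pooled_sd") <- pooled_sd
  attr(out, "safe_mean_rate") <- safe_mean
  attr(out, "degenerate") <- degenerate
  out
}

#' Fit a logistic neurometric function to d-prime vs depth
#'
#' Nonlinear least squares of d'(x) = y0 + a / (1 + exp(-k (x - x0))) with
#' the slope constrained non-negative (d' non-decreasing toward 0 dB) and
#' the range a >= 0, using Levenberg-Marquardt with multiple starts over an
#' x0 grid. Fit quality is the Pearson correlation between fitted and
#' observed d' with its two-tailed p value.
#'
#' @param depth_db Depths (dB re: 100%), >= 4 values.
#' @param dprime Observed neural d' at each depth.
#' @return An object of class `neurometric_logistic`: `y0`, `a`, `k`, `x0`,
#'   `r`, `p`, `valid`, `rss`, and the data.
#' @export
fit_neurometric_logistic <- function(depth_db, dprime) {
  ok <- is.finite(depth_db) & is.finite(dprime)
  x <- depth_db[ok]; y <- dprime[ok]
  if (length(x) < 4) abort("logistic fitting needs >= 4 depths.")
  invalid <- function() {
    structure(list(y0 = NA_real_, a = NA_real_, k = NA_real_, x0 = NA_real_,
                   r = NA_real_, p = NA_real_, valid = FALSE, rss = NA_real_,
                   data = tibble(depth_db = x, dprime = y)),
              class = "neurometric_logistic")
  }
  if (sd(y) == 0) return(invalid())
  span <- max(diff(range(x)), 1)
  starts <- expand.grid(x0 = unique(c(x, mean(range(x)))),
                        k = c(0.3, 1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(y0 = min(y), a = max(max(y) - min(y), 0.1),
               k = starts$k[i], x0 = starts$x0[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + a / (1 + exp(-k * (x - x0))),
        start = st,
        lower = c(y0 = -Inf, a = 0, k = 0, x0 = min(x) - 3 * span),
        upper = c(y0 = Inf, a = Inf, k = 1e3, x0 = max(x) + 3 * span),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(invalid())
  cf <- coef(best$fit)
  yhat <- cf["y0"] + cf["a"] / (1 + exp(-cf["k"] * (x - cf["x0"])))
  if (sd(yhat) < 1e-12) {
    out <- invalid()
    out$y0 <- unname(cf["y0"]); out$a <- unname(cf["a"])
    out$k <- unname(cf["k"]); out$x0 <- unname(cf["x0"])
    out$rss <- best$rss
    return(out)
  }
  ct <- suppressWarnings(cor.test(yhat, y, method = "pearson"))
  structure(list(y0 = unname(cf["y0"]), a = unname(cf["a"]),
                 k = unname(cf["k"]), x0 = unname(cf["x0"]),
                 r = unname(ct$estimate), p = ct$p.value, valid = TRUE,
                 rss = best$rss,
                 data = tibble(depth_db = x, dprime = y, fitted = yhat)),
            class = "neurometric_logistic")
}

#' Evaluate a fitted logistic neurometric function
#'
#' @param object A `neurometric_logistic` fit.
#' @param depth_db Depths at which to evaluate.
#' @param ... Unused.
#' @export
predict.neurometric_logistic <- function(object, depth_db, ...) {
  if (!object$valid) return(rep(NA_real_, length(depth_db)))
  object$y0 + object$a / (1 + exp(-object$k * (depth_db - object$x0)))
}

#' Neural detection threshold at d' = 1
#'
#' Closed-form inversion of the fitted logistic at d' = 1. The threshold is
#' unattained when the fit never crosses 1 on (-Inf, 0\]: flat fit, lower
#' asymptote already above 1, upper asymptote below 1, or a crossing beyond
#' 0 dB.
#'
#' @param fit A `neurometric_logistic` object (or a list with `y0`, `a`,
#'   `k`, `x0`, and optionally `valid`).
#' @param criterion d' criterion (default 1).
#' @return One-row tibble: `threshold_db`, `attained`.
#' @export
neurometric_threshold <- function(fit, criterion = 1) {
  unattained <- tibble(threshold_db = NA_real_, attained = FALSE)
  if (!is.null(fit$valid) && !fit$valid) return(unattained)
  y0 <- fit$y0; a <- fit$a; k <- fit$k; x0 <- fit$x0
  if (!all(is.finite(c(y0, a, k, x0))) || a <= 0 || k <= 0) return(unattained)
  if (y0 >= criterion) return(unattained)          # never crosses from below
  if (y0 + a <= criterion) return(unattained)      # asymptote below criterion
  x <- x0 - log(a / (criterion - y0) - 1) / k
  if (x > 0) return(unattained)
  tibble(threshold_db = x, attained = TRUE)
}

#' AM-responsivity classification
#'
#' A unit is AM responsive iff (1) its neurometric fit is significant
#' (Pearson p < alpha) and (2) its maximum observed neural d' is >= 1.
#'
#' @param fit_p Pearson p value of the neurometric fit (NA = invalid fit).
#' @param max_dprime Maximum observed neural d' across depths.
#' @param alpha Significance level for the fit (default 0.05).
#' @param dprime_min Minimum required maximum d' (default 1).
#' @return Logical.
#' @export
classify_am_responsive <- function(fit_p, max_dprime, alpha = 0.05,
                                   dprime_min = 1) {
  !is.na(fit_p) & fit_p < alpha & !is.na(max_dprime) &
    max_dprime >= dprime_min
}

#' Vector strength of phase locking
#'
#' Projects spike times onto the modulation cycle, theta_j = 2 pi
#' frac(t_j f), and returns the resultant length of the unit phase vectors,
#' VS = |sum exp(i theta_j)| / n. VS = 1 for perfect phase locking, 0 for
#' uniform (or perfectly antiphase) spiking.
#'
#' @param spike_times Spike times (s), pooled across trials; >= 1 spike.
#' @param am_rate_hz Modulation frequency (Hz).
#' @return Vector strength in \[0, 1\].
#' @export
vector_strength <- function(spike_times, am_rate_hz = 5) {
  check_number(am_rate_hz, "am_rate_hz", lower = 1e-12)
  n <- length(spike_times)
  if (n < 1) abort("vector strength is undefined for zero spikes.")
  theta <- 2 * pi * ((spike_times * am_rate_hz) %% 1)
  min(sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n, 1)
}

#' Rayleigh test of circular uniformity
#'
#' Z = n VS^2; the p value uses the standard small-sample correction
#' p = exp(-Z) (1 + (2 Z - Z^2) / (4 n)), clipped to \[0, 1\].
#'
#' @param vs Vector strength.
#' @param n Number of spikes (phases).
#' @param alpha Significance level for the `significant` flag (default
#'   0.001).
#' @return One-row tibble: `statistic` (Z), `p_value`, `significant`.
#' @export
rayleigh_test <- function(vs, n, alpha = 0.001) {
  check_number(vs, "vs", lower = 0, upper = 1)
  n <- check_count(n, "n", lower = 1)
  z <- n * vs^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  p <- min(max(p, 0), 1)
  tibble(statistic = z, p_value = p, significant = p < alpha)
}

#' Full neurometric analysis of one unit
#'
#' Runs the per-unit chain: trial firing rates, per-depth neural d', the
#' logistic neurometric fit, AM-responsivity classification, the neural
#' threshold at d' = 1, and per-depth phase locking (vector strength over
#' spikes pooled across the depth's trials, with the Rayleigh test).
#'
#' @param spikes Spike tibble for one unit.
#' @param window_s Analysis window (s, default 1).
#' @param am_rate_hz Modulation rate (Hz, default 5).
#' @param alpha Fit-significance level (default 0.05).
#' @param vs_alpha Rayleigh significance level (default 0.001).
#' @param trial_table Optional (trial_id, stimulus) table to restore
#'   zero-spike trials.
#' @return Object of class `neurometric_result`: `unit_id`, `unit_class`,
#'   `dprime_by_depth`, `fit` (`neurometric_logistic`), `responsive`,
#'   `threshold_db`, `attained`, `phase_locking` (per-depth VS + Rayleigh),
#'   `degenerate`.
#' @export
neurometric <- function(spikes, window_s = 1, am_rate_hz = 5, alpha = 0.05,
                        vs_alpha = 0.001, trial_table = NULL) {
  stopifnot(is.data.frame(spikes))
  uid <- unique(spikes$unit_id)
  if (length(uid) != 1) abort("`neurometric()` expects a single unit.")
  rates <- unit_firing_rates(spikes, window_s, trial_table = trial_table)
  dpd <- neural_dprime_by_depth(rates)
  degenerate <- isTRUE(attr(dpd, "degenerate"))
  fit <- if (!degenerate && sum(is.finite(dpd$dprime)) >= 4) {
    fit_neurometric_logistic(dpd$depth_db, dpd$dprime)
  } else {
    structure(list(y0 = NA_real_, a = NA_real_, k = NA_real_, x0 = NA_real_,
                   r = NA_real_, p = NA_real_, valid = FALSE, rss = NA_real_,
                   data = tibble(depth_db = dpd$depth_db,
                                 dprime = dpd$dprime)),
              class = "neurometric_logistic")
  }
  max_dp <- if (all(is.na(dpd$dprime))) NA_real_
            else max(dpd$dprime, na.rm = TRUE)
  responsive <- isTRUE(classify_am_responsive(fit$p, max_dp, alpha = alpha))
  thr <- neurometric_threshold(fit)
  pl <- spikes |>
    filter(.data$spike_time_s >= 0, .data$spike_time_s < window_s,
           .data$stimulus != "safe") |>
    group_by(.data$stimulus) |>
    summarise(depth_db = stimulus_to_depth(.data$stimulus[1]),
              n_spikes = dplyr::n(),
              vs = vector_strength(.data$spike_time_s, am_rate_hz),
              .groups = "drop")
  if (nrow(pl)) {
    ray <- purrr::map2(pl$vs, pl$n_spikes,
                       function(v, n) rayleigh_test(v, n, alpha = vs_alpha))
    ray <- list_rbind(ray)
    pl <- dplyr::bind_cols(pl, rename(ray, rayleigh_z = "statistic",
                                      rayleigh_p = "p_value"))
    pl <- arrange(pl, .data$depth_db)
  }
  structure(list(unit_id = uid, unit_class = spikes$unit_class[1],
                 dprime_by_depth = dpd, fit = fit, max_dprime = max_dp,
                 responsive = responsive, threshold_db = thr$threshold_db,
                 attained = thr$attained, phase_locking = pl,
                 degenerate = degenerate,
                 alpha = alpha, vs_alpha = vs_alpha),
            class = "neurometric_result")
}

#' Neurometric summary over all units in a spike table
#'
#' Applies [neurometric()] to each unit; units with fewer than 2 trials for
#' any stimulus contribute NA d' there (the stimulus is excluded) and units
#' whose pooled SD is zero are flagged degenerate.
#'
#' @inheritParams neurometric
#' @param spikes Spike tibble for one or more units.
#' @return Tibble with one row per unit: `unit_id`, `unit_class`,
#'   `max_dprime`, `fit_r`, `fit_p`, `responsive`, `threshold_db`,
#'   `attained`, `degenerate`, `best_vs`, `min_rayleigh_p`, plus a `result`
#'   list-column of `neurometric_result` objects.
#' @export
neurometrics <- function(spikes, window_s = 1, am_rate_hz = 5, alpha = 0.05,
                         vs_alpha = 0.001, trial_table = NULL) {
  stopifnot(is.data.frame(spikes))
  res <- lapply(split(spikes, spikes$unit_id), function(sp) {
    tryCatch(
      neurometric(sp, window_s = window_s, am_rate_hz = am_rate_hz,
                  alpha = alpha, vs_alpha = vs_alpha,
                  trial_table = trial_table),
      error = function(e) NULL)
  })
  keep <- !vapply(res, is.null, logical(1))
  if (any(!keep)) {
    inform(sprintf("%d unit(s) excluded from neurometrics (insufficient trials).",
                   sum(!keep)))
  }
  res <- res[keep]
  rows <- lapply(res, function(r) {
    tibble(unit_id = r$unit_id, unit_class = r$unit_class,
           max_dprime = r$max_dprime, fit_r = r$fit$r, fit_p = r$fit$p,
           responsive = r$responsive, threshold_db = r$threshold_db,
           attained = r$attained, degenerate = r$degenerate,
           best_vs = if (nrow(r$phase_locking)) max(r$phase_locking$vs)
                     else NA_real_,
           min_rayleigh_p = if (nrow(r$phase_locking))
             min(r$phase_locking$rayleigh_p) else NA_real_)
  })
  out <- list_rbind(rows)
  out$result <- unname(res)
  out
}

#' @export
print.neurometric_result <- function(x, ...) {
  cat(sprintf("Neurometric result for unit %s (%s)\n", x$unit_id,
              x$unit_class))
  cat(sprintf("  max neural d': %.2f; fit r = %.3f (p = %.3g)\n",
              x$max_dprime, x$fit$r, x$fit$p))
  cat(sprintf("  AM responsive: %s; threshold: %s\n",
              x$responsive,
              if (x$attained) sprintf("%.2f dB re: 100%%", x$threshold_db)
              else "unattained"))
  invisible(x)
}

#' @export
tidy.neurometric_result <- function(x, ...) {
  dpd <- x$dprime_by_depth
  out <- tibble(depth_db = dpd$depth_db, n = dpd$n,
                mean_rate = dpd$mean_rate, dprime = dpd$dprime)
  if (nrow(x$phase_locking)) {
    out <- left_join(out,
                     select(x$phase_locking, "depth_db", "vs", "rayleigh_p"),
                     by = "depth_db")
  }
  out
}

#' @export
glance.neurometric_result <- function(x, ...) {
  tibble(unit_id = x$unit_id, unit_class = x$unit_class,
         y0 = x$fit$y0, a = x$fit$a, k = x$fit$k, x0 = x$fit$x0,
         fit_r = x$fit$r, fit_p = x$fit$p, max_dprime = x$max_dprime,
         responsive = x$responsive, threshold_db = x$threshold_db,
         attained = x$attained, degenerate = x$degenerate)
}
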