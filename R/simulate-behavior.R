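# Synthetic behavioral observer: Go/Nogo sessions from a cumulative-Gaussian
# psychometric observer with lapse and a session false-alarm rate.

#' Stimulus specification
#'
#' Describes the AM stimulus set: modulation rate, analysis-window duration,
#' the tested depths (dB re: 100%, all <= 0), and the nominal sound level
#' (informational only; average power across depths is treated as already
#' equalized).
#'
#' @param am_rate_hz Modulation frequency in Hz (default 5).
#' @param duration_s Trial / analysis window length in seconds (default 1).
#' @param depths_db Numeric vector of AM depths in dB re: 100%, each <= 0.
#' @param carrier_level_db_spl Nominal sound level in dB SPL (default 45).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(am_rate_hz = 5, duration_s = 1,
                          depths_db = seq(-21, 0, by = 3),
                          carrier_level_db_spl = 45) {
  check_number(am_rate_hz, "am_rate_hz", lower = 1e-9)
  check_number(duration_s, "duration_s", lower = 1e-9)
  if (length(depths_db) < 1) abort("`depths_db` must be non-empty.")
  db_to_linear(depths_db)  # validates <= 0
  structure(list(am_rate_hz = am_rate_hz, duration_s = duration_s,
                 depths_db = sort(depths_db),
                 carrier_level_db_spl = carrier_level_db_spl),
            class = "stimulus_spec")
}

#' Behavioral observer parameters
#'
#' A Bernoulli observer whose Warn-trial hit probability follows a cumulative
#' Gaussian of depth with lapse, riding on a Safe-trial false-alarm rate:
#' p(hit | depth) = fa_rate + (1 - fa_rate - lapse) * Phi((depth - threshold_db) / width_db).
#'
#' @param threshold_db Psychometric midpoint in dB re: 100%.
#' @param width_db Cumulative-Gaussian spread (dB), > 0.
#' @param lapse Upper-asymptote miss probability in \[0, 0.2\].
#' @param fa_rate Safe-trial withdrawal probability in (0, 1).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(threshold_db = -12, width_db = 3,
                            lapse = 0.02, fa_rate = 0.05) {
  check_number(threshold_db, "threshold_db")
  check_number(width_db, "width_db", lower = 1e-9)
  check_number(lapse, "lapse", lower = 0, upper = 0.2)
  check_number(fa_rate, "fa_rate", lower = 1e-12, upper = 1 - 1e-12)
  structure(list(threshold_db = threshold_db, width_db = width_db,
                 lapse = lapse, fa_rate = fa_rate),
            class = "observer_params")
}

#' Warn-trial hit probability of the generative observer
#'
#' @param observer An [observer_params()] object.
#' @param depth_db Depths in dB re: 100%.
#' @return Hit probabilities.
#' @export
observer_hit_prob <- function(observer, depth_db) {
  stopifnot(inherits(observer, "observer_params"))
  observer$fa_rate + (1 - observer$fa_rate - observer$lapse) *
    pnorm((depth_db - observer$threshold_db) / observer$width_db)
}

#' Simulate one Go/Nogo behavioral session
#'
#' Generates `n_warn` Warn trials per tested depth (depth order randomly
#' interleaved), each preceded by 3-5 Safe trials (uniform). Warn responses
#' are Bernoulli draws from the observer's hit probability at that depth;
#' Safe withdrawals are Bernoulli draws at the observer's false-alarm rate.
#'
#' @param observer An [observer_params()] object.
#' @param stim A [stimulus_spec()] object (supplies the tested depths).
#' @param n_warn Warn trials per depth (>= 1).
#' @param seed Integer seed; a fixed seed gives a bit-identical session.
#' @param session_id Session label.
#' @return A trial tibble with columns `session_id`, `trial_index`,
#'   `trial_type`, `depth_db` (NA on safe trials), `response`, `outcome`.
#' @export
simulate_behavior_session <- function(observer, stim, n_warn = 10,
                                      seed = 1, session_id = "s01") {
  stopifnot(inherits(observer, "observer_params"),
            inherits(stim, "stimulus_spec"))
  n_warn <- check_count(n_warn, "n_warn", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  depths <- sample(rep(stim$depths_db, each = n_warn))
  n_w <- length(depths)
  n_safe <- sample(3:5, n_w, replace = TRUE)
  # lay out each warn trial after its 3-5 preceding safe trials
  block <- rep(seq_len(n_w), n_safe + 1L)
  is_warn <- unlist(lapply(n_safe, function(k) c(rep(FALSE, k), TRUE)))
  depth_db <- ifelse(is_warn, depths[block], NA_real_)
  p <- ifelse(is_warn, observer_hit_prob(observer, depths[block]),
              observer$fa_rate)
  response <- ifelse(runif(length(p)) < p, "withdraw", "stay")
  classify_outcomes(tibble(
    session_id = session_id,
    trial_index = seq_along(block),
    trial_type = ifelse(is_warn, "warn", "safe"),
    depth_db = depth_db,
    response = response
  ))
}
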