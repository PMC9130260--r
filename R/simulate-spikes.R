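# Synthetic spike trains: inhomogeneous Poisson processes whose rate follows
# the AM envelope, with depth-dependent gain and tunable phase locking.

#' Single-unit generative parameters
#'
#' Parameters of the inhomogeneous-Poisson unit model. The instantaneous rate
#' on a trial with linear modulation index m is
#' r(t) = R * max(0, 1 + gain * m * (dc_gain + sin(2 pi f t))),
#' where R is the baseline rate scaled by a per-trial lognormal factor with
#' coefficient of variation `rate_noise_cv`. The model expresses the dual
#' rate/temporal code of AM-responsive cortical units: the sinusoidal term
#' locks spikes to the modulation envelope, while `dc_gain` puts a fraction
#' of the depth coupling into a sustained rate increase, so the cycle-averaged
#' rate R * (1 + dc_gain * gain * m) grows smoothly with modulation depth
#' (half-wave rectification at zero adds further rate growth once
#' gain * m > 1). When `kappa` > 0 spike phases are additionally concentrated
#' toward the modulation peak by von-Mises thinning with concentration
#' kappa * m (rate-compensated, so the mean rate is approximately preserved).
#'
#' @param unit_id Unit identifier.
#' @param unit_class `"single"` or `"multi"`.
#' @param baseline_rate_hz Mean rate to unmodulated noise (>= 0).
#' @param gain Dimensionless depth-to-rate coupling (>= 0).
#' @param dc_gain Fraction of the depth coupling expressed as a sustained
#'   (cycle-averaged) rate increase (>= 0).
#' @param kappa Phase concentration of spike phases (von Mises, >= 0).
#' @param rate_noise_cv Trial-to-trial multiplicative rate variability (>= 0).
#' @return An object of class `unit_params`.
#' @export
unit_params <- function(unit_id = "u001", unit_class = c("single", "multi"),
                        baseline_rate_hz = 20, gain = 4, dc_gain = 0.15,
                        kappa = 2, rate_noise_cv = 0.2) {
  unit_class <- match.arg(unit_class)
  check_number(baseline_rate_hz, "baseline_rate_hz", lower = 0)
  check_number(gain, "gain", lower = 0)
  check_number(dc_gain, "dc_gain", lower = 0)
  check_number(kappa, "kappa", lower = 0)
  check_number(rate_noise_cv, "rate_noise_cv", lower = 0)
  structure(list(unit_id = unit_id, unit_class = unit_class,
                 baseline_rate_hz = baseline_rate_hz, gain = gain,
                 dc_gain = dc_gain, kappa = kappa,
                 rate_noise_cv = rate_noise_cv),
            class = "unit_params")
}

#' Population generative parameters
#'
#' Ranges (uniform) from which per-unit parameters are drawn when simulating
#' a recorded population. Units are simulated independently (no shared noise).
#'
#' @param n_units Number of units (>= 1).
#' @param baseline_range,gain_range,kappa_range,cv_range Length-2 numeric
#'   ranges for [unit_params()] fields.
#' @param dc_gain Sustained rate-coupling fraction shared by all units (see
#'   [unit_params()]).
#' @param prop_single Proportion of single (vs multi) units.
#' @return An object of class `population_params`.
#' @export
population_params <- function(n_units = 30,
                              baseline_range = c(10, 40),
                              gain_range = c(1, 6),
                              kappa_range = c(0, 4),
                              cv_range = c(0.05, 0.25),
                              dc_gain = 0.15,
                              prop_single = 0.5) {
  n_units <- check_count(n_units, "n_units", lower = 1)
  check_number(prop_single, "prop_single", lower = 0, upper = 1)
  check_number(dc_gain, "dc_gain", lower = 0)
  for (nm in c("baseline_range", "gain_range", "kappa_range", "cv_range")) {
    r <- get(nm)
    if (length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < 0) {
      abort(sprintf("`%s` must be a non-negative, ordered length-2 range.", nm))
    }
  }
  structure(list(n_units = n_units, baseline_range = baseline_range,
                 gain_range = gain_range, kappa_range = kappa_range,
                 cv_range = cv_range, dc_gain = dc_gain,
                 prop_single = prop_single),
            class = "population_params")
}

#' Draw a population of units
#'
#' @param pop A [population_params()] object.
#' @param seed Optional integer seed (NULL uses the current RNG state).
#' @return A tibble with one row per unit and the [unit_params()] fields.
#' @export
draw_units <- function(pop, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- pop$n_units
  tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    unit_class = ifelse(runif(n) < pop$prop_single, "single", "multi"),
    baseline_rate_hz = runif(n, pop$baseline_range[1], pop$baseline_range[2]),
    gain = runif(n, pop$gain_range[1], pop$gain_range[2]),
    dc_gain = pop$dc_gain,
    kappa = runif(n, pop$kappa_range[1], pop$kappa_range[2]),
    rate_noise_cv = runif(n, pop$cv_range[1], pop$cv_range[2])
  )
}

#' Simulate one spike train
#'
#' Draws spike times on \[0, duration) from the unit model described in
#' [unit_params()], by thinning a homogeneous Poisson process at the rate
#' envelope's maximum. For a Safe trial (`depth_db = NA` or `"safe"`) the
#' rate is constant and spike phases are uniform.
#'
#' @param unit A [unit_params()] object (or a one-row tibble of its fields).
#' @param stim A [stimulus_spec()] object.
#' @param depth_db AM depth in dB re: 100%, or `NA` / `"safe"` for the
#'   unmodulated Safe stimulus.
#' @param seed Optional integer seed (NULL uses the current RNG state, so a
#'   caller can thread one seeded stream through many trials).
#' @return Sorted numeric vector of spike times in seconds. Attribute
#'   `rectified` is TRUE when gain * m exceeded 1 and the rate envelope was
#'   rectified at zero.
#' @export
simulate_spike_train <- function(unit, stim, depth_db = NA, seed = NULL) {
  if (is.data.frame(unit)) unit <- as.list(unit[1, ])
  stopifnot(inherits(stim, "stimulus_spec"))
  if (!is.null(seed)) set.seed(seed)
  safe <- is.na(depth_db[1]) || identical(depth_db[1], "safe")
  m <- if (safe) 0 else db_to_linear(as.numeric(depth_db))
  a <- unit$gain * m
  dur <- stim$duration_s
  f <- stim$am_rate_hz
  cv <- unit$rate_noise_cv
  r0 <- unit$baseline_rate_hz
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    r0 <- r0 * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (r0 <= 0) return(structure(numeric(0), rectified = a > 1))
  c0 <- unit$dc_gain %||% 0
  kap <- unit$kappa * m
  # mean of exp(kappa*(sin(theta) - 1)) over uniform phase
  hbar <- if (kap > 0) besselI(kap, 0, expon.scaled = TRUE) else 1
  rmax <- r0 * (1 + a * (c0 + 1)) / hbar
  n_cand <- rpois(1, rmax * dur)
  rect <- a * (1 - c0) > 1
  if (n_cand == 0) return(structure(numeric(0), rectified = rect))
  t_cand <- runif(n_cand, 0, dur)
  s <- sin(2 * pi * f * t_cand)
  env <- pmax(0, 1 + a * (c0 + s))
  vm <- if (kap > 0) exp(kap * (s - 1)) / hbar else 1
  rate <- r0 * env * vm
  keep <- runif(n_cand) < rate / rmax
  structure(sort(t_cand[keep]), rectified = rect)
}

#' Simulate a paired behavioral + population recording session
#'
#' Generates a behavioral session ([simulate_behavior_session()]) and, for
#' every trial, one spike train per unit over the trial's analysis window,
#' sharing trial labels so behavioral and neural analyses can be linked.
#'
#' @param pop A [population_params()] object, or a pre-drawn unit tibble from
#'   [draw_units()].
#' @param observer An [observer_params()] object.
#' @param stim A [stimulus_spec()] object.
#' @param n_trials_per_stim Warn trials per depth (>= 1; the population
#'   decoder requires >= 8).
#' @param seed Integer master seed; fixed seed gives bit-identical output.
#' @param session_id Session label.
#' @return A list of class `population_session` with elements `trials` (the
#'   behavioral trial tibble), `spikes` (tibble: `unit_id`, `unit_class`,
#'   `trial_id`, `stimulus`, `spike_time_s`), and `units` (unit parameter
#'   tibble, with a `rectified` flag per unit).
#' @export
simulate_population_session <- function(pop, observer, stim,
                                        n_trials_per_stim = 8, seed = 1,
                                        session_id = "s01") {
  n_trials_per_stim <- check_count(n_trials_per_stim, "n_trials_per_stim",
                                   lower = 1)
  units <- if (is.data.frame(pop)) as_tibble(pop)
           else draw_units(pop, seed = derive_seed(seed, 1))
  if (nrow(units) < 1) abort("population must contain at least one unit.")
  trials <- simulate_behavior_session(observer, stim,
                                      n_warn = n_trials_per_stim,
                                      seed = derive_seed(seed, 2),
                                      session_id = session_id)
  stim_label <- ifelse(trials$trial_type == "safe", "safe",
                       format_depth(trials$depth_db))
  spikes <- vector("list", nrow(units))
  rectified <- logical(nrow(units))
  for (u in seq_len(nrow(units))) {
    up <- as.list(units[u, ])
    set.seed(derive_seed(seed, 100L + u))
    per_trial <- lapply(seq_len(nrow(trials)), function(i) {
      simulate_spike_train(up, stim, depth_db = trials$depth_db[i])
    })
    n_per <- lengths(per_trial)
    rectified[u] <- up$gain * (1 - (up$dc_gain %||% 0)) *
      max(db_to_linear(stats::na.omit(unique(trials$depth_db)))) > 1
    spikes[[u]] <- tibble(
      unit_id = up$unit_id, unit_class = up$unit_class,
      trial_id = rep(trials$trial_index, n_per),
      stimulus = rep(stim_label, n_per),
      spike_time_s = round(unlist(per_trial), 6))
  }
  units$rectified <- rectified
  structure(list(trials = trials, spikes = list_rbind(spikes), units = units),
            class = "population_session")
}

# Canonical text label for a depth stimulus (shared by spike tables and the
# decoder); "safe" for the unmodulated stimulus.
format_depth <- function(depth_db) {
  ifelse(is.na(depth_db), "safe", sprintf("%.10g", depth_db))
}

#' Parse spike-table stimulus labels back to depths
#'
#' @param stimulus Character vector of stimulus labels (`"safe"` or a depth
#'   in dB re: 100%).
#' @return Numeric depths (NA for `"safe"`).
#' @export
stimulus_to_depth <- function(stimulus) {
  out <- suppressWarnings(as.numeric(stimulus))
  out[stimulus == "safe"] <- NA_real_
  if (anyNA(out[stimulus != "safe"])) {
    abort("unparseable stimulus label (expected \"safe\" or a depth in dB).")
  }
  out
}

#' Read / write a spike-table CSV
#'
#' Columns: `unit_id`, `unit_class`, `trial_id`, `stimulus` (depth in dB or
#' `"safe"`), `spike_time_s` (seconds from stimulus onset, 6 decimals).
#'
#' @param path File path.
#' @param spikes Spike tibble to write.
#' @export
read_spikes <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          unit_id = readr::col_character(),
                          unit_class = readr::col_character(),
                          trial_id = readr::col_integer(),
                          stimulus = readr::col_character(),
                          spike_time_s = readr::col_double()
                        ))
  if (any(sp$spike_time_s < 0)) abort("spike times must be >= 0.")
  sp
}

#' @rdname read_spikes
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(is.data.frame(spikes))
  out <- spikes[, c("unit_id", "unit_class", "trial_id", "stimulus",
                    "spike_time_s")]
  # fixed 6-decimal seconds on disk; reading the file back is a fixed point
  out$spike_time_s <- sprintf("%.6f", out$spike_time_s)
  readr::write_csv(out, path)
  invisible(spikes)
}
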