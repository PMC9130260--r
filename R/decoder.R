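# Linear population readout: Warn-vs-Safe classification of population spike
# count vectors with per-unit trial subsampling, leave-one-out
# cross-validation over many iterations, and conversion to d-prime.

#' Decoder configuration
#'
#' @param trials_per_unit Trials subsampled per unit and class each
#'   iteration (default 8; 7 train / 1 held-out test per class).
#' @param n_iterations Number of subsampling iterations (default 500).
#' @param min_units Minimum units for a within-session decode (default 10).
#' @param min_trials_per_depth Minimum trials per depth for session
#'   inclusion (default 8).
#' @param cost Regularization constant of the linear maximum-margin
#'   classifier (default 1).
#' @param seed Master seed; per-depth streams are derived from it so
#'   per-depth results are independent of evaluation order.
#' @param pooled_depth_range Depth range (dB) allowed in pooled
#'   pseudo-population mode (default -18 to -6).
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(trials_per_unit = 8, n_iterations = 500,
                           min_units = 10, min_trials_per_depth = 8,
                           cost = 1, seed = 1,
                           pooled_depth_range = c(-18, -6)) {
  trials_per_unit <- check_count(trials_per_unit, "trials_per_unit",
                                 lower = 2)
  n_iterations <- check_count(n_iterations, "n_iterations", lower = 1)
  min_units <- check_count(min_units, "min_units", lower = 1)
  min_trials_per_depth <- check_count(min_trials_per_depth,
                                      "min_trials_per_depth", lower = 2)
  check_number(cost, "cost", lower = 1e-12)
  stopifnot(length(pooled_depth_range) == 2)
  structure(list(trials_per_unit = trials_per_unit,
                 n_iterations = n_iterations, min_units = min_units,
                 min_trials_per_depth = min_trials_per_depth, cost = cost,
                 seed = seed,
                 pooled_depth_range = sort(pooled_depth_range)),
            class = "decoder_config")
}

#' Build population response vectors from a spike table
#'
#' Counts spikes over the analysis window per (unit, stimulus, trial). Units
#' lacking `min_trials` trials for any required stimulus (Safe plus every
#' requested depth) are dropped and reported.
#'
#' @param spikes Spike tibble.
#' @param window_s Count window in seconds (default 1).
#' @param min_trials Minimum trials per (unit, stimulus) (default 8).
#' @param depths Depths to include (default: all depths in the table).
#' @param unit_class Optional filter, e.g. `"single"` for pooled mode.
#' @param trial_table Optional (trial_id, stimulus) table restoring
#'   zero-spike trials (see [unit_firing_rates()]).
#' @return Object of class `population_response`: `units` (tibble),
#'   `depths`, `counts` (per unit, a named list of integer count vectors per
#'   stimulus), `dropped` (tibble of excluded units with reasons).
#' @export
build_response_vectors <- function(spikes, window_s = 1, min_trials = 8,
                                   depths = NULL, unit_class = NULL,
                                   trial_table = NULL) {
  rates <- unit_firing_rates(spikes, window_s, trial_table = trial_table)
  if (!is.null(unit_class)) {
    rates <- rates[rates$unit_class %in% unit_class, ]
  }
  if (nrow(rates) == 0) abort("no spike data after filtering.")
  all_depths <- sort(unique(rates$depth_db[!is.na(rates$depth_db)]))
  if (is.null(depths)) depths <- all_depths
  depths <- sort(depths)
  required <- c("safe", format_depth(depths))
  rates$count <- as.integer(round(rates$rate * window_s))
  units <- distinct(rates, .data$unit_id, .data$unit_class)
  counts <- list()
  dropped <- list()
  for (i in seq_len(nrow(units))) {
    uid <- units$unit_id[i]
    ur <- rates[rates$unit_id == uid, ]
    per_stim <- split(ur$count, ur$stimulus)
    have <- vapply(required, function(s) {
      length(per_stim[[s]] %||% integer(0))
    }, integer(1))
    if (any(have < min_trials)) {
      dropped[[uid]] <- tibble(
        unit_id = uid,
        reason = sprintf("only %d trial(s) for stimulus %s (need %d)",
                         min(have), required[which.min(have)], min_trials))
      next
    }
    counts[[uid]] <- per_stim[required]
  }
  dropped <- if (length(dropped)) list_rbind(dropped)
             else tibble(unit_id = character(), reason = character())
  if (length(counts) == 0) {
    abort(sprintf(
      "no unit has >= %d trials for every required stimulus; %d unit(s) dropped.",
      min_trials, nrow(dropped)))
  }
  if (nrow(dropped)) {
    inform(sprintf("%d unit(s) dropped from the response matrix.",
                   nrow(dropped)))
  }
  structure(list(units = units[units$unit_id %in% names(counts), ],
                 depths = depths, counts = counts, dropped = dropped,
                 window_s = window_s, min_trials = min_trials),
            class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  cat(sprintf("Population response matrix: %d unit(s), %d depth(s) + safe\n",
              length(x$counts), length(x$depths)))
  if (nrow(x$dropped)) cat(sprintf("  (%d unit(s) dropped)\n", nrow(x$dropped)))
  invisible(x)
}

#' Decode one AM depth against Safe
#'
#' Per iteration, and independently for each unit and class, subsamples
#' `trials_per_unit` trials without replacement, holds out one per class
#' (leave-one-out: `trials_per_unit - 1` train / 1 test per class),
#' assembles the N-dimensional train and test response vectors, fits a
#' linear maximum-margin classifier, and classifies the two held-out
#' vectors. The hit rate is the fraction of Warn test vectors classified
#' Warn and the false-alarm rate the fraction of Safe test vectors
#' classified Warn, over completed iterations. Iterations whose train set is
#' degenerate (all vectors identical) are skipped and counted.
#'
#' @param resp A [build_response_vectors()] object.
#' @param depth Depth (dB re: 100%) to decode; must be present in `resp`.
#' @param config A [decoder_config()].
#' @return One-row tibble: `depth_db`, `hit_rate`, `fa_rate`,
#'   `n_completed`, `n_skipped`.
#' @export
decode_depth <- function(resp, depth, config = decoder_config()) {
  stopifnot(inherits(resp, "population_response"),
            inherits(config, "decoder_config"))
  lab <- format_depth(depth)
  if (!depth %in% resp$depths) {
    abort(sprintf("depth %s dB is not in the response matrix.", lab))
  }
  tpu <- config$trials_per_unit
  uids <- names(resp$counts)
  n_units <- length(uids)
  warn_counts <- lapply(resp$counts, function(cc) cc[[lab]])
  safe_counts <- lapply(resp$counts, function(cc) cc[["safe"]])
  if (any(vapply(warn_counts, length, integer(1)) < tpu) ||
      any(vapply(safe_counts, length, integer(1)) < tpu)) {
    abort(sprintf("every unit needs >= %d trials for depth %s and safe.",
                  tpu, lab))
  }
  # per-depth RNG stream derived from the master seed: results do not depend
  # on the order in which depths are decoded
  set.seed(derive_seed(config$seed, 1000L + as.integer(round(abs(depth) * 8))))
  y_train <- factor(rep(c("warn", "safe"), each = tpu - 1),
                    levels = c("safe", "warn"))
  hits <- 0L; fas <- 0L; skipped <- 0L
  for (it in seq_len(config$n_iterations)) {
    train <- matrix(0, nrow = 2 * (tpu - 1), ncol = n_units)
    test <- matrix(0, nrow = 2, ncol = n_units)
    for (u in seq_len(n_units)) {
      iw <- sample.int(length(warn_counts[[u]]), tpu)
      is_ <- sample.int(length(safe_counts[[u]]), tpu)
      w <- warn_counts[[u]][iw]
      s <- safe_counts[[u]][is_]
      train[, u] <- c(w[-1], s[-1])
      test[, u] <- c(w[1], s[1])
    }
    if (all(train == rep(train[1, ], each = nrow(train)))) {
      skipped <- skipped + 1L
      next
    }
    model <- tryCatch(
      e1071::svm(x = train, y = y_train, kernel = "linear",
                 cost = config$cost, scale = FALSE,
                 type = "C-classification"),
      error = function(e) NULL)
    if (is.null(model)) {
      skipped <- skipped + 1L
      next
    }
    pred <- predict(model, test)
    hits <- hits + (pred[1] == "warn")
    fas <- fas + (pred[2] == "warn")
  }
  completed <- config$n_iterations - skipped
  if (skipped > 0.1 * config$n_iterations) {
    warn(sprintf("%d of %d iterations skipped (degenerate train sets) at %s dB.",
                 skipped, config$n_iterations, lab))
  }
  if (completed == 0) {
    abort(sprintf("all iterations degenerate at depth %s dB.", lab))
  }
  tibble(depth_db = depth, hit_rate = hits / completed,
         fa_rate = fas / completed, n_completed = completed,
         n_skipped = skipped)
}

#' Population neurometric function from the decoder
#'
#' Decodes every depth in the response matrix, converts hit/false-alarm
#' rates to d' (0.05/0.95 clipping), fits the logistic neurometric function,
#' and extracts the threshold at d' = 1. With fewer than 4 decodable depths
#' the per-depth results are still returned but the threshold is unattained.
#'
#' @param resp A [build_response_vectors()] object.
#' @param config A [decoder_config()].
#' @param clip Rate clipping for the d' conversion.
#' @return Object of class `decoder_result`: `by_depth` (tibble with rates
#'   and d'), `fit` (`neurometric_logistic` or NULL), `threshold_db`,
#'   `attained`, `n_units`, `config`.
#' @export
decoder_neurometric <- function(resp, config = decoder_config(),
                                clip = c(0.05, 0.95)) {
  by_depth <- list_rbind(lapply(resp$depths, function(d) {
    decode_depth(resp, d, config)
  }))
  by_depth$dprime <- compute_dprime(by_depth$hit_rate, by_depth$fa_rate,
                                    clip = clip)
  fit <- NULL
  thr <- tibble(threshold_db = NA_real_, attained = FALSE)
  if (nrow(by_depth) >= 4 && sd(by_depth$dprime) > 0) {
    fit <- fit_neurometric_logistic(by_depth$depth_db, by_depth$dprime)
    thr <- neurometric_threshold(fit)
  }
  structure(list(by_depth = by_depth, fit = fit,
                 threshold_db = thr$threshold_db, attained = thr$attained,
                 n_units = length(resp$counts), config = config),
            class = "decoder_result")
}

#' Within-session population decode paired with behavior
#'
#' Applies the session inclusion filters (at least `min_units` units each
#' with at least `min_trials_per_depth` trials per depth and safe), runs the
#' population decoder, and pairs its threshold with the session's
#' behavioral threshold for correlation analysis.
#'
#' @param spikes Spike tibble for one session (single and/or multi units).
#' @param behavioral_threshold_db The session's behavioral detection
#'   threshold (dB), e.g. from [psychometric_threshold()].
#' @param config A [decoder_config()].
#' @param window_s Count window (s).
#' @param trial_table Optional (trial_id, stimulus) table.
#' @return A list: `included` (logical), `reason` (when excluded), `result`
#'   (`decoder_result` or NULL), `behavioral_threshold_db`, `n_units`.
#' @export
within_session_decode <- function(spikes, behavioral_threshold_db,
                                  config = decoder_config(), window_s = 1,
                                  trial_table = NULL) {
  resp <- tryCatch(
    build_response_vectors(spikes, window_s = window_s,
                           min_trials = config$min_trials_per_depth,
                           trial_table = trial_table),
    error = function(e) NULL)
  n_units <- if (is.null(resp)) 0L else length(resp$counts)
  if (n_units < config$min_units) {
    return(list(included = FALSE,
                reason = sprintf("%d unit(s) pass the trial filter (need %d)",
                                 n_units, config$min_units),
                result = NULL,
                behavioral_threshold_db = behavioral_threshold_db,
                n_units = n_units))
  }
  res <- decoder_neurometric(resp, config)
  list(included = TRUE, reason = NA_character_, result = res,
       behavioral_threshold_db = behavioral_threshold_db,
       n_units = n_units)
}

#' Pooled pseudo-population decode over sessions
#'
#' Decodes a pseudo-population assembled from units pooled across recording
#' sessions (by default single units only), with trials sampled
#' independently per unit. The depth grid is restricted to the configured
#' pooled range (default -18 to -6 dB re: 100%); requesting a depth outside
#' it is refused.
#'
#' @param spikes Spike tibble pooled across sessions. `unit_id` values must
#'   be unique across sessions.
#' @param config A [decoder_config()].
#' @param depths Depth grid (default: all depths present within the pooled
#'   range).
#' @param unit_class Unit classes to pool (default `"single"`).
#' @param window_s Count window (s).
#' @param trial_table Optional (trial_id, stimulus) table.
#' @return A `decoder_result`.
#' @export
pooled_decode <- function(spikes, config = decoder_config(), depths = NULL,
                          unit_class = "single", window_s = 1,
                          trial_table = NULL) {
  rng <- config$pooled_depth_range
  if (!is.null(depths) && any(depths < rng[1] | depths > rng[2])) {
    abort(sprintf("pooled mode is restricted to depths in [%g, %g] dB re: 100%%.",
                  rng[1], rng[2]))
  }
  resp <- build_response_vectors(spikes, window_s = window_s,
                                 min_trials = config$trials_per_unit,
                                 depths = depths, unit_class = unit_class,
                                 trial_table = trial_table)
  if (is.null(depths)) {
    keep <- resp$depths >= rng[1] & resp$depths <= rng[2]
    if (!any(keep)) abort("no depths inside the pooled depth range.")
    resp$depths <- resp$depths[keep]
  }
  decoder_neurometric(resp, config)
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("Population decoder result (%d units, %d iterations/depth)\n",
              x$n_units, x$config$n_iterations))
  print(as.data.frame(x$by_depth), row.names = FALSE)
  if (x$attained) {
    cat(sprintf("  threshold at d' = 1: %.2f dB re: 100%%\n", x$threshold_db))
  } else {
    cat("  threshold at d' = 1: unattained\n")
  }
  invisible(x)
}

#' @export
tidy.decoder_result <- function(x, ...) {
  x$by_depth
}

#' @export
glance.decoder_result <- function(x, ...) {
  tibble(threshold_db = x$threshold_db, attained = x$attained,
         n_units = x$n_units, n_iterations = x$config$n_iterations,
         max_dprime = max(x$by_depth$dprime),
         fit_r = if (is.null(x$fit)) NA_real_ else x$fit$r,
         fit_p = if (is.null(x$fit)) NA_real_ else x$fit$p)
}
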