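# Signal-detection d-prime with rate clipping, sliding-window training
# performance, and the trials-to-criterion measure.

#' Signal-detection d-prime with rate clipping
#'
#' Computes d' = z(hit rate) - z(false-alarm rate), after constraining both
#' rates to a floor/ceiling (default 0.05/0.95) so that perfect sessions do
#' not yield infinite d'. The same clipping convention is used for
#' behavioral, sliding-window, psychometric-transform, and decoder d' so all
#' stages share the bound |d'| <= 2 * qnorm(0.95) = 3.2897.
#'
#' @param hit_rate,fa_rate Proportions in \[0, 1\] (vectorised).
#' @param clip Length-2 numeric, the rate floor and ceiling.
#' @return Numeric vector of d' values in z-units.
#' @examples
#' compute_dprime(0.9, 0.1)
#' compute_dprime(1, 0)   # clipped: 2 * qnorm(0.95)
#' @export
compute_dprime <- function(hit_rate, fa_rate, clip = c(0.05, 0.95)) {
  if (anyNA(hit_rate) || anyNA(fa_rate)) {
    abort("`hit_rate` and `fa_rate` must not contain NA.")
  }
  if (any(hit_rate < 0 | hit_rate > 1) || any(fa_rate < 0 | fa_rate > 1)) {
    abort("rates must be proportions in [0, 1].")
  }
  stopifnot(length(clip) == 2, clip[1] < clip[2])
  h <- pmin(pmax(hit_rate, clip[1]), clip[2])
  f <- pmin(pmax(fa_rate, clip[1]), clip[2])
  qnorm(h) - qnorm(f)
}

#' Sliding-window d-prime over Warn trials
#'
#' Scores procedural training performance as a function of Warn-trial number:
#' for each window of `window` consecutive Warn trials the hit rate is the
#' proportion of hits in the window and the false-alarm rate is taken from
#' Safe trials whose trial index falls between the first and last Warn trial
#' of the window (falling back to the whole-session false-alarm rate when no
#' Safe trial is enclosed). Windows never cross session boundaries.
#'
#' @param trials A trial tibble as returned by [classify_outcomes()] /
#'   [simulate_behavior_session()], with columns `session_id`, `trial_index`,
#'   `trial_type`, `outcome`.
#' @param window Number of Warn trials per window (default 5).
#' @param clip Rate clipping bounds passed to [compute_dprime()].
#' @return A tibble with one row per window: `session_id`, `warn_index`
#'   (index, in Warn trials, of the last trial of the window), `hit_rate`,
#'   `fa_rate`, `dprime`. Zero rows (with a warning) if no session has
#'   `window` Warn trials.
#' @export
sliding_window_dprime <- function(trials, window = 5, clip = c(0.05, 0.95)) {
  trials <- validate_trials(trials)
  window <- check_count(window, "window", lower = 1)
  out <- lapply(split(trials, trials$session_id), function(tr) {
    tr <- tr[order(tr$trial_index), ]
    warn <- tr[tr$trial_type == "warn", ]
    safe <- tr[tr$trial_type == "safe", ]
    n_warn <- nrow(warn)
    if (n_warn < window) return(NULL)
    session_fa <- if (nrow(safe)) mean(safe$outcome == "false_alarm") else 0
    idx <- seq_len(n_warn - window + 1)
    rows <- lapply(idx, function(i) {
      w <- warn[i:(i + window - 1), ]
      enclosed <- safe$trial_index >= w$trial_index[1] &
        safe$trial_index <= w$trial_index[window]
      fa <- if (any(enclosed)) mean(safe$outcome[enclosed] == "false_alarm")
            else session_fa
      tibble(
        session_id = w$session_id[1],
        warn_index = i + window - 1L,
        hit_rate = mean(w$outcome == "hit"),
        fa_rate = fa
      )
    })
    list_rbind(rows)
  })
  out <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    warn(sprintf("fewer than %d warn trials in every session; empty result.",
                 window))
    return(tibble(session_id = character(), warn_index = integer(),
                  hit_rate = double(), fa_rate = double(), dprime = double()))
  }
  out$dprime <- compute_dprime(out$hit_rate, out$fa_rate, clip = clip)
  out
}

#' Warn trials to reach the training criterion
#'
#' Scans a sliding-window d' sequence for the first window at or above the
#' training criterion (d' >= 1.5 by convention) and reports the number of
#' Warn trials experienced up to and including that window.
#'
#' @param dprime_windows A tibble from [sliding_window_dprime()] (a single
#'   session), or a bare numeric d' sequence.
#' @param criterion Performance criterion on d' (default 1.5).
#' @param window Window size used to build the sequence (needed only when a
#'   bare numeric sequence is supplied; default 5).
#' @return A one-row tibble with `trials_to_criterion` (NA if never reached)
#'   and `reached` (logical).
#' @export
trials_to_criterion <- function(dprime_windows, criterion = 1.5, window = 5) {
  if (is.numeric(dprime_windows)) {
    dseq <- dprime_windows
    warn_index <- seq_along(dseq) + window - 1L
  } else {
    stopifnot(is.data.frame(dprime_windows))
    if (length(unique(dprime_windows$session_id)) > 1) {
      abort("`trials_to_criterion()` expects windows from a single session.")
    }
    dseq <- dprime_windows$dprime
    warn_index <- dprime_windows$warn_index
  }
  hit <- which(dseq >= criterion)
  if (length(hit) == 0) {
    tibble(trials_to_criterion = NA_integer_, reached = FALSE)
  } else {
    tibble(trials_to_criterion = as.integer(warn_index[hit[1]]),
           reached = TRUE)
  }
}
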