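# Trial-log handling: outcome classification, validation, CSV round-trip.

TRIAL_TYPES <- c("warn", "safe")
RESPONSES <- c("withdraw", "stay")
OUTCOMES <- c("hit", "miss", "false_alarm", "correct_reject")

#' Classify Go/Nogo trial outcomes
#'
#' Maps (trial type, response) pairs onto signal-detection outcomes: a
#' withdrawal on a Warn (AM) trial is a hit, staying on a Warn trial a miss,
#' withdrawing on a Safe (unmodulated) trial a false alarm, and staying on a
#' Safe trial a correct reject.
#'
#' @param trials A data frame with at least `trial_type` (`"warn"`/`"safe"`)
#'   and `response` (`"withdraw"`/`"stay"`) columns.
#' @return The input as a tibble with an `outcome` column added (replaced if
#'   already present).
#' @examples
#' classify_outcomes(tibble::tibble(
#'   trial_type = c("warn", "warn", "safe", "safe"),
#'   response = c("withdraw", "stay", "withdraw", "stay")
#' ))
#' @export
classify_outcomes <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (!all(c("trial_type", "response") %in% names(trials))) {
    abort("`trials` must have `trial_type` and `response` columns.")
  }
  bad_type <- which(!trials$trial_type %in% TRIAL_TYPES)
  if (length(bad_type)) {
    abort(sprintf("unknown trial_type %s at row %d.",
                  dQuote(trials$trial_type[bad_type[1]]), bad_type[1]))
  }
  bad_resp <- which(!trials$response %in% RESPONSES)
  if (length(bad_resp)) {
    abort(sprintf("unknown response %s at row %d.",
                  dQuote(trials$response[bad_resp[1]]), bad_resp[1]))
  }
  trials <- as_tibble(trials)
  trials$outcome <- dplyr::case_when(
    trials$trial_type == "warn" & trials$response == "withdraw" ~ "hit",
    trials$trial_type == "warn" & trials$response == "stay" ~ "miss",
    trials$trial_type == "safe" & trials$response == "withdraw" ~ "false_alarm",
    TRUE ~ "correct_reject"
  )
  trials
}

# Validate (and complete) a trial tibble used by downstream scoring.
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  needed <- c("session_id", "trial_index", "trial_type")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(sprintf("trial log is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"outcome" %in% names(trials)) trials <- classify_outcomes(trials)
  bad <- which(!trials$outcome %in% OUTCOMES)
  if (length(bad)) {
    abort(sprintf("unknown outcome %s at row %d.",
                  dQuote(trials$outcome[bad[1]]), bad[1]))
  }
  warn_rows <- trials$trial_type == "warn"
  if ("depth_db" %in% names(trials)) {
    d <- trials$depth_db[warn_rows]
    if (anyNA(d) || any(!is.finite(d)) || any(d > 0)) {
      abort("warn trials must carry a finite depth_db <= 0.")
    }
  }
  as_tibble(trials)
}

#' Read / write a trial-log CSV
#'
#' The on-disk format has columns `session_id`, `trial_index`, `trial_type`,
#' `depth_db` (empty for safe trials), `response`, `outcome`.
#'
#' @param path File path.
#' @param trials Trial tibble to write.
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `trials` invisibly.
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          session_id = readr::col_character(),
                          trial_index = readr::col_integer(),
                          trial_type = readr::col_character(),
                          depth_db = readr::col_double(),
                          response = readr::col_character(),
                          outcome = readr::col_character()
                        ))
  validate_trials(tr)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  readr::write_csv(trials[, c("session_id", "trial_index", "trial_type",
                              "depth_db", "response", "outcome")], path)
  invisible(trials)
}
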