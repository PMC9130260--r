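# Shared fixtures for the test suite. Everything is generated in code; no
# data files.

quick_stim <- function(depths = c(-18, -15, -12, -9, -6)) {
  stimulus_spec(am_rate_hz = 5, duration_s = 1, depths_db = depths)
}

# A tiny hand-specified trial log covering all four (type, response) cells.
tiny_trials <- function() {
  tibble::tibble(
    session_id = "t",
    trial_index = 1:10,
    trial_type = c("safe", "safe", "warn", "safe", "warn",
                   "safe", "safe", "warn", "safe", "warn"),
    depth_db = c(NA, NA, -6, NA, -12, NA, NA, -9, NA, -15),
    response = c("stay", "withdraw", "withdraw", "stay", "stay",
                 "stay", "stay", "withdraw", "withdraw", "withdraw")
  )
}

# Build a spike table directly from per-(unit, stimulus) count vectors, one
# synthetic spike per count unit at evenly spaced times. counts is a named
# list: counts[[unit_id]][[stimulus]] = integer vector of per-trial counts.
spikes_from_counts <- function(counts, unit_class = "single") {
  rows <- list()
  for (uid in names(counts)) {
    for (stim in names(counts[[uid]])) {
      trial_id <- 0L
      for (k in counts[[uid]][[stim]]) {
        trial_id <- trial_id + 1L
        if (k > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            unit_id = uid, unit_class = unit_class, trial_id = trial_id,
            stimulus = stim,
            spike_time_s = seq(0, 0.999, length.out = k))
        } else {
          # keep the trial visible via the trial table instead
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Per-unit trial table enumerating every (unit, trial_id, stimulus) cell in
# a counts list (restores zero-spike trials without inventing trials a unit
# never saw).
trial_table_from_counts <- function(counts) {
  rows <- list()
  for (uid in names(counts)) {
    for (stim in names(counts[[uid]])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        unit_id = uid, trial_id = seq_along(counts[[uid]][[stim]]),
        stimulus = stim)
    }
  }
  dplyr::bind_rows(rows)
}

# Spike table for units whose counts are drawn i.i.d. from `rcount(n)`
# per stimulus; used for exchangeability / separability decoder tests.
random_count_spikes <- function(n_units, stimuli, n_trials, rcount,
                                unit_class = "single") {
  counts <- list()
  for (u in seq_len(n_units)) {
    uid <- sprintf("u%02d", u)
    counts[[uid]] <- lapply(stats::setNames(stimuli, stimuli),
                            function(s) rcount(n_trials))
  }
  counts
}
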