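# End-to-end orchestration: configuration, the simulate -> behavior ->
# neurometrics -> decode chain, cross-stage linking statistics, and the run
# report. Every artifact is plain CSV/JSON/YAML and regenerable bit-for-bit
# from the resolved config + master seed.

#' Default run configuration
#'
#' A desk-scale demonstration configuration for [run_full_pipeline()]:
#' a handful of simulated sessions whose observers are generatively coupled
#' to their recorded populations (more sensitive populations belong to
#' observers with better behavioral thresholds), so the within-session
#' behavior-vs-decoder correlation is positive by construction.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1,
    stimulus = list(am_rate_hz = 5, duration_s = 1,
                    depths_db = c(-21, -18, -15, -12, -9, -6),
                    carrier_level_db_spl = 45),
    population = list(n_units = 12, baseline_range = c(10, 40),
                      gain_range = c(1, 6), kappa_range = c(0, 4),
                      cv_range = c(0.05, 0.25), dc_gain = 0.15,
                      prop_single = 0.5),
    experiment = list(n_sessions = 4, n_trials_per_stim = 8,
                      sensitivity_range = c(0.4, 1),
                      observer_width_db = 3, observer_lapse = 0.02,
                      observer_fa_rate = 0.05,
                      threshold_per_sensitivity_db = -14,
                      threshold_offset_db = -4,
                      threshold_noise_sd_db = 1),
    analysis = list(clip = c(0.05, 0.95), criterion = 1.5, window = 5,
                    alpha = 0.05, vs_alpha = 0.001),
    decoder = list(trials_per_unit = 8, n_iterations = 100, min_units = 10,
                   min_trials_per_depth = 8, cost = 1,
                   pooled_depth_range = c(-18, -6))
  ), class = "run_config")
}

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, overlays it on
#' [default_run_config()], and validates the schema: unknown keys are
#' rejected, numeric constraints checked by the underlying constructors.
#'
#' @param path Path to a YAML/JSON config file, or NULL for defaults.
#' @param overrides Optional named list overriding individual entries
#'   (nested lists merge by name).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- unclass(default_run_config())
  user <- list()
  if (!is.null(path)) user <- yaml::read_yaml(path)
  if (!is.null(overrides)) user <- modify_list(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  for (section in names(user)) {
    if (is.list(cfg[[section]])) {
      bad <- setdiff(names(user[[section]]), names(cfg[[section]]))
      if (length(bad)) {
        abort(sprintf("unknown key(s) in config section `%s`: %s.",
                      section, paste(bad, collapse = ", ")))
      }
      cfg[[section]] <- modify_list(cfg[[section]], user[[section]])
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  # constructor validation (errors name the offending field)
  do.call(stimulus_spec, cfg$stimulus)
  do.call(population_params, cfg$population)
  do.call(decoder_config, c(cfg$decoder, list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Simulate a multi-session experiment with behavior-neural coupling
#'
#' Draws, per session, a latent sensitivity in `sensitivity_range`, scales
#' the population's depth-to-rate gains by it, and sets the observer's
#' psychometric midpoint to `threshold_offset_db + threshold_per_sensitivity_db *
#' sensitivity` plus Gaussian noise. Sessions with more sensitive
#' populations therefore have better (more negative) behavioral thresholds,
#' mirroring the link the within-session analysis is designed to detect.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @return A list of `population_session` objects, one per session, each
#'   with an extra `observer` element.
#' @export
simulate_experiment <- function(config = default_run_config()) {
  stim <- do.call(stimulus_spec, config$stimulus)
  ex <- config$experiment
  sessions <- vector("list", ex$n_sessions)
  for (s in seq_len(ex$n_sessions)) {
    sseed <- derive_seed(config$seed, 5000L + s)
    set.seed(sseed)
    sens <- runif(1, ex$sensitivity_range[1], ex$sensitivity_range[2])
    thr <- ex$threshold_offset_db + ex$threshold_per_sensitivity_db * sens +
      rnorm(1, 0, ex$threshold_noise_sd_db)
    thr <- min(thr, -1)
    obs <- observer_params(threshold_db = thr,
                           width_db = ex$observer_width_db,
                           lapse = ex$observer_lapse,
                           fa_rate = ex$observer_fa_rate)
    pp <- config$population
    pp$gain_range <- pp$gain_range * sens
    pop <- do.call(population_params, pp)
    sid <- sprintf("s%02d", s)
    sess <- simulate_population_session(pop, obs, stim,
                                        n_trials_per_stim = ex$n_trials_per_stim,
                                        seed = sseed, session_id = sid)
    # unit ids globally unique so sessions can be pooled
    sess$spikes$unit_id <- paste(sid, sess$spikes$unit_id, sep = "_")
    sess$units$unit_id <- paste(sid, sess$units$unit_id, sep = "_")
    sess$observer <- obs
    sess$sensitivity <- sens
    sessions[[s]] <- sess
  }
  names(sessions) <- vapply(sessions, function(x) x$trials$session_id[1],
                            character(1))
  sessions
}

#' Correlate behavioral with neural detection thresholds
#'
#' Pearson correlation (two-tailed) between per-session behavioral
#' thresholds and a neural threshold — either the session's median
#' AM-responsive unit threshold or the population-decoder threshold — with
#' the least-squares line. Sessions excluded from decoding or with an
#' unattained threshold are dropped and counted.
#'
#' @param link A link table with columns `behavioral_threshold_db` and
#'   either `decoder_threshold_db` or `unit_threshold_db` (see
#'   [run_full_pipeline()]), one row per session.
#' @param which `"decoder"` or `"unit"`.
#' @return One-row tibble: `r`, `p`, `intercept`, `slope`, `n_used`,
#'   `n_dropped`.
#' @export
correlate_behavior_neural <- function(link, which = c("decoder", "unit")) {
  which <- match.arg(which)
  col <- paste0(which, "_threshold_db")
  if (!col %in% names(link)) {
    abort(sprintf("link table has no `%s` column.", col))
  }
  x <- link[[col]]
  y <- link$behavioral_threshold_db
  ok <- is.finite(x) & is.finite(y)
  if ("included" %in% names(link)) ok <- ok & link$included
  if (sum(ok) < 3) {
    abort(sprintf("need >= 3 sessions with both thresholds attained, have %d.",
                  sum(ok)))
  }
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "pearson"))
  line <- lm(y[ok] ~ x[ok])
  tibble(r = unname(ct$estimate), p = ct$p.value,
         intercept = unname(coef(line)[1]), slope = unname(coef(line)[2]),
         n_used = sum(ok), n_dropped = sum(!ok))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> behavior -> neurometrics -> decode -> report on a
#' validated configuration, writing every stage's artifacts (trial-log CSV,
#' per-session spike CSVs, psychometric JSON, unit-summary CSV, decoder
#' JSON, link table, report.md) plus the resolved config into `out_dir`.
#' Idempotent: the same config and seed regenerate byte-identical artifacts.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the link table, correlations, and paths.
#' @export
run_full_pipeline <- function(config = default_run_config(), out_dir,
                              quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    config <- read_run_config(overrides = config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  an <- config$analysis
  dcfg <- do.call(decoder_config, c(config$decoder, list(seed = config$seed)))

  say("stage simulate: %d session(s)", config$experiment$n_sessions)
  sessions <- simulate_experiment(config)
  trials <- list_rbind(lapply(sessions, function(s) s$trials))
  write_trials(trials, file.path(out_dir, "trials.csv"))
  for (sid in names(sessions)) {
    write_spikes(sessions[[sid]]$spikes,
                 file.path(out_dir, sprintf("spikes_%s.csv", sid)))
  }

  say("stage behavior: psychometric fits")
  behavior <- lapply(sessions, function(s) {
    fit <- fit_psychometric(s$trials, clip = an$clip)
    c(as.list(glance(fit)),
      list(threshold_param_db = fit$threshold_param_db,
           width_db = fit$width_db, lapse = fit$lapse, guess = fit$guess))
  })
  jsonlite::write_json(behavior, file.path(out_dir, "behavior.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  say("stage neurometrics: per-unit analysis")
  unit_rows <- list()
  for (sid in names(sessions)) {
    s <- sessions[[sid]]
    tt <- tibble(trial_id = s$trials$trial_index,
                 stimulus = format_depth(s$trials$depth_db))
    nm <- neurometrics(s$spikes, window_s = config$stimulus$duration_s,
                       am_rate_hz = config$stimulus$am_rate_hz,
                       alpha = an$alpha, vs_alpha = an$vs_alpha,
                       trial_table = tt)
    nm$result <- NULL
    nm$session_id <- sid
    unit_rows[[sid]] <- nm
  }
  units_summary <- list_rbind(unit_rows)
  readr::write_csv(units_summary, file.path(out_dir, "units_summary.csv"))

  say("stage decode: within-session + pooled")
  link_rows <- list()
  decoder_json <- list()
  for (sid in names(sessions)) {
    s <- sessions[[sid]]
    tt <- tibble(trial_id = s$trials$trial_index,
                 stimulus = format_depth(s$trials$depth_db))
    beh_thr <- behavior[[sid]]$threshold_db %||% NA_real_
    ws <- within_session_decode(s$spikes, beh_thr, config = dcfg,
                                window_s = config$stimulus$duration_s,
                                trial_table = tt)
    us <- units_summary[units_summary$session_id == sid &
                          units_summary$attained, ]
    link_rows[[sid]] <- tibble(
      session_id = sid,
      behavioral_threshold_db = beh_thr %||% NA_real_,
      unit_threshold_db = if (nrow(us)) median(us$threshold_db) else NA_real_,
      decoder_threshold_db = if (ws$included) ws$result$threshold_db
                             else NA_real_,
      n_units = ws$n_units,
      included = ws$included,
      exclusion_reason = ws$reason)
    decoder_json[[sid]] <- list(
      included = ws$included, reason = ws$reason, n_units = ws$n_units,
      by_depth = if (ws$included) ws$result$by_depth else NULL,
      threshold_db = if (ws$included) ws$result$threshold_db else NA,
      attained = if (ws$included) ws$result$attained else FALSE)
  }
  pooled_spikes <- list_rbind(lapply(sessions, function(s) s$spikes))
  # per-unit trial table: pooled units saw only their own session's trials
  pooled_tt <- list_rbind(lapply(sessions, function(s) {
    tidyr::crossing(
      distinct(s$spikes, .data$unit_id),
      tibble(trial_id = s$trials$trial_index,
             stimulus = format_depth(s$trials$depth_db)))
  }))
  pooled <- tryCatch(
    pooled_decode(pooled_spikes, config = dcfg,
                  window_s = config$stimulus$duration_s,
                  trial_table = pooled_tt),
    error = function(e) NULL)
  decoder_json$pooled <- if (is.null(pooled)) {
    list(included = FALSE, reason = "pooled decode failed its filters")
  } else {
    list(included = TRUE, n_units = pooled$n_units,
         by_depth = pooled$by_depth, threshold_db = pooled$threshold_db,
         attained = pooled$attained)
  }
  jsonlite::write_json(decoder_json, file.path(out_dir, "decoder.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  link <- list_rbind(link_rows)
  readr::write_csv(link, file.path(out_dir, "link_table.csv"))

  correlations <- list()
  for (which in c("decoder", "unit")) {
    correlations[[which]] <- tryCatch(
      correlate_behavior_neural(link, which),
      error = function(e) tibble(r = NA_real_, p = NA_real_,
                                 intercept = NA_real_, slope = NA_real_,
                                 n_used = 0L, n_dropped = nrow(link)))
  }
  jsonlite::write_json(correlations, file.path(out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  say("stage report")
  write_report(out_dir)
  invisible(list(link = link, correlations = correlations,
                 out_dir = out_dir))
}

#' Write a human-readable run report
#'
#' Assembles `report.md` from the stage artifacts present in a run
#' directory: behavioral thresholds, responsive-unit counts, decoder
#' thresholds, behavior-neural correlations, and every exclusion with its
#' reason. Missing stages are flagged as absent rather than failing.
#'
#' @param run_dir A directory produced by [run_full_pipeline()].
#' @return Invisibly, the path to `report.md`.
#' @export
write_report <- function(run_dir) {
  p <- function(...) file.path(run_dir, ...)
  lines <- c("# AM depth-detection run report", "")
  if (file.exists(p("behavior.json"))) {
    beh <- jsonlite::read_json(p("behavior.json"))
    lines <- c(lines, "## Behavior", "",
               "| session | threshold (dB re: 100%) | attained | FA rate |",
               "|---|---|---|---|")
    for (sid in names(beh)) {
      b <- beh[[sid]]
      thr <- if (isTRUE(b$attained)) sprintf("%.2f", b$threshold_db) else "unattained"
      lines <- c(lines, sprintf("| %s | %s | %s | %.3f |", sid, thr,
                                isTRUE(b$attained), b$fa_rate))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "## Behavior", "", "_absent_", "")
  }
  if (file.exists(p("units_summary.csv"))) {
    us <- readr::read_csv(p("units_summary.csv"), show_col_types = FALSE)
    lines <- c(lines, "## Unit neurometrics", "",
               sprintf("- units analysed: %d", nrow(us)),
               sprintf("- AM responsive: %d", sum(us$responsive)),
               sprintf("- thresholds attained: %d", sum(us$attained)))
    if (any(us$attained)) {
      lines <- c(lines, sprintf(
        "- median attained unit threshold: %.2f dB re: 100%%",
        median(us$threshold_db[us$attained])))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "## Unit neurometrics", "", "_absent_", "")
  }
  if (file.exists(p("decoder.json"))) {
    dec <- jsonlite::read_json(p("decoder.json"))
    lines <- c(lines, "## Population decoder", "")
    for (sid in setdiff(names(dec), "pooled")) {
      d <- dec[[sid]]
      if (isTRUE(d$included)) {
        thr <- if (isTRUE(d$attained)) sprintf("%.2f dB", d$threshold_db)
               else "unattained"
        lines <- c(lines, sprintf("- %s: %d units, threshold %s", sid,
                                  d$n_units, thr))
      } else {
        lines <- c(lines, sprintf("- %s: excluded (%s)", sid, d$reason))
      }
    }
    pd <- dec$pooled
    if (isTRUE(pd$included)) {
      thr <- if (isTRUE(pd$attained)) sprintf("%.2f dB", pd$threshold_db)
             else "unattained"
      lines <- c(lines, sprintf("- pooled single units: %d units, threshold %s",
                                pd$n_units, thr))
    } else {
      lines <- c(lines, sprintf("- pooled: excluded (%s)", pd$reason))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "## Population decoder", "", "_absent_", "")
  }
  if (file.exists(p("correlations.json"))) {
    co <- jsonlite::read_json(p("correlations.json"))
    lines <- c(lines, "## Behavior-neural correlations", "")
    for (which in names(co)) {
      c1 <- co[[which]][[1]]
      if (is.null(c1$r) || !is.numeric(c1$r)) {
        lines <- c(lines, sprintf("- %s: not computed (insufficient pairs)",
                                  which))
      } else {
        lines <- c(lines, sprintf("- %s thresholds: r = %.3f, p = %.3g (n = %d)",
                                  which, c1$r, c1$p, c1$n_used))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, p("report.md"))
  invisible(p("report.md"))
}
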