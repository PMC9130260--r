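quick_cfg <- function(...) {
  decoder_config(n_iterations = 100, min_units = 2, seed = 5, ...)
}

test_that("response vectors equal a brute-force recount", {
  counts <- list(
    u01 = list(safe = rep(3L, 8), `-6` = c(5L, 6L, 4L, 5L, 7L, 5L, 6L, 5L)),
    u02 = list(safe = c(2L, 0L, 1L, 3L, 2L, 2L, 1L, 2L),
               `-6` = c(4L, 3L, 5L, 4L, 4L, 3L, 5L, 4L)))
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  expect_equal(sort(names(resp$counts)), c("u01", "u02"))
  # one unit, 8 trials of 3 spikes each -> an 8-vector of 3s
  expect_equal(resp$counts$u01$safe, rep(3L, 8))
  # brute-force groupby recount straight off the spike table
  for (uid in names(counts)) {
    for (stim in names(counts[[uid]])) {
      brute <- vapply(seq_len(8), function(t) {
        sum(sp$unit_id == uid & sp$stimulus == stim & sp$trial_id == t &
              sp$spike_time_s >= 0 & sp$spike_time_s < 1)
      }, integer(1))
      expect_equal(sort(resp$counts[[uid]][[stim]]), sort(brute))
    }
  }
})

test_that("units below the trial minimum are dropped and reported", {
  counts <- list(
    u01 = list(safe = rep(3L, 8), `-6` = rep(5L, 8)),
    u02 = list(safe = rep(2L, 7), `-6` = rep(4L, 8)))  # 7 safe trials
  sp <- spikes_from_counts(counts)
  tt <- dplyr::bind_rows(
    tibble::tibble(trial_id = 1:8, stimulus = "safe"),
    tibble::tibble(trial_id = 1:8, stimulus = "-6"))
  # u02 has no row for safe trial 8 in its own data; restrict its table
  expect_message(
    resp <- build_response_vectors(sp, min_trials = 8,
                                   trial_table = trial_table_from_counts(counts)),
    "dropped")
  expect_equal(names(resp$counts), "u01")
  expect_equal(resp$dropped$unit_id, "u02")
  # nothing left -> refused with a diagnostic
  counts_bad <- list(u01 = list(safe = rep(1L, 3), `-6` = rep(2L, 3)))
  expect_error(
    build_response_vectors(spikes_from_counts(counts_bad), min_trials = 8,
                           trial_table = trial_table_from_counts(counts_bad)),
    "no unit")
})

test_that("exchangeable classes decode at chance", {
  set.seed(99)
  counts <- random_count_spikes(8, c("safe", "-12"), 30,
                                function(n) rpois(n, 12))
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  res <- decode_depth(resp, -12, quick_cfg())
  d <- compute_dprime(res$hit_rate, res$fa_rate)
  expect_lt(abs(d), 0.6)
})

test_that("perfect separation saturates at the clipped ceiling", {
  counts <- random_count_spikes(5, "safe", 10, function(n) rep(0L, n))
  for (u in names(counts)) counts[[u]][["-6"]] <- rep(10L, 10)
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  res <- decode_depth(resp, -6, quick_cfg())
  expect_equal(res$hit_rate, 1)
  expect_equal(res$fa_rate, 0)
  expect_equal(compute_dprime(1, 0), 2 * qnorm(0.95), tolerance = 1e-12)
})

test_that("a single-unit decoder approaches the ideal-observer d-prime", {
  # approximately normal counts, equal spread: analytic d' = 3 / 2 = 1.5
  set.seed(31)
  counts <- list(u01 = list(
    safe = pmax(0L, as.integer(round(rnorm(200, 10, 2)))),
    `-9` = pmax(0L, as.integer(round(rnorm(200, 13, 2))))))
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  res <- decode_depth(resp, -9, decoder_config(n_iterations = 500,
                                               min_units = 1, seed = 7))
  d <- compute_dprime(res$hit_rate, res$fa_rate)
  expect_lt(abs(d - 1.5), 0.4)
})

test_that("decoding is deterministic and order-independent per depth", {
  set.seed(1)
  counts <- random_count_spikes(6, c("safe", "-6", "-12"), 12,
                                function(n) rpois(n, 8))
  for (u in names(counts)) counts[[u]][["-6"]] <- rpois(12, 14)
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  cfg <- quick_cfg()
  a <- decode_depth(resp, -6, cfg)
  # decoding another depth first must not change the -6 dB stream
  invisible(decode_depth(resp, -12, cfg))
  b <- decode_depth(resp, -6, cfg)
  expect_identical(a, b)
})

test_that("fully degenerate populations are refused with accounting", {
  counts <- list(u01 = list(safe = rep(5L, 10), `-6` = rep(5L, 10)),
                 u02 = list(safe = rep(5L, 10), `-6` = rep(5L, 10)))
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  expect_error(suppressWarnings(decode_depth(resp, -6, quick_cfg())),
               "degenerate")
})

test_that("the decoder neurometric chain yields a monotone curve and threshold", {
  # separability grows toward 0 dB by construction
  set.seed(8)
  depths <- c(-18, -14, -10, -6)
  bump <- c(0.2, 1.5, 4, 8)  # rate increase over baseline per depth
  counts <- list()
  for (u in 1:6) {
    uid <- sprintf("u%02d", u)
    counts[[uid]] <- list(safe = rpois(12, 10))
    for (i in seq_along(depths)) {
      counts[[uid]][[sprintf("%.10g", depths[i])]] <-
        rpois(12, 10 + bump[i])
    }
  }
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
  res <- decoder_neurometric(resp, quick_cfg())
  expect_s3_class(res, "decoder_result")
  expect_gt(cor(res$by_depth$depth_db, res$by_depth$dprime), 0.8)
  expect_true(res$attained)
  expect_lt(res$threshold_db, -6)
  expect_equal(nrow(tidy(res)), 4)
  expect_equal(glance(res)$n_units, 6)
})

test_that("within-session filters enforce the unit and trial minima", {
  set.seed(12)
  mk_session <- function(n_units) {
    counts <- random_count_spikes(n_units, c("safe", "-12", "-9", "-6", "-15"),
                                  8, function(n) rpois(n, 8))
    for (u in names(counts)) {
      counts[[u]][["-6"]] <- rpois(8, 16)
      counts[[u]][["-9"]] <- rpois(8, 13)
    }
    counts
  }
  c9 <- mk_session(9)
  ws9 <- within_session_decode(spikes_from_counts(c9), -10,
                               decoder_config(n_iterations = 20, seed = 2),
                               trial_table = trial_table_from_counts(c9))
  expect_false(ws9$included)
  expect_match(ws9$reason, "need 10")
  c10 <- mk_session(10)
  ws10 <- within_session_decode(spikes_from_counts(c10), -10,
                                decoder_config(n_iterations = 20, seed = 2),
                                trial_table = trial_table_from_counts(c10))
  expect_true(ws10$included)
  expect_equal(ws10$n_units, 10)
  expect_equal(ws10$behavioral_threshold_db, -10)
})

test_that("pooled mode enforces its depth range and is reproducible", {
  set.seed(3)
  counts <- random_count_spikes(4, c("safe", "-12", "-9", "-15", "-6"), 10,
                                function(n) rpois(n, 9))
  sp <- spikes_from_counts(counts)
  tt <- trial_table_from_counts(counts)
  cfg <- quick_cfg()
  expect_error(pooled_decode(sp, cfg, depths = c(-3, -6), trial_table = tt),
               "restricted")
  p1 <- pooled_decode(sp, cfg, trial_table = tt)
  p2 <- pooled_decode(sp, cfg, trial_table = tt)
  expect_identical(tidy(p1), tidy(p2))
  expect_true(all(p1$by_depth$depth_db >= -18 & p1$by_depth$depth_db <= -6))
})

test_that("adding an informative unit does not hurt the decoder", {
  set.seed(44)
  base <- random_count_spikes(4, "safe", 20, function(n) rpois(n, 10))
  for (u in names(base)) base[[u]][["-9"]] <- rpois(20, 13)
  plus <- base
  plus$u99 <- list(safe = rpois(20, 10), `-9` = rpois(20, 20))
  d_of <- function(counts, seed) {
    sp <- spikes_from_counts(counts)
    tt <- trial_table_from_counts(counts)
    resp <- build_response_vectors(sp, min_trials = 8, trial_table = tt)
    res <- decode_depth(resp, -9, decoder_config(n_iterations = 150,
                                                 min_units = 1, seed = seed))
    compute_dprime(res$hit_rate, res$fa_rate)
  }
  d_base <- mean(sapply(1:5, function(s) d_of(base, s)))
  d_plus <- mean(sapply(1:5, function(s) d_of(plus, s)))
  expect_gt(d_plus, d_base - 0.1)
})
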