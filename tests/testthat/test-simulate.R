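test_that("parameter constructors reject out-of-range values by name", {
  expect_error(observer_params(width_db = -1), "width_db")
  expect_error(observer_params(lapse = 0.5), "lapse")
  expect_error(observer_params(fa_rate = 0), "fa_rate")
  expect_error(stimulus_spec(depths_db = c(-6, 3)), "depth")
  expect_error(unit_params(baseline_rate_hz = -2), "baseline_rate_hz")
  expect_error(population_params(n_units = 0), "n_units")
})

test_that("behavioral sessions are deterministic and structurally valid", {
  obs <- observer_params()
  stim <- quick_stim()
  a <- simulate_behavior_session(obs, stim, n_warn = 6, seed = 99)
  b <- simulate_behavior_session(obs, stim, n_warn = 6, seed = 99)
  expect_identical(a, b)
  # each warn trial preceded by 3-5 safe trials
  warn_pos <- which(a$trial_type == "warn")
  gaps <- diff(c(0, warn_pos)) - 1
  expect_true(all(gaps %in% 3:5))
  # every depth appears n_warn times
  expect_true(all(table(a$depth_db[warn_pos]) == 6))
})

test_that("deep depths saturate and the midpoint halves the hit rate", {
  stim0 <- stimulus_spec(depths_db = 0)
  # depth far above threshold, no lapse, negligible FA -> certain hits
  obs_easy <- observer_params(threshold_db = -30, width_db = 2, lapse = 0,
                              fa_rate = 1e-9)
  tr <- simulate_behavior_session(obs_easy, stim0, n_warn = 200, seed = 1)
  expect_equal(mean(tr$outcome[tr$trial_type == "warn"] == "hit"), 1)
  # at the midpoint the hit probability is one half
  stim_mid <- stimulus_spec(depths_db = -12)
  obs_mid <- observer_params(threshold_db = -12, width_db = 3, lapse = 0,
                             fa_rate = 1e-9)
  tr2 <- simulate_behavior_session(obs_mid, stim_mid, n_warn = 2000, seed = 2)
  hr <- mean(tr2$outcome[tr2$trial_type == "warn"] == "hit")
  expect_lt(abs(hr - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("empirical hit rates track the analytic observer curve", {
  obs <- observer_params(threshold_db = -12, width_db = 3, lapse = 0.02,
                         fa_rate = 0.05)
  depths <- seq(-21, 0, by = 3)
  stim <- stimulus_spec(depths_db = depths)
  n <- 5000
  tr <- simulate_behavior_session(obs, stim, n_warn = n, seed = 7)
  warn <- tr[tr$trial_type == "warn", ]
  for (d in depths) {
    p <- observer_hit_prob(obs, d)
    emp <- mean(warn$outcome[warn$depth_db == d] == "hit")
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
  # safe withdrawals follow the FA rate
  safe <- tr[tr$trial_type == "safe", ]
  expect_lt(abs(mean(safe$outcome == "false_alarm") - 0.05),
            3 * sqrt(0.05 * 0.95 / nrow(safe)))
})

test_that("safe spike trains are constant-rate Poisson at the baseline", {
  u <- unit_params(baseline_rate_hz = 20, gain = 0, kappa = 0,
                   rate_noise_cv = 0)
  stim <- quick_stim()
  set.seed(11)
  counts <- replicate(10000, length(simulate_spike_train(u, stim, NA)))
  se <- sqrt(20 / 10000)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # Poisson: variance tracks the mean
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)
  # all times inside the window
  st <- simulate_spike_train(u, stim, NA, seed = 3)
  expect_true(all(st >= 0 & st < stim$duration_s))
})

test_that("phase locking rises monotonically with kappa at full depth", {
  stim <- quick_stim()
  vs_mean <- sapply(c(0, 1, 3, 8), function(k) {
    u <- unit_params(baseline_rate_hz = 30, gain = 1, kappa = k,
                     rate_noise_cv = 0)
    set.seed(101)
    mean(replicate(30, {
      st <- unlist(lapply(1:20, function(i)
        simulate_spike_train(u, stim, 0)))
      vector_strength(st, stim$am_rate_hz)
    }))
  })
  expect_true(all(diff(vs_mean) > 0))
})

test_that("safe-trial phases look uniform under the Rayleigh test", {
  u <- unit_params(baseline_rate_hz = 30, gain = 4, kappa = 3,
                   rate_noise_cv = 0.1)
  stim <- quick_stim()
  set.seed(5)
  reject <- replicate(40, {
    st <- unlist(lapply(1:30, function(i) simulate_spike_train(u, stim, NA)))
    vs <- vector_strength(st, stim$am_rate_hz)
    rayleigh_test(vs, length(st))$significant
  })
  # type-I error at alpha = 0.001: zero rejections in 40 draws is the norm
  expect_lte(sum(reject), 1)
})

test_that("modulation energy of the rate never falls as depth rises", {
  # cycle-averaged modulation energy of r(t) is monotone in m; check via
  # the spike-phase resultant at increasing depth
  u <- unit_params(baseline_rate_hz = 40, gain = 3, kappa = 2,
                   rate_noise_cv = 0)
  stim <- quick_stim()
  vs_by_depth <- sapply(c(-18, -12, -6, 0), function(d) {
    set.seed(13)
    st <- unlist(lapply(1:60, function(i) simulate_spike_train(u, stim, d)))
    vector_strength(st, stim$am_rate_hz)
  })
  expect_true(all(diff(vs_by_depth) > -0.02))
})

test_that("population sessions are reproducible and fully indexed", {
  pop <- population_params(n_units = 20)
  obs <- observer_params()
  stim <- stimulus_spec(depths_db = seq(-16, -6, by = 2))
  s1 <- simulate_population_session(pop, obs, stim, n_trials_per_stim = 8,
                                    seed = 21)
  s2 <- simulate_population_session(pop, obs, stim, n_trials_per_stim = 8,
                                    seed = 21)
  expect_identical(s1, s2)
  # every (unit, trial) pair appears at most once per spike-group; row count
  # equals the total number of spikes
  key <- paste(s1$spikes$unit_id, s1$spikes$trial_id, s1$spikes$spike_time_s)
  expect_equal(nrow(s1$spikes), length(key))
  per_pair <- dplyr::count(s1$spikes, unit_id, trial_id)
  expect_true(all(per_pair$n >= 1))
  expect_lte(nrow(per_pair), 20 * nrow(s1$trials))
  expect_true(all(s1$spikes$spike_time_s >= 0 &
                    s1$spikes$spike_time_s < stim$duration_s))
  # spike CSV round trip: labels and indices exact, times to the 6-decimal
  # on-disk precision; a second round trip is a fixed point
  path <- withr::local_tempfile(fileext = ".csv")
  write_spikes(s1$spikes, path)
  back <- read_spikes(path)
  expect_equal(as.data.frame(back[, 1:4]), as.data.frame(s1$spikes[, 1:4]))
  expect_equal(back$spike_time_s, s1$spikes$spike_time_s, tolerance = 1e-6)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_spikes(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(simulate_population_session(pop, obs, stim,
                                           n_trials_per_stim = 0, seed = 1),
               "n_trials_per_stim")
})
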