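# Independent oracle for the logistic threshold: bisection on the fitted
# curve.
bisect_threshold <- function(y0, a, k, x0, lo = -60, hi = 0, tol = 1e-8) {
  f <- function(x) y0 + a / (1 + exp(-k * (x - x0))) - 1
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("firing rate is spike count over the window", {
  expect_equal(firing_rate(numeric(0)), 0)
  expect_equal(firing_rate(seq(0.01, 0.99, length.out = 20)), 20)
  expect_equal(firing_rate(seq(0.01, 0.49, length.out = 7), window_s = 0.5), 14)
  expect_warning(r <- firing_rate(c(0.2, 1.4)), "outside")
  expect_equal(r, 1)
})

test_that("neural d-prime matches direct arithmetic on known rates", {
  # safe mean 10, depth mean 14, every stimulus sample variance 4 -> pooled
  # SD 2, d' = (14 - 10) / 2
  dev <- c(-3, -1, 1, 3) / sqrt(5 / 3)  # sample variance exactly 4
  rates <- tibble::tibble(
    stimulus = rep(c("safe", "-6"), each = 4),
    depth_db = rep(c(NA, -6), each = 4),
    rate = c(10 + dev, 14 + dev))
  expect_equal(var(10 + dev), 4, tolerance = 1e-12)
  dpd <- neural_dprime_by_depth(rates)
  expect_equal(dpd$dprime, 2, tolerance = 1e-12)
  expect_equal(attr(dpd, "pooled_sd"), 2, tolerance = 1e-12)
  # equal means give zero d'
  rates0 <- rates
  rates0$rate <- rep(10 + dev, 2)
  expect_equal(neural_dprime_by_depth(rates0)$dprime, 0)
  # zero variance everywhere flags the unit degenerate
  ratesc <- rates
  ratesc$rate <- rep(c(10, 14), each = 4)
  dg <- neural_dprime_by_depth(ratesc)
  expect_true(attr(dg, "degenerate"))
  expect_true(is.na(dg$dprime))
})

test_that("noiseless logistic data are recovered to high precision", {
  x <- seq(-24, 0, by = 3)
  truth <- list(y0 = 0, a = 3, k = 1, x0 = -10)
  y <- truth$y0 + truth$a / (1 + exp(-truth$k * (x - truth$x0)))
  fit <- fit_neurometric_logistic(x, y)
  expect_true(fit$valid)
  expect_lt(abs(fit$a - truth$a) / truth$a, 1e-3)
  expect_lt(abs(fit$k - truth$k) / truth$k, 1e-3)
  expect_lt(abs(fit$x0 - truth$x0) / abs(truth$x0), 1e-3)
  expect_lt(abs(fit$y0 - truth$y0), 1e-3)
  expect_gt(fit$r, 0.9999)
})

test_that("constant d-prime data invalidate the fit", {
  x <- seq(-18, -6, by = 3)
  fit <- fit_neurometric_logistic(x, rep(1.3, length(x)))
  expect_false(fit$valid)
  expect_true(is.na(fit$r))
  expect_error(fit_neurometric_logistic(c(-9, -6), c(0, 1)), ">= 4")
})

test_that("noisy logistic midpoints are recovered within 2 dB", {
  x <- seq(-20, 0, by = 4)
  set.seed(55)
  err <- replicate(100, {
    y <- 0.2 + 2.5 / (1 + exp(-0.8 * (x + 10))) + rnorm(length(x), 0, 0.3)
    fit <- fit_neurometric_logistic(x, y)
    if (fit$valid) fit$x0 - (-10) else NA_real_
  })
  expect_lt(median(abs(err), na.rm = TRUE), 2)
})

test_that("the closed-form threshold equals bisection on the fit", {
  # symmetric case: half-range at midpoint equals the criterion
  fit <- list(y0 = 0, a = 2, k = 1, x0 = -10, valid = TRUE)
  thr <- neurometric_threshold(fit)
  expect_equal(thr$threshold_db, -10, tolerance = 1e-9)
  # max below criterion: unattained
  expect_false(neurometric_threshold(list(y0 = 0, a = 0.8, k = 1, x0 = -10,
                                          valid = TRUE))$attained)
  # lower asymptote above criterion: the fit never crosses upward
  expect_false(neurometric_threshold(list(y0 = 1.4, a = 2, k = 1, x0 = -10,
                                          valid = TRUE))$attained)
  set.seed(8)
  for (i in 1:25) {
    pars <- list(y0 = runif(1, -0.5, 0.8), a = runif(1, 0.5, 4),
                 k = runif(1, 0.1, 3), x0 = runif(1, -20, -2), valid = TRUE)
    got <- neurometric_threshold(pars)
    oracle <- bisect_threshold(pars$y0, pars$a, pars$k, pars$x0)
    if (got$attained) {
      expect_lt(abs(got$threshold_db - oracle), 1e-6)
    } else {
      # bisection either found nothing or a crossing beyond 0 dB
      expect_true(is.na(oracle) || oracle > 0)
    }
  }
})

test_that("AM responsivity is the stated conjunction, exhaustively", {
  cases <- expand.grid(p = c(0.01, 0.2), maxd = c(0.9, 2))
  got <- with(cases, classify_am_responsive(p, maxd, alpha = 0.05))
  expect_equal(got, with(cases, p < 0.05 & maxd >= 1))
  # NA fit p (invalid fit) is never responsive
  expect_false(classify_am_responsive(NA, 3))
})

test_that("vector strength has its analytic extremes and invariances", {
  f <- 5
  # all spikes at one phase
  expect_equal(vector_strength((0:99) / f, f), 1)
  # equal split at antiphase cancels
  t2 <- c((0:49) / f, (0:49 + 0.5) / f)
  expect_equal(vector_strength(t2, f), 0, tolerance = 1e-12)
  # invariant to a common phase shift
  set.seed(3)
  t3 <- sort(runif(200))
  expect_equal(vector_strength(t3, f), vector_strength(t3 + 0.02, f),
               tolerance = 1e-9)
  # invariant to trial partitioning: pooled phases are pooled phases
  expect_equal(vector_strength(c(t3[1:100], t3[101:200]), f),
               vector_strength(t3, f))
  expect_error(vector_strength(numeric(0)), "zero spikes")
})

test_that("uniform phases give the Rayleigh mean resultant", {
  set.seed(17)
  n <- 200
  vs <- replicate(400, vector_strength(runif(n), 1))
  # E[VS] ~ sqrt(pi) / (2 sqrt(n)) under uniformity
  expect_lt(abs(mean(vs) - sqrt(pi) / (2 * sqrt(n))), 0.01)
})

test_that("the Rayleigh test behaves at its extremes", {
  r1 <- rayleigh_test(1, 100)
  expect_lt(r1$p_value, 1e-20)
  expect_true(r1$significant)
  r0 <- rayleigh_test(0, 100)
  expect_equal(r0$p_value, 1, tolerance = 1e-6)
  expect_false(r0$significant)
})

test_that("safe-vs-safe splits center neural d-prime on zero", {
  u <- unit_params(baseline_rate_hz = 25, gain = 0, kappa = 0,
                   rate_noise_cv = 0.1)
  stim <- quick_stim()
  set.seed(23)
  rates_all <- replicate(40, length(simulate_spike_train(u, stim, NA)))
  dps <- replicate(200, {
    idx <- sample(40, 20)
    a <- rates_all[idx]; b <- rates_all[-idx]
    sp <- sqrt(((19) * var(a) + (19) * var(b)) / 38)
    (mean(a) - mean(b)) / sp
  })
  expect_lt(abs(mean(dps)), 0.1)
})

test_that("the per-unit pipeline ties rates, fits and phase locking together", {
  stim <- quick_stim(seq(-18, -3, by = 3))
  u <- unit_params(unit_id = "uX", baseline_rate_hz = 30, gain = 5,
                   kappa = 2, rate_noise_cv = 0.1)
  set.seed(41)
  rows <- list()
  for (stim_lab in c("safe", as.character(stim$depths_db))) {
    d <- if (stim_lab == "safe") NA else as.numeric(stim_lab)
    for (t in 1:12) {
      st <- simulate_spike_train(u, stim, d)
      if (length(st)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          unit_id = "uX", unit_class = "single",
          trial_id = t, stimulus = stim_lab, spike_time_s = st)
      }
    }
  }
  spikes <- dplyr::bind_rows(rows)
  res <- neurometric(spikes, window_s = 1, am_rate_hz = 5)
  expect_s3_class(res, "neurometric_result")
  expect_true(res$fit$valid)
  expect_true(res$responsive)
  expect_true(res$attained)
  expect_lt(res$threshold_db, 0)
  # d' increases toward 0 dB for a driven unit
  dpd <- res$dprime_by_depth
  expect_gt(cor(dpd$depth_db, dpd$dprime, method = "spearman"), 0.5)
  expect_true(all(res$phase_locking$vs >= 0 & res$phase_locking$vs <= 1))
  # tidy/glance surfaces
  expect_true("vs" %in% names(tidy(res)))
  expect_equal(glance(res)$unit_id, "uX")
})
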