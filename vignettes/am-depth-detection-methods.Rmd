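---
title: "Methods: linking AM depth-detection behavior to cortical coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking AM depth-detection behavior to cortical coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdetect)
```

## The problem

In a Go/Nogo amplitude-modulation (AM) depth-detection task, an animal
drinks from a spout during continuous unmodulated noise (Safe trials) and
must withdraw when the noise becomes sinusoidally amplitude-modulated at
5 Hz (Warn trials). Warn stimuli vary in modulation depth, expressed in dB
re: 100% (0 dB is full modulation, `m = 10^(depth_db/20)`). The analysis
chain implemented here scores behavior with signal-detection theory, fits
psychometric and neurometric functions whose detection threshold is the
depth at which d' = 1, quantifies phase locking of cortical spiking, and
reads AM depth out of population spike counts with a cross-validated linear
classifier. All stages operate on plain tabular inputs (trial logs and
spike tables) and can be exercised end to end on the package's synthetic
data generator.

## Behavioral scoring

Each trial is classified from its (type, response) pair: warn + withdraw is
a hit, warn + stay a miss, safe + withdraw a false alarm, safe + stay a
correct reject. Sensitivity is `d' = z(hit rate) − z(false-alarm rate)`
with both rates constrained to [0.05, 0.95] before the probit transform,
which bounds |d'| at `2 * qnorm(0.95) = 3.2897`. The source convention
states this clipping for the psychometric transform; we apply it uniformly
(training curves, sliding windows, neurometric conversion, decoder output)
because every stage is exposed to empirical rates of 0 or 1, and a uniform
bound keeps all d' values on one comparable scale.

Procedural training is scored with a 5-trial sliding window over Warn
trials. The window's false-alarm rate uses the Safe trials temporally
enclosed between the window's first and last Warn trial; when a window
encloses no Safe trial, the whole-session false-alarm rate is substituted.
Windows never cross session boundaries. Training criterion is the first
window with d' >= 1.5, reported as a Warn-trial count.

## Psychometric model

Hit rates versus depth are fit with a cumulative Gaussian with lapse,

p(x) = gamma + (1 − gamma − lambda) * Phi((x − m) / sigma),

by maximum a posteriori (MAP) estimation on the binomial likelihood. Design
choices where the procedure was open:

* **Guess rate gamma** is pinned to the measured session false-alarm rate:
  in Go/Nogo the lower asymptote of the withdrawal probability is exactly
  the tendency to withdraw without a signal.
* **Lapse lambda** is free on [0, 0.2] under a Beta(1, 24) prior (mean
  0.04, most mass below 0.05); trained animals rarely lapse more.
* **Midpoint and spread** get weakly informative priors spanning the tested
  depth range (normal on m centred mid-range with SD equal to the range;
  lognormal on sigma centred at a quarter of the range).
* MAP rather than a full posterior keeps the fit deterministic and cheap;
  point estimates are what the downstream threshold extraction needs.

Optimisation is multi-start L-BFGS-B over a grid of midpoint and spread
starts; the fit is flagged non-converged if the optimiser fails, if m or
sigma lands on its box boundary, or if the fitted curve does not beat a
flat (depth-independent) model on likelihood — the latter catches sessions
whose hit rate decreases with depth. A lapse estimate of exactly zero is
*not* a boundary failure: zero is the prior's mode.

The detection threshold solves d'(x) = 1 on the fitted curve analytically:
with z_F = z(clip(gamma)), the target hit rate is Phi(1 + z_F), and the
threshold is `m + sigma * qnorm((target − gamma)/(1 − gamma − lambda))`.
It is flagged unattained — never extrapolated — when the clipped curve
cannot reach d' = 1 at any depth <= 0 dB.

Perceptual learning is summarised by an ordinary-least-squares ANCOVA-style
model, `threshold ~ log10(day) (+ group + interaction)`, with day 1 the
first psychometric session; the slope is reported in dB per log10(day) and
the group term in dB.

## Neurometric analysis

Per unit, firing rate is the spike count over the 1 s analysis window.
Neural d' at each depth is the mean rate difference from the unmodulated
Safe stimulus divided by the pooled SD across all stimuli (Safe included),
where "pooled" is the standard degrees-of-freedom-weighted root-mean of
per-stimulus variances. Including Safe in the pool follows the plain
reading of "pooled across all the stimuli"; excluding it would rescale all
d' values by a bounded factor without changing ranks. Units with fewer than
2 trials for a stimulus exclude that stimulus (variance undefined); units
with zero pooled SD are flagged degenerate.

Neural d' versus depth is fit with a 4-parameter logistic
`y0 + a / (1 + exp(−k (x − x0)))` by Levenberg–Marquardt least squares,
with `a >= 0` and `k >= 0` so the curve is non-decreasing toward 0 dB, and
multi-start initialisation over an x0 grid (the observed depths) crossed
with three slope scales. Fit validity is the Pearson correlation between
fitted and observed d' with its two-tailed p value; constant-d' data leave
the correlation undefined and the fit invalid. A unit is **AM responsive**
iff the fit is significant (p < 0.05 by default) *and* its maximum observed
neural d' is >= 1. The neural threshold inverts the logistic at d' = 1 in
closed form and is unattained when the fit never crosses 1 on (−Inf, 0] —
including the case where the lower asymptote already sits above 1.

Phase locking is vector strength: spike phases `theta = 2*pi*frac(t*f)`
pooled across a depth's trials, VS = resultant length / n. Pooling (rather
than averaging per-trial VS) makes n in the Rayleigh statistic the total
spike count, matching the test's formulation `Z = n VS^2` with the
small-sample-corrected p value `exp(−Z) (1 + (2Z − Z^2)/(4n))`, thresholded
at p < 0.001. At n >= 50 the correction is numerically immaterial.

## Population decoder

Spike counts over the 1000 ms window from N units form the population
response vector. Per depth and per iteration, 8 trials per class are
subsampled without replacement independently for each unit, one per class
is held out (7 train / 1 test per class), a linear maximum-margin
classifier (SVM, linear kernel, cost 1) is fit to the 14 training vectors,
and the 2 held-out vectors are classified. Over 500 iterations the hit rate
is the fraction of Warn tests classified Warn and the false-alarm rate the
fraction of Safe tests classified Warn; both convert to d' with the usual
clipping, are fit with the same logistic, and yield a threshold at d' = 1.
Decisions where the procedure was open:

* One held-out trial *per class* per iteration, so hits and false alarms
  accrue at the same rate.
* Trials are resampled independently per unit in both modes. Pooled
  pseudo-populations have no shared trial identity by construction; within
  sessions we use the same scheme for consistency (a flag preserving
  simultaneous trial identity is deliberately not the default, since the
  source procedure describes per-unit subsampling).
* Class balance is exact (7 + 7), so no class weighting is used.
* Iterations whose training set is degenerate (all vectors identical) are
  skipped and counted; rates use completed iterations as the denominator.
* One master seed spawns an independent RNG stream per depth, so per-depth
  results do not depend on decoding order.

Within-session decoding applies the inclusion filters (>= 10 single/multi
units, >= 8 trials per depth) and pairs the decoder threshold with the
session's behavioral threshold. Pooled mode decodes single units pooled
across sessions on a depth grid restricted to [−18, −6] dB.

## The synthetic-data generator

The generator exists so that every stage is testable without animal
recordings; its defaults are the study conditions the analyses assume.

**Observer.** A Bernoulli observer whose Warn hit probability is the
cumulative Gaussian above (the exact model family the fitter inverts), with
a session false-alarm rate; each Warn trial is preceded by a uniform 3–5
Safe trials. Default width 3 dB, lapse 0.02, false-alarm rate 0.05 — the
false-alarm regime of well-trained animals (grand-average FA rates of
about 0.05) and threshold around −12 dB, mid-range for trained observers.

**Units.** Spike trains are inhomogeneous Poisson with rate

r(t) = R * max(0, 1 + g * m * (c0 + sin(2 pi f t))),

R the baseline scaled per trial by a lognormal factor (CV
`rate_noise_cv`), g the depth coupling, and c0 (`dc_gain`, default 0.15)
the fraction of the coupling expressed as a sustained rate increase. The
two terms implement the dual code of AM-responsive cortex: envelope-locked
firing (further concentrated by rate-compensated von-Mises thinning with
concentration `kappa * m`) and a cycle-averaged rate that grows smoothly
with depth — a pure zero-mean sinusoidal modulation would leave the total
spike count distribution independent of depth, contradicting the observed
growth of firing rate with modulation depth and leaving a rate-based d'
with nothing to measure. Half-wave rectification at zero adds further rate
growth once `g*m > 1` and is flagged per unit. Population defaults
(baseline 10–40 Hz, gain 1–6, kappa 0–4, CV 0.05–0.25, half single units)
are calibrated so that AM-responsive simulated single units have
neurometric thresholds averaging roughly −8 to −12 dB with a spread down to
about −16 dB — the threshold regime reported for AM-responsive cortical
units — rather than a uniformly super-sensitive population.

**Coupling.** `simulate_experiment()` draws a latent session sensitivity
that scales the population's gains and (inversely, with noise) sets the
observer's midpoint, so behavioral and neural thresholds co-vary across
sessions by construction. This is the positive control for the
behavior–neural correlation analysis, not a claim about mechanism.

**What the generator does not emulate:** noise correlations between units
(units are conditionally independent; a correlated-noise extension would
be a config addition, not a claim about data), non-Poisson spiking
statistics, adaptation within or across trials, session-to-session
motivational drift, and reaction-time structure. Passing tests therefore
certify the analysis chain under these idealised conditions; they do not
certify robustness to correlated noise or non-stationarity in real
recordings.

## Numerical conventions and edge cases

* Rate clipping bounds every d' at ±3.2897; clipped extremes are exact
  fractions, so equality tests against `2*qnorm(0.95)` are meaningful.
* Thresholds are never extrapolated beyond 0 dB; "unattained" is an
  explicit flagged state at every stage. When a fitted function sits above
  d' = 1 across the entire tested range, the function never *crosses* the
  criterion and the threshold is likewise flagged rather than invented; in
  range-censored comparisons such results are treated as at-or-below the
  deepest tested depth.
* The logistic inversion and the psychometric inversion are closed-form and
  are tested against bisection and grid-search oracles.
* Reproducibility: every stochastic routine takes a seed; sub-seeds are
  derived arithmetically (kept below 2^31) per stage, per unit, and per
  depth, so artifacts regenerate bit-identically from a config and master
  seed, and per-depth decoder results are order-independent.
* Problem sizes used by the test suite (100 observers at 100 trials/depth
  for psychometric recovery; 50 units on a gain grid; 10^4 Rayleigh nulls;
  50 populations of 30 units, 8 trials, 500 decoder iterations for the
  population-vs-unit comparison) were chosen as the smallest scales at
  which the Monte-Carlo statements they verify are stable.

## Known limitations

* The MAP psychometric fit reports no posterior width; uncertainty on
  thresholds must come from resampling if needed.
* The 4-parameter logistic on 4–6 depth points is intentionally faithful to
  the source procedure but is weakly constrained; single-unit threshold
  estimates from 8 trials per stimulus are noisy, and extreme-value
  statistics over many units (e.g. "the best unit") inherit a winner's-curse
  bias. The population-vs-unit comparison censors thresholds at the tested
  range edge partly for this reason.
* The linear SVM with 14 training vectors in N dimensions is far from the
  ideal observer for large N; decoder d' understates the information in the
  population, which is the same conservatism the source procedure carries.

## A worked example

```{r example, eval = FALSE}
library(amdetect)

stim <- stimulus_spec(depths_db = seq(-18, -6, by = 3))
obs <- observer_params(threshold_db = -12)
pop <- population_params(n_units = 30)

sess <- simulate_population_session(pop, obs, stim,
                                    n_trials_per_stim = 8, seed = 1)

fit <- fit_psychometric(sess$trials)
glance(fit)

tt <- data.frame(trial_id = sess$trials$trial_index,
                 stimulus = ifelse(is.na(sess$trials$depth_db), "safe",
                                   sprintf("%.10g", sess$trials$depth_db)))
units <- neurometrics(sess$spikes, trial_table = tt)

resp <- build_response_vectors(sess$spikes, min_trials = 8,
                               trial_table = tt)
decoder <- decoder_neurometric(resp, decoder_config(seed = 1))
glance(decoder)
autoplot(decoder)
```
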