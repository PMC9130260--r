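# amdetect

Behavioral and neural analysis of amplitude-modulation (AM) depth detection.

## What problem this solves, and for whom

In Go/Nogo AM detection experiments, an animal drinks during continuous
broadband noise (Safe trials) and withdraws when the noise becomes
sinusoidally modulated at 5 Hz (Warn trials) at some depth `m`, expressed in
dB re: 100% (`depth_db = 20·log10(m)`, 0 dB = full modulation). Laboratories
running such experiments — and anyone relating psychophysics to cortical
single-unit and population recordings — need one consistent chain from raw
trial logs and spike tables to detection thresholds:

* **Signal detection**: `d' = z(hit rate) − z(false-alarm rate)`, with rates
  clipped to [0.05, 0.95] so |d'| ≤ 2·z(0.95) = 3.2897; 5-trial sliding
  windows over training; warn trials to the d' ≥ 1.5 criterion.
* **Psychometric functions**: MAP cumulative-Gaussian fits of hit rate vs
  depth, `p(x) = γ + (1−γ−λ)·Φ((x−m)/σ)`, with γ pinned to the session
  false-alarm rate; the detection threshold is the depth where the fitted,
  clipped curve crosses **d' = 1**; learning curves as OLS
  `threshold ~ log10(day) + group` (ANCOVA-style).
* **Neurometrics per unit**: firing-rate d' per depth
  (`d'_FR = z(depth) − z(unmodulated)`, pooled-SD normalised), 4-parameter
  logistic fits, AM-responsivity (significant fit **and** max d' ≥ 1),
  thresholds at d' = 1, vector strength `VS = |Σ e^{iθ}|/n` with the Rayleigh
  test `Z = n·VS²` at p < 0.001.
* **Population decoder**: spike-count response vectors, 8 trials subsampled
  per unit and class, leave-one-out linear SVM over 500 iterations, hit/FA →
  d' → logistic fit → threshold; within-session (≥ 10 units, ≥ 8
  trials/depth) and pooled pseudo-population (depths −18…−6 dB) modes.
* **A synthetic-data generator** (Bernoulli observer over the exact
  psychometric family; inhomogeneous Poisson spike trains with sinusoidal
  5 Hz rate modulation, graded depth-to-rate coupling and tunable phase
  locking) so the full pipeline runs and is tested without any recordings.

Everything takes plain data frames (tibbles) and returns tibbles or small
fitted objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(amdetect)

stim <- stimulus_spec(depths_db = seq(-18, -6, by = 3))   # 5 Hz, 1 s window
obs  <- observer_params(threshold_db = -12)
pop  <- population_params(n_units = 30)

sess <- simulate_population_session(pop, obs, stim,
                                    n_trials_per_stim = 8, seed = 1)

fit <- fit_psychometric(sess$trials)
fit
#> Psychometric fit (cumulative Gaussian, MAP)
#>   midpoint m: -11.61 dB, width sigma: 2.22 dB
#>   lapse: 0.000, guess (= session FA rate): 0.082
#>   threshold at d' = 1: -12.84 dB re: 100%
```

The generating observer had its midpoint at −12 dB; from 40 warn trials the
fit recovers the midpoint within half a dB and places the d' = 1 detection
threshold at −12.8 dB.

```r
tt <- data.frame(trial_id = sess$trials$trial_index,
                 stimulus = ifelse(is.na(sess$trials$depth_db), "safe",
                                   sprintf("%.10g", sess$trials$depth_db)))
units <- neurometrics(sess$spikes, trial_table = tt)
#> responsive units: 25 of 30; median attained threshold: -12.04 dB

resp    <- build_response_vectors(sess$spikes, min_trials = 8, trial_table = tt)
decoder <- decoder_neurometric(resp, decoder_config(seed = 1))
decoder
#> Population decoder result (30 units, 500 iterations/depth)
#>  depth_db hit_rate fa_rate n_completed n_skipped   dprime
#>       -18    0.716   0.228         500         0 1.316449
#>       -15    0.856   0.086         500         0 2.428325
#>       -12    0.994   0.000         500         0 3.289707
#>        -9    1.000   0.000         500         0 3.289707
#>        -6    1.000   0.000         500         0 3.289707
#>   threshold at d' = 1: unattained
```

25 of 30 simulated units pass the AM-responsivity criteria with a median
neural threshold of −12 dB, while the 30-unit population readout is above
d' = 1 at every tested depth — its threshold lies at or below the −18 dB
edge of the tested range, i.e. the population decodes depths the typical
single unit cannot, mirroring the pooled-population result the analysis is
designed to expose. `autoplot(decoder)`, `autoplot(fit)` and
`tidy()`/`glance()` give figures and tidy summaries of each object.

`run_full_pipeline(read_run_config("config.yaml"), "out/")` chains
simulate → behavior → neurometrics → decode → report, writing CSV/JSON
artifacts, a link table of behavioral vs neural thresholds with Pearson
correlations, and `report.md`; identical config + seed regenerates every
artifact byte-for-byte. A thin CLI over the same functions is in
`inst/scripts/amdetect.R`.

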