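# breathradar

Non-contact respiration sensing from a 60 GHz FMCW radar, for signal-
processing and machine-learning researchers working on radar vital-sign
estimation. The package implements the full chain from raw radar frame
cubes to a per-user-adaptable breathing-waveform estimate:

* a physics-based **synthetic scene simulator** (breathing chest, static
  clutter, motion bursts, quantized reference belt) that stands in for the
  private recording campaign the method was developed on;
* **range-FFT preprocessing** with dynamic range-bin tracking, moving-target-
  indication (MTI) clutter removal, phase extraction and unwrapping;
* a **cascaded biquad band-pass** respiration filter (Q = 2) and two
  central-frequency labeling procedures;
* **autocorrelation-based motion-corruption detection** producing per-session
  weights `tau = 1 - gamma`;
* a **frequency-constrained convolutional variational autoencoder** (C-VAE)
  mapping the radar phase `x` to the belt reference `x_belt`, trained with

  `L* = tau * BCE(x_hat, x_belt) + KL[N(mu, sigma) || N(0,1)] + gamma * K * (y - y_hat)^2`,

  `K = 1000`, where `y` is the belt-derived central breathing frequency and
  `y_hat` its regression from the latent code;
* **episodic meta-learning** (second- and first-order MAML, Reptile, and a
  stabilized MAML with multi-step loss, derivative-order annealing and
  cosine-annealed outer rate) for few-shot adaptation to new users, plus the
  corruption-weighted fusion estimator
  `x* = (tau * x_hat + 2 * gamma * biquad(x, y_hat)) / (tau + 2 * gamma)`.

The radar geometry follows the standard FMCW relations
`dr = c / (2 Bw)` and `Rmax = (dr / 2) * ns`; chest micro-motion is read
from the phase of the selected range cell, `phi = 4 * pi * R / lambda`.

## Worked example

```r
library(breathradar)

cfg <- radar_config()
cfg
#> <radar_config>
#>   f0: 60 GHz, Bw: 4 GHz, tc: 150 us, Fs: 2 MHz
#>   Tx/Rx: 1/3, chirps/frame: 2, samples/chirp: 200, frame rate: 20 Hz
#>   range resolution: 0.0375 m, max range: 3.75 m

user <- make_user(seed = 42)
round(c(fc_hz = user$fc_true, breath_mm = 1000 * user$breath_amp,
        range_m = user$base_range), 3)
#>     fc_hz breath_mm   range_m
#>     0.449     9.037     0.366

session <- simulate_session(user, cfg, seed = 7)
session
#> <session_record> user000042 [40cm] 660 frames @ 22 Hz, 30 s

trace <- extract_phase_trace(session, cfg)   # raw cube -> unwrapped phase in [0,1]
fs <- session$frame_rate

label <- belt_fc_reference(session$belt, fs) # training label from the belt
label
#> <fc_label> 0.45 Hz (27 bpm) via belt_spectrum

metrics <- breath_metrics(trace$x, fs, fc = label$fc)
metrics
#> <breath_metrics> 14 peaks, W = 98, mean bpm = 27.01, corruption = 0.112

radar_fc <- belt_fc_reference(trace$x, fs)   # radar-side estimate
round(c(truth = user$fc_true, belt_label = label$fc,
        radar_estimate = radar_fc$fc), 3)
#>          truth     belt_label radar_estimate
#>          0.449          0.450          0.450
```

The user breathes at 0.449 Hz (27 breaths/min) with a 9 mm chest excursion
at 37 cm; the belt label and the fully non-contact radar estimate both land
on 0.450 Hz, and the corruption detector attributes 11% of this session's
windows to the simulated hand motion.

Meta-training and few-shot adaptation run through `prepare_meta_tasks()`,
`train_meta()`, and `adapt_to_user()`; `scaled_meta_experiment()` packages a
complete seeded study (cohort simulation, preprocessing, 60 episodes of
second-order MAML, evaluation, and a 20-trial adaptation experiment) that
runs in about twenty seconds.

A thin command-line front end is installed at `inst/cli/breathradar`
(`simulate`, `label`, `metrics` subcommands) for working with session
containers on disk.

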