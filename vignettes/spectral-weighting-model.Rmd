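---
title: "A Bayesian spectral-weighting model of elevation localisation and its plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian spectral-weighting model of elevation localisation and its plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(soundelev)
library(dplyr)
```

## The scientific problem

Sound-source elevation in the median plane cannot be read from interaural
differences — they vanish there. The only cue is the direction-dependent
spectral filtering of the pinna, described by head-related transfer functions
(HRTFs). Estimating elevation from a single eardrum spectrum is ill-posed:
the received log-spectrum is the sum of an unknown source spectrum X(f) and
an unknown filter H(f; elevation). `soundelev` implements an ideal-observer
account of how listeners nevertheless localise, and of how localisation of
*spectrally impoverished* sounds improves with training:

1. The proximal spectrum S(f) = H(f; true elevation) + X(f) (plus sensory
   noise) is weighted per frequency band by a profile w(f) expressing the
   system's confidence in each band: S'(f) = w(f) * (S(f) - mean(S)).
2. S' is cross-correlated with every stored HRTF template; the rectified
   correlation, raised to a sharpness exponent and normalised, acts as a
   likelihood over candidate elevations.
3. The likelihood is multiplied by a Gaussian prior centred at eye level
   (straight ahead) and the posterior maximum (MAP) is the response.

Perceptual learning is modelled as plasticity of w(f) alone: training with
visual feedback, or mere repeated exposure to consistent weak cues, raises
the weights of informative but initially distrusted bands. Because w(f) is
shared across stimuli and locations, the improvement generalises — the
signature phenomenon the package reproduces.

## The synthetic world

No public HRTF data accompany the behavioural protocol, so `synth_hrtf()`
generates filter sets with the canonical human cue structure:

* a direction-independent **ear-canal resonance**: Gaussian bump in
  log-frequency at 2.5 kHz (quarter-wave resonance of a ~3.5 cm canal),
  15 dB high, 0.30 octaves wide;
* the **pinna notch**, the dominant cue: a 25 dB dip whose centre moves
  linearly at 15 Hz/deg from 7600 Hz (at 0 deg), staying within 5–10 kHz
  across the grid; notch width 0.08 octaves;
* **weak low-band cues** from ~3–3.5 kHz: an elevation-proportional tilt
  (0.05 dB/deg upward, 0.12 dB/deg downward — the curves diverge
  predominantly downward) whose onset frequency itself drifts with elevation,
  plus a 6 dB random field (3.3–5.4 kHz) that is smooth in frequency and in
  elevation and is attenuated to 60% above the horizon. The field supplies
  the idiosyncratic but consistent fine structure real pinnae show in this
  band; without it the low-band cues form a one-parameter family whose
  members correlate perfectly, and no amount of re-weighting could make LP6
  sounds localisable;
* an **erratic high band** above 10 kHz: a seeded random Fourier field,
  independent across elevations, 22 dB in amplitude.

The constructor enforces the structural invariants (resonance
direction-independence, strict monotonicity of the interpolated notch centre,
mutual uniqueness of all rows at pairwise correlation < 0.99 over the
analysis band), so every generated world supports unambiguous template
matching.

```{r hrtf, fig.height = 3.5}
h <- synth_hrtf()
autoplot(h)
```

## The observer and its noise model

`observer()` bundles the stored templates (by default the listener's own
true filters), the weighting profile, the prior and three numbers that
matter:

* `sigma_prior = 30` deg — width of the Gaussian prior on elevation. It
  produces the response-gain shrinkage g = 1/(1 + sigma_eps^2/sigma_p^2)
  whose closed form `closed_form_gain_var()` implements and which the
  Monte-Carlo simulator `simulate_map_trials()` verifies numerically.
* `sensory_noise_sd = 3` dB — acoustic noise per band, *level-dependent*:
  for a band attenuated by X dB the noise sd scales as 10^(-X/40). Internal
  noise has roughly fixed linear amplitude, so its dB-domain footprint grows
  as a band's level falls towards threshold; the compressive exponent
  follows the near-miss-to-Weber growth of intensity discrimination at low
  sensation level. This is what makes a 25–35 dB band-stop attenuation
  destroy the notch cues it covers while a 15 dB attenuation only degrades
  them.
* `internal_noise_sd = 2` dB — comparison noise added *after* weighting.
  This term is load-bearing: Pearson correlation is scale-invariant, so
  without post-weighting noise a uniformly down-weighted band costs nothing
  and weight learning could not change behaviour. With it, w(f) sets each
  band's signal-to-internal-noise ratio, and raising the weight of an
  informative band genuinely improves the likelihood.

Template comparison runs over the 3.5–14 kHz analysis band, restricted to
the bands the input actually defines: bands more than 20 dB below the
stimulus peak (the out-of-band floor of LP6, the 6–9 kHz trough of BS25 and
BS35) are excluded. This single audibility rule reproduces the otherwise puzzling
equality of BS25 and BS35 performance — both lose the entire notch band —
while BS15 retains a noisy notch and sits between them and broadband noise.

The likelihood sharpness exponent is `beta = 10`. The rectification of the
correlation function is principled (only positive correlations can indicate
the source), but no unique mapping from a correlation to a likelihood
magnitude exists; we use max(C, 0)^beta and calibrated beta, together with
the two noise levels, so that the simulated 275-trial control experiment
reproduces the benchmark ordinal pattern of elevation gains
(GWN > BS15 > {BS25 ~ BS35} > LP6) with the low-pass stimulus showing the
largest positive (upward) response bias. That upward LP6 bias emerges from
the model rather than being built in: upward-elevation templates carry
little variance in the sub-6 kHz window, so a noisy, nearly featureless
weighted spectrum correlates best with them, and the MAP lands above the
horizon.

```{r control}
fits <- bind_rows(lapply(1:4, function(s) {
  L <- simulate_listener(s, master_seed = 1)
  fit_responses(simulate_test_session(L$observer, "control",
                                      seed = derive_seed(1, s, "control")),
                "elevation")
}))
fits |> group_by(stim_kind) |> summarise(gain = mean(gain), bias = mean(bias))
```

## The naive weighting profile

`default_weight_profile()` peaks at 7.5 kHz (the notch band is trusted
most), falls off steeply below (width 0.18 octaves, floor 0.10 — the weak
low-frequency cues start heavily discounted) and more gently above (width
0.3 octaves — modest naive trust in the high band). The asymmetry encodes
the starting point of the learning story: everything the training can teach
is already audible, just under-weighted.

## Weight learning

The training paradigm presents 432 trials at six midsagittal elevations
(+60, +40, +20, −10, −30, −50 deg; 72 each in pseudo-random shuffled blocks
with no elevation more than twice in a row). Two update rules share one
machinery and differ only in the teaching signal:

* `update_weights_feedback()` — the visually revealed true elevation
  (Experiment 1, band-stop training);
* `update_weights_exposure()` — the mode of the trial's own sensory
  likelihood, scaled by the trial's confidence (its peak posterior mass), so
  that only evidence-bearing trials teach (Experiment 2, feedback-free
  exposure to low-pass noise). Trials whose likelihood fell back to uniform
  carry no signal and produce no update. Because the internal teacher is
  noisier than an external light, exposure learning is slower and weaker
  than feedback learning at the same learning rate — the expected ordering
  (feedback > exposure > none) follows from teacher quality rather than
  from separate tuning.

Four numerical choices deserve explanation, because the naive formulation
fails quietly:

1. **Smooth surrogate.** The MAP argmax on a discrete template grid is
   piecewise constant in the weights, so a finite-difference gradient of the
   squared MAP error is zero almost everywhere. The gradient is therefore
   taken on the *posterior mean*, which moves smoothly with the weights; the
   recorded behavioural response remains the MAP estimate.
2. **Common random numbers.** One internal-noise draw is shared between the
   unperturbed estimator and all per-band perturbed re-runs (perturbation
   0.01), so trial-averaged steps follow the gradient of the *expected*
   loss under the internal noise. Without this the rule over-boosts bands
   whose marginal contribution is noise-dominated, and listeners who start
   out accurate are made worse.
3. **Normalised steps.** The descent direction is rescaled to a fixed
   per-trial norm (`learning_rate`, 0.03 for feedback, 0.05 for exposure,
   in weight units). This bounds the per-trial weight change by
   construction; noise-driven directions cancel over the session while
   consistently informative bands accumulate.
4. **Consolidation.** The session integrates directions with an exponential
   moving average (`momentum = 0.95`, a ~20-trial memory) before stepping.
   For listeners whose cues are weak the raw per-trial direction is mostly
   noise; without consolidation their weights random-walk to the bounds
   instead of converging. The exported one-trial update rules correspond to
   `momentum = 0`.

Weights are clipped to [0, 1] after every step, and a session never aborts:
degenerate trials are recorded and skipped.

```{r training, fig.height = 3}
L <- simulate_listener(1, master_seed = 7)
tr <- simulate_training_session(L$observer,
                                learning_config("feedback_delta", seed = 11))
plot_learning_curve(windowed_regression(tr$trials))
```

## Protocols, analysis and statistics

`simulate_test_session()` implements the study protocols exactly:
135 trials (45 each of LP6/BS35/BS25) over azimuth [−90, 90] x elevation
[−55, 85] deg for Experiment 1 tests; 116 trials (58 each of GWN and LP6)
over [−50, 50] x [−50, 70] for Experiment 2; 275 trials (55 each of all
five stimuli) over [−20, 20] x [−50, 60] for the control. Targets are drawn
uniformly by rejection inside the double-pole frontal hemifield
(|azimuth| + |elevation| <= 90 deg). Azimuth is treated as a separate,
nearly noiseless binaural channel (responses are target azimuth plus 2 deg
Gaussian noise) purely so the trial tables carry both components.

The analysis layer mirrors the paper's: per-stimulus linear
stimulus-response fits (gain, bias, Pearson r and r^2, the mean absolute
residual error around the fit and the mean absolute localisation error),
windowed regression (50-trial windows advanced by 5 trials, anchored at
trial 1, giving 77 windows in a 432-trial session), and a one-sided exact
sign test. Improvements are counted strictly (ties count against) over the
four measures gain-up, r^2-up, |bias|-down, MAE-down across the nine
listeners, i.e. 36 values per stimulus. The binomial tail is computed from
an exactly built Pascal row; note that the exact tail at 29/36 is 1.56e-4
and at 24/36 is 0.033, so thresholds quoted from normal approximations
differ from the exact test implemented here — 26/36 is the smallest count
with p < 0.01.

Simulated cohorts (9 listeners for the feedback experiment, 3 for the
exposure experiment) draw their HRTF parameters, prior width and noise
levels with ±20% uniform jitter per listener (the notch centre only ±4%, or
it would leave the 5–10 kHz band at extreme elevations), all derived
deterministically from one master seed via `derive_seed()`.

## What the simulations do and do not show

The generator emulates the *structure* of real spectral cues, not any
individual's ears: absolute gains, notch trajectories and the weak-cue
field are qualitative stand-ins with figure-level realism only, and the behavioural targets are ordinal patterns and
sign-test outcomes, not subject-level numbers (which would summarise
non-public human data). Passing simulations therefore show that the
weighting-plus-prior mechanism *suffices* to produce the phenomena —
control-stimulus ordering, within-session learning, cross-stimulus and
cross-location generalisation, weaker feedback-free learning with
downward-dominant expansion, broadband immunity — not that human listeners
implement exactly this rule.

Cohort-level outcomes at the protocol's own sample sizes are genuinely
noisy: a 45-trial test fit has a gain standard error near 0.1, and a
3-listener exposure cohort's session trajectory is dominated by sampling.
The package's checks therefore use the cohort statistics the protocols
support (sign tests pooled over 36 values; session-level qualitative
effects pooled over replicate cohorts where a single cohort would be a coin
flip), with simulation sizes chosen to keep a full verification run in the
low minutes.

Known limitations: reaction times are represented only by the posterior-peak
confidence proxy; template mismatch (stored filters differing from the true
ones) is expressible but unexplored; the exposure rule can, for individual
weak-cue listeners, consolidate an upward-biased self-consistent solution —
a real failure mode of self-training that a 3-listener design
cannot rule out either.
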