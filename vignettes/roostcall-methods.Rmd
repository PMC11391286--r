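---
title: "roostcall: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{roostcall: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Corvids wintering in communal roosts call intensely when they arrive at
dusk, fall mostly quiet overnight, and build a crescendo of calling that
culminates in a mass departure around first light. Because these birds use
vocal signalling to reach a collective departure consensus, anthropogenic
noise and light are plausible disruptors of both their rest and their
coordination. `roostcall` implements the full measurement chain needed to
study this: it converts overnight audio into per-second calling-intensity
series, derives the five per-night statistics used as responses in the
analysis (settling slope, overnight calling proportion, pre-departure
slope, departure cohesion, roost-emptying time), quantifies background
noise, segments departure observations into collective groups, and fits the
corresponding linear mixed models. A synthetic soundscape generator with
known ground truth makes every stage testable without field recordings.

## Acoustic processing

**Per-second band power.** Audio is cut into non-overlapping 1 s frames
aligned to the recording start (a partial trailing frame is dropped). Within
each frame the power spectral density is estimated by Welch's method
(256-sample segments, 50% overlap, periodic Hann taper) and integrated over
the analysis band: 1000–3000 Hz for calls, which captures the bulk of
jackdaw call energy while excluding most other sources, and 0–4000 Hz for
background noise. The result is reported in dB (`10·log10`), floored at
−120 dB so silent frames are finite and deterministic. Band-*integrated*
power per second was chosen over a per-bin maximum: integration is the
natural estimate of calling energy, is monotone in band width, and is the
quantity whose white-noise behaviour we can verify against direct
periodogram summation (the two agree within a fraction of a dB; the test
suite enforces < 1 dB).

**Noise reduction.** Field pipelines commonly clean recordings with a GUI
noise-reduction tool; `roostcall` uses a deterministic equivalent: STFT
spectral gating (FFT 1024, hop 512, periodic Hann). Bins whose magnitude
falls at or below a per-bin gate — the mean magnitude spectrum of a
reference segment times a sensitivity multiplier — are attenuated by the
reduction depth (default 6 dB); everything else passes untouched. With a
50% periodic-Hann overlap the analysis windows sum exactly to one, so the
reconstruction is exact wherever no bin is gated; `reduction_db = 0`
returns the input to machine precision. The sensitivity default is 3.0:
STFT magnitudes of stationary noise are approximately Rayleigh, and a gate
at three times the mean magnitude lies above ~99% of the noise *power*, so
a noise-only stretch is attenuated by close to the full 6 dB (the suite
checks 6 ± 1 dB). A gate at twice the mean — a common default in audio
tools — leaves the upper magnitude tail ungated, and that tail carries
roughly 18% of the power, capping the measured reduction near 4 dB; the
higher default is a deliberate calibration so the nominal depth means what
it says. Calls well above the noise floor sit far above the gate and pass
with their band energy intact within 1 dB.

**Trimming and normalization.** Calling recorded before arrival or after
departure (birds in transit) is removed by keeping the span between the
loudest second of the first 2 h and the loudest second of the last 2.5 h,
ties broken earliest for determinism. Each night is then min–max
normalized to [0, 1] (nPSD). The normalization method is a design choice:
the calling thresholds of 0.2 and 0.4 only make sense on a unit scale, and
a per-night min–max absorbs exactly the constant dB offset produced by
recorder placement relative to the birds, which is the stated purpose of
normalizing. A constant series maps to all zeros. Min–max is idempotent and
invariant to adding any constant dB offset, and both properties are tested.

## Per-night statistics

* **Settling slope**: OLS slope of the first hour of nPSD against time,
  reported per hour. Negative means settling; slightly positive slopes
  (nights when the birds do not quieten within the hour) are retained, not
  discarded.
* **Overnight calling proportion**: fraction of seconds with nPSD ≥ 0.2
  (0.4 for the conservative robustness variant) between one hour after the
  trimmed start ("after the birds settled", operationalized as the end of
  the settling window) and 1.5 h before the trimmed end. The proportion is
  non-increasing in the threshold by construction, and the suite verifies
  this through the full pipeline.
* **Pre-departure slope**: OLS slope of the final 1.5 h, per hour.
* **Background noise**: mean jointly-normalized 0–4000 Hz band PSD in the
  hour before arrival, a two-hour overnight window (23:00–01:00 by clock
  when the recording starts at 16:00), and the hour before continuous
  departure calling begins. The noise profile for this measurement is taken
  from a call-heavy stretch around the arrival peak so the birds' own calls
  are gated out of the noise estimate. Because the onset of "continuous
  departure calling" is a judgement call in the field, the pipeline
  substitutes a deterministic surrogate: the first second of the final
  1.5 h whose nPSD stays at or above threshold for 60 consecutive seconds,
  falling back to the window start.

## Departure coding

A group departure is two or more birds leaving in the same compass sector
(8 discrete sectors; video coding cannot resolve finer bearings) within a
10 s window, separated from other departing groups by at least 2 s. The
written rule leaves the window's anchor ambiguous; `roostcall` anchors it
at the cluster's first event *and* requires every consecutive same-direction
gap to be under 2 s, which implements both stated clauses deterministically.
Clusters are built greedily left-to-right per direction; single-bird
clusters are singletons (they count toward emptying time but are not
groups). The segmentation is validated against an independently coded
brute-force oracle on thousands of random event sets, and round-trips
exactly with the event generator whenever planted spreads and gaps respect
the thresholds. Cohesion is the largest group's share of roost size; the
emptying time runs from the first to the last departure event.

## Mixed models

Each response is modelled as a Gaussian linear mixed model with crossed
random intercepts for roost site and month (the design states both without
nesting). All fits used for inference are maximum likelihood, not REML:
single-term-deletion likelihood-ratio tests compare models with different
fixed-effect structures, which is only valid under ML. Predictors are
centred and scaled to unit SD so coefficients are comparable; the binary
rain indicator is scaled like any other column. The overnight calling
proportion is logit-transformed, with proportions clamped to
[1e-3, 1 − 1e-3] so exact zeros and ones (possible on silent or saturated
synthetic nights) stay finite. For each predictor the report carries the
scaled estimate and SE, the deletion χ², df, p and ΔAIC, and a variance
inflation factor computed from the fixed-effects design via an auxiliary
OLS fit. The five-model suite mirrors the study design: noise in the
matching window is the focal predictor for each response, the three
departure models additionally include overnight calling (on the logit
scale), and roost size, temperature, windspeed and rain enter everywhere.
When light data exist, variants of the first three models add mean light
and drop the most-urban site (the one without a light logger). No
multiple-testing correction is applied across the five models, matching
the original reporting; treat marginal p-values accordingly.

## The synthetic generator

`simulate_night()` draws call times from a three-phase rate function —
linear decay from an arrival peak, homogeneous Poisson calling overnight, a
linear crescendo ending at the departure anchor, silence outside — by
Poisson thinning, then renders band-limited white background noise (plus an
optional < 1 kHz anthropogenic component) and one Hann-enveloped linear
chirp (1.2→2.8 kHz, 0.2–0.5 s) per call. All randomness flows from one
integer seed per call; there is no global state. Defaults describe a
plausible night: arrival 30 min in, an arrival peak of 1800 calls/h
decaying to a 30 calls/h night over about an hour, a 1.5 h crescendo, and a
−45 dB RMS noise floor with calls at −15 dB.

Nominal 16 h nights at 8 kHz are supported but heavy (~4.6·10⁸ samples),
so `compressed_night_scenario()` maps the night onto a shorter timeline:
times scale by `scale`, per-hour rates by `1/scale`, and the two rate
derivatives by `1/scale²`, preserving expected per-phase counts. Call
transients keep their physical duration, so compressed nights are denser
second-by-second than real ones — good for exercising the pipeline, wrong
for studying absolute calling proportions, which is why tests that compare
against planted fractions choose their rates explicitly. The test suite
runs mostly at 1/120 and 1/240 of real time (8 and 4 minute nights); these
sizes are the package's own choice of test geometry, balancing resolution
against run time.

One subtlety the generator exposed: the *measured* pre-departure slope
lives in normalized log-power space, so simply raising the crescendo's
end rate does not raise the measured slope — the log curve saturates early
and the night's own maximum rescales the series. A "steeper consensus" is
therefore generated as the same peak calling intensity reached over a
shorter ramp, which matches the field interpretation (a sharp, late rise
versus a gradual build-up that is already elevated when the regression
window opens) and yields strictly ordered measured slopes on paired nights.

`simulate_season()` is the generative counterpart of the mixed models:
covariates drawn from uniform ranges, responses built from scaled linear
predictors plus site and month random intercepts plus Gaussian residuals,
proportions formed on the logit scale and back-transformed. Its defaults
(five sites, 24 nights each, effect 0.4 on the logit scale, site SD 0.3,
month SD 0.2, residual SD 0.5) put the planted effect at the magnitude the
pipeline is designed to recover, with an estimator SE near 0.05 at 120
nights. What passing recovery and calibration tests show is that the
*pipeline* is unbiased and correctly calibrated under its own generative
assumptions — Gaussian residuals, uniform covariates, crossed intercepts;
they do not certify the field data's error structure, spatial
autocorrelation, or observer effects.

## Numerical conventions

dB floor −120 for zero power; argmax ties broken to the earliest second;
1 s frames aligned to the recording start with the partial trailing frame
dropped; constant series normalize to all zeros; proportions clamped at
1e-3 before logit; lme4 singular fits (a variance estimated at zero) are
recorded but treated as legitimate; non-convergence warnings flag the
report rather than aborting. Test and acceptance problem sizes: 100
simulated seasons of 120 nights for effect recovery, 200 seasons for null
calibration, 50 compressed nights for threshold monotonicity, 300–800
random event sets against the brute-force oracle.

## Known limitations

Synthetic calls are deterministic chirps, not jackdaw vocalizations; there
is no spatial acoustics, no multi-microphone selection step, and no
modelling of wind or rain on the recordings. The departure-onset heuristic
and the "settled" boundary are deterministic surrogates for field
judgements. The exact parameter set of GUI noise-reduction tools is not
recoverable, so the gating here is an approximation calibrated to deliver
its nominal attenuation depth. Reproducing field regression coefficients
requires the field recordings themselves; the package validates structure,
signs and calibration, not those numbers.
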