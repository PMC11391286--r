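# roostcall

Acoustic and collective-behaviour analysis of corvid winter roosts.

Corvids such as jackdaws (*Corvus monedula*) roost communally in winter:
they arrive calling at dusk, quieten as they settle, call sparsely through
the night, and build a crescendo of calling that triggers a coordinated
mass departure at dawn. Because vocal signalling underpins this collective
decision, overnight noise and light pollution are candidate disruptors of
both the birds' rest and their coordination. `roostcall` is for
behavioural ecologists and bioacousticians who want to run this analysis
chain end to end — from overnight WAV recordings and video-coded departure
tables to fitted mixed models — or to validate such a pipeline against
synthetic data with known ground truth.

## What it computes

For each roost-night the waveform is noise-reduced by STFT spectral gating
(6 dB depth against a quiet-period noise profile), summarized as
band-integrated power spectral density per second over 1000–3000 Hz (the
call band), trimmed to the occupancy period (loudest second of the first
2 h through loudest second of the last 2.5 h), and min–max normalized to
[0, 1] per night (nPSD). From the nPSD series come the per-night responses:

- **settling slope** — OLS slope of the first hour, in normalized
  dB Hz⁻¹ h⁻¹ (negative = settling);
- **overnight calling proportion** — fraction of seconds with nPSD ≥ 0.2
  (0.4 for a conservative variant) between settling and 1.5 h before
  departure;
- **pre-departure slope** — OLS slope of the final 1.5 h;
- background-noise covariates: mean normalized 0–4000 Hz band power before
  arrival, overnight (23:00–01:00), and before departure calling begins.

Video-coded departure events (time, birds, compass sector) are segmented
into **group departures** — two or more birds leaving in the same
direction within a 10 s window, separated by ≥ 2 s from other groups —
yielding departure cohesion (largest group as a proportion of roost size)
and roost-emptying time.

Each response *y* is then modelled as a Gaussian linear mixed model

    y = Xβ + u_site + u_month + ε,   u ~ N(0, σ²_g),  ε ~ N(0, σ²)

fitted by maximum likelihood, with scaled predictors (so β are comparable
effect sizes), a logit transform for the calling proportion, per-predictor
single-term-deletion likelihood-ratio tests (χ², df, p, ΔAIC) and variance
inflation factors. A synthetic generator produces roost-night audio,
departure streams and whole seasons with planted effects, so recovery and
calibration are testable without field data.

## Worked example

Simulate one compressed-time night (16 h mapped to 8 min), run the full
acoustic pipeline, and segment a small departure table:

```r
library(roostcall)

sc <- compressed_night_scenario(scale = 1 / 120, seed = 42,
                                night_call_rate = 2)
night <- simulate_night(sc)
night$truth$counts
#>      arrival        night predeparture
#>          944           25         2638

cfg <- scale_pipeline_config(pipeline_config(), 1 / 120)
m <- assemble_night_metrics(night$audio,
                            covariates = list(roost_size = 300,
                                              temp_mean = 4.5,
                                              wind_mean = 12, rain = 0),
                            config = cfg)
round(unlist(m[c("settle_slope", "night_call_prop", "predeparture_slope",
                 "noise_prearrival", "noise_overnight")]), 3)
#>       settle_slope    night_call_prop predeparture_slope
#>            -92.706              0.073             21.934
#>   noise_prearrival    noise_overnight
#>              0.487              0.058
```

The settling slope is negative (calling dies down after arrival; the
magnitude is on the compressed timeline), 7.3% of overnight seconds exceed
the calling threshold, and the pre-departure slope is positive — the
crescendo. On the departure side:

```r
ev <- data.frame(time_s = c(0, 1, 2.5, 40, 40.8),
                 n_birds = c(1, 1, 1, 2, 1),
                 direction = c("N", "N", "N", "SW", "SW"))
seg <- segment_group_departures(ev)
departure_summary(seg, roost_size = 92)
#>   largest_group_prop n_groups time_to_empty_s roost_size
#> 1          0.0326087        2            40.8         92
smallest_group_percent(92)
#> [1] 2.17
```

Three birds leaving within 2.5 s northward form one group (3/92 = 3.3% of
the roost); the smallest possible group, two birds, would be 2.17% of this
roost. Finally, a simulated season with a planted overnight-noise effect
of 0.4 on the logit of the calling proportion:

```r
season <- simulate_season(season_truth(), seed = 1)
suite <- run_prediction_suite(season)
suite$reports$night_calling$fit
#> <roost_lmm> night_calling (logit response), n = 120
#>                 estimate     se       t
#> (Intercept)      -1.5118 0.2210 -6.8399
#> noise_overnight   0.4384 0.0483  9.0759
#> roost_size        0.0223 0.0485  0.4584
#> temp_mean        -0.0411 0.0513 -0.8023
#> wind_mean         0.0802 0.0516  1.5535
#> rain              0.0866 0.0505  1.7163
```

The planted effect is recovered (0.44 ± 0.05 against a truth of 0.4); the
deletion test for `noise_overnight` gives χ² = 61.8, df = 1, p < 1e-14,
while the null covariates stay non-significant.

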