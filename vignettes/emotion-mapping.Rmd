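---
title: "Methods: biosignal indexes, normalization and the emotion map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biosignal indexes, normalization and the emotion map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromamap)
```

## The measurement model

`aromamap` evaluates psychological responses to olfactory stimuli on the two
axes of the circumplex model of affect: **arousal**, read from single-channel
frontal EEG, and **valence**, read from pulse-derived heart-rate variability
(HRV). A session consists of a 60 s pre-stimulus resting minute, then seven
exposures — six aromas for 60 s each in randomized order and isovaleric acid
(IVA, the unpleasant odor) for 30 s, always last — each followed by 60 s of
rest. The analysis rests on three assumptions:

1. the resting minute at the very start of the session, unaffected by any
   stimulus, is a valid neutral reference for that participant;
2. stimulus effects appear as *changes* from that reference, so subtracting
   the baseline mean removes stable individual differences;
3. responses may differ between the first and latter half of an exposure
   (habituation), so windows of 30 s (aromas) and 15 s (IVA) must carry
   defined index values — which constrains HRV to ultra-short-term indexes.

## Index definitions

**HRV / valence.** Beats are detected on the PPG as local maxima above an
adaptive threshold (rolling median + 3 × rolling MAD over 2 s) with a 300 ms
refractory period; intervals outside 300–2000 ms are discarded and the
adjacent successive-difference pairs invalidated. Over a window (an interval
belongs to a window if its *second* beat falls inside it — a causal
convention for ultra-short windows):

* `pNN50` = proportion of successive differences with |ΔNN| **strictly**
  greater than 50 ms (the conventional NN50 definition), reported as a
  proportion in [0, 1];
* `RMSSD` = √mean(ΔNN²) in ms. RMSSD supports the statistical analysis only;
  it is never placed on the emotion map.

**EEG / arousal.** The signal is cut into non-overlapping 1 s epochs
(matching the ~1 Hz output cadence of the emulated headset), Hann-windowed,
and a periodogram is integrated over each band's closed range: δ 1–3, θ 4–7,
low-α 8–9, high-α 10–12, low-β 13–17, high-β 18–30, γ 31–50 Hz. From these:

* **Attention−Meditation surrogate.** The headset's native Attention and
  Meditation indexes come from a proprietary algorithm; their only published
  characterization is that Attention emphasizes β and Meditation α. The
  surrogate is therefore the relative power share scaled to 0–100:
  `att = 100·(lowβ+highβ)/T`, `med = 100·(lowα+highα)/T`, `T` = total power
  of all seven bands. The difference is bounded in [−100, 100] with neutral
  point 0. Epochs with `T = 0` are undefined, not zero. All outputs label
  this index a surrogate.
* **MA Hβ/Hα.** `highβ/(highα + ε)` (ε = 1e−12 guards empty denominators),
  smoothed by a 15 s trailing moving average with an expanding prefix, so no
  future samples enter a value. The implemented ratio is the *named* one —
  high-β over high-α, high value = high arousal; the source literature once
  inverts the denominator in prose, which we treat as a slip and flag in the
  function documentation.
* **δ and θ** are the raw per-epoch band powers (unitless magnitudes,
  meaningful as relative quantities). γ is computed but excluded from
  default analyses because of muscle-artifact contamination.

## Normalization and statistics

Per participant and index, `Bavg` is the mean over the defined baseline
samples and every exposure sample is normalized as `EX = Exi − Bavg`. For
the HRV indexes — which are per-window scalars, not 1 Hz streams — the
baseline value is the index computed over the resting minute itself.
Windows are half-open on the 1 Hz grid (`[onset, mid)`, `[mid, end)`), so
the midpoint sample belongs to the latter half and nothing is double
counted. A window summary is declared undefined when more than 50% of its
samples are undefined (configurable).

Per group (male/female × 20s–30s/40s–50s), index and exposure half, the
normalized changes form a participants × 7 stimuli matrix analyzed by
one-factor within-subject repeated-measures ANOVA (fitted through
`stats::aov` with an `Error(participant)` stratum), reported with the
uncorrected p-value to mirror the original analysis, plus the
Greenhouse–Geisser epsilon and corrected p for transparency. Post hoc
comparisons are paired two-sided t tests on all 21 pairs with **no**
p-value adjustment; rows with missing cells are removed listwise and
counted.

## The emotion map

Points are group means of the **raw** per-window index means (not the
normalized changes — the map's origin construction already anchors at rest):
7 stimuli × 3 windows (all / first half / latter half) = 21 points, drawn
with 7 stimulus colors and circle/triangle/square markers for the three
windows. Axis presets:

| axis | range | origin |
|---|---|---|
| Attention−Meditation | −100 … 100 | 0 (fixed) |
| MA Hβ/Hα | 0 … 2 (extended if data exceed 2) | 1, the β–α parity point of a ratio (our choice; configurable) |
| pNN50 (valence) | 0 … 1 | mean resting pNN50 of the plotted participants |
| δ | data-driven | none drawn |

Quadrants follow strict comparison against the origins (HV right of the
valence origin, HA above the arousal origin; equality is "on_axis"), so
LAHV — low arousal, high valence, the relaxed-pleasant state — is the lower
right quadrant. Valence is plotted on X and arousal on Y throughout.
An extended low-arousal Y-range is available as an alternative axis preset
for ratio maps, with no new computation behind it.

## The synthetic-data generator

Real recordings of this kind are not public, so the generator is first-class
tested code that produces sessions with the statistical structure the
analysis assumes:

* **Inter-beat intervals**: a mean-reverting AR(1) process around
  `mean_ibi_ms` (default 800 ms, φ = 0.9) parameterized so successive
  differences are zero-mean Gaussian with standard deviation `sigma_d` in
  stationarity, clamped to 300–2000 ms. This gives closed-form recovery
  targets: E[RMSSD] → σd and E[pNN50] → 2Φ(−50/σd).
* **PPG**: one Gaussian pulse (width 0.12 s) per beat at 500 Hz — the
  simplest shape with an unambiguous peak, so beat detection can be
  validated by round trip (±20 ms). With the default detector (k = 3) the
  round trip holds for mean intervals of roughly 550–1500 ms; at faster
  rates pulse overlap inflates the rolling MAD and a smaller `k` or narrower
  pulse is needed.
* **EEG**: per band, FFT-masked white noise scaled to unit RMS times the
  band amplitude, at 512 Hz; a pure band-center sinusoid mode exists for
  exact spectral tests. Per-stimulus effects are amplitude multipliers per
  band and a per-stimulus `sigma_d`; rest blocks (and the questionnaire
  gaps, which the analysis never reads) use baseline parameters.
* **Cohorts**: the default composition reproduces the emulated study
  (9/6 male and 10/7 female participants in their 20s/30s, 3/12 male and
  9/6 female in their 40s/50s; 62 total, groups of 15/17/15/15), with
  per-participant randomized aroma order, IVA always last, and optional
  participant-level jitter on `sigma_d`. One root seed is split
  hierarchically (Lehmer mixing) per participant, channel and condition.

Because effect sizes in physical units are not documented for this kind of
experiment, the default `effect_spec()` is a null specification and the
examples inject illustrative effects (e.g. lavender σd = 45 ms vs baseline
25 ms). What the generator does **not** emulate: EEG blink/EMG artifacts,
realistic PPG morphology, respiration coupling, or the sensor's own ~1 Hz
output quantization. Passing tests therefore demonstrate that the pipeline's
*math* is correct and recovers known structure — not that it is robust to
every artifact of real recordings.

## Numerical choices and verification sizes

* Spectral leakage: with 1 s Hann epochs a band edge leaks ~25% of its power
  into the adjacent integer bin. Bands ≥ 3 Hz wide absorb this (filtered
  noise concentrates ≥ 90% in band); the 2-Hz-wide low-α band reaches ~88%
  with noise synthesis, so exact spectral checks for it use the sinusoid
  mode (≥ 96% in band). This is a resolution property of 1 s epochs, not a
  defect of either component.
* The strict `> 50 ms` comparison makes pNN50 robust at the threshold;
  windowed indexes never bridge differences across removed intervals.
* Degenerate statistics are explicit: zero error mean square reports F = 0 /
  p = 1 (no effect) or F = ∞ / p = 0 (zero-noise effect) with a warning;
  fewer than 3 complete participants is an error, not a silent NA.
* Verification sizes, chosen once for desk-scale runs: HRV recovery uses
  100 seeded replicates of 300 s series at σd ∈ {10, 30, 60} ms through the
  full PPG path; the normalization null uses 100 seeded 2-participant
  cohorts through the full signal pipeline (grand-mean change tested at
  |t| < 3); ANOVA calibration uses 500 null 15 × 7 matrices simulated at the
  statistics layer (participant intercept + iid noise), where the type-I
  rate must land in 0.05 ± 0.02.

## Known limitations

* The Attention/Meditation surrogate is a documented stand-in; absolute
  values are not comparable to the proprietary indexes, only the bounded
  scale and the β-vs-α contrast are.
* Ultra-short-window RMSSD is slightly downward-biased (Jensen bias of the
  square root) and the bias grows as windows shrink; it cancels in
  normalized changes only approximately.
* The beat detector is tuned for clean synthetic pulses; real PPG with
  motion artifacts would need a more robust front end.
* With 1 s epochs, δ (1–3 Hz) rests on 1–3 periodogram bins; its per-epoch
  estimates are accordingly noisy, which is why it is treated as a relative,
  smoothed quantity.
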