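---
title: "Closed-loop aversive visual conditioning of walking bees: models and methods"
author: "apisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop aversive visual conditioning of walking bees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisim)
```

## The paradigm

A forager honeybee walks in a 26 cm linear chamber whose two halves carry
independent colored light fields (blue 465 nm, green 525 nm, yellow 590 nm
LEDs) over an electrifiable grid; a row of 26 infrared sensors samples its
position at 16 Hz. Conditioning is *operant and closed-loop*: at each trial
onset the danger light λ+ appears on whichever half the bee occupies, the
safe light λ− (or darkness) on the other half, and in reinforced protocols
10 V / 100 ms pulses at 4 Hz run on the λ+ side from 3 s to 14 s after
onset — 44 scheduled pulses, delivered only while the bee is actually on
the λ+ half. Stimuli last 14 s with 44 s onset-to-onset spacing; a 2 min
dark habituation precedes the first trial. Because the bee's own crossing
terminates punishment, learning is measured simultaneously as place
preference (PI), as experienced punishment (shock counts), and as
anticipatory arousal (speed).

`apisim` encodes the four protocol families exactly as scheduled
(`build_protocol()`), simulates bees through them (`simulate_bee()`,
`simulate_cohort()`), and implements the complete metric pipeline.

## The behavioral model

The synthetic bee is a persistent random walk in one dimension with
reflecting chamber ends, updated every 1/16 s. Its walking direction
$d \in \{-1, +1\}$ flips with probability

$$p_{\text{flip}} = \mathrm{clip}\!\left[(1 - \rho) \;+\;
  g \,\big(U_{\text{behind}} - U_{\text{ahead}}\big),\; 0, 1\right]$$

where $\rho$ is the persistence, $g$ the crossing gain, and
$U_{\text{ahead}}$ the *expressed utility* of the chamber half the bee is
walking toward (the utilities are compared relative to the heading: a bee
walking into the worse half turns more often, one walking toward the
better half commits to the crossing). Each half's utility combines
phototactic drive and learned aversion:

$$U(\lambda, I) \;=\; a(\lambda, I) \;-\; \max\{0,\; V_\lambda - s_\lambda\}$$

* $a(\lambda, I) = A_\lambda\, I/(I + h)$ is the innate attractiveness of
  LED $\lambda$ at intensity $I$ percent, a saturating function with
  half-saturation $h$ and wavelength-dependent gains $A_\lambda$
  (darkness: 0).
* $V_\lambda \in [0, V_{\max}]$ is the acquired place aversion of light
  $\lambda$. Each *delivered* pulse while the bee stands under light
  $\lambda$ updates $V_\lambda \leftarrow V_\lambda + \alpha\,(V_{\max} -
  V_\lambda)$ — learning is tied to experienced punishment, which creates
  the operant contingency: a bee that escapes early learns less but is
  also punished less, so avoidance self-limits at an equilibrium instead
  of saturating.
* $s_\lambda \ge 0$ is the *safety prior*, subtracted before aversion is
  expressed. With $s_G = V_{\max}$, green light accumulates $V_G$
  normally but never expresses it as place avoidance — the model's account
  of the green-light asymmetry: danger is learned (see arousal below) but
  not acted on spatially.

Two further traces shape speed. Per-sample speed is drawn as
$\mathcal{N}(v_0, \sigma_v)$ truncated at zero, then multiplied by

* an **arousal factor** $1 + \kappa \max_\lambda F_\lambda$ over the lit
  LEDs, where the fear trace $F_\lambda \in [0,1]$ grows per delivered
  pulse with its own (much faster) rate $\alpha_F$. A fast separate trace
  is needed because anticipatory speed-up appears within a few trials and
  is of similar size whether the danger light is avoidable (blue/yellow;
  few accumulated pulses) or not (green; many pulses);
* an **escape factor** $f_s$ from the first received pulse of a trial
  until light offset.

Positions are emitted after snapping to the sensor centers (1 cm pitch),
so downstream speed and occupancy estimates face the same discretization
as the real device; pulse delivery itself is decided on the emitted,
quantized position at the scheduled pulse sample, which makes an offline
fictive recount from the written trace reproduce the delivered count
exactly (this equivalence is asserted over a thousand simulated trials in
the test suite).

### Parameters, defaults, rationale

| parameter | default | units | role / why this value |
|---|---|---|---|
| `base_speed_cm_s`, `speed_sd` | 4, 1 | cm/s | matches the 2–5 cm/s walking range of the assay |
| `persistence` ($\rho$) | 0.98 | — | straight runs of ~3 s / 12 cm, the end-to-end shuttling seen in the chamber; lower values make the walk too diffusive to redistribute within a 14 s trial (see the bias note below) |
| `crossing_gain` ($g$) | 0.05 | — | scales taxis; set so innate color preferences bias but do not pin the walk |
| `attractiveness` | $A_B{=}1$, $A_G{=}1.15$, $A_Y{=}0.9$, $h{=}30$ | — | encodes strong phototaxis at 100% vs darkness and the innate ordering green > blue > yellow, with equal-preference crossings in the observed 45–85% intensity range |
| `learning_rate_alpha` ($\alpha$) | 0.002 | per pulse | slow acquisition; with the operant feedback this halves shock exposure over nine trials rather than abolishing it |
| `aversion_max` ($V_{\max}$) | 2 | — | learned avoidance can outweigh phototaxis but remains finite |
| `safety_prior` ($s$) | B 0, G 2, Y 0 | — | green fully protected ($s_G = V_{\max}$): aversion acquired, never expressed |
| `anticipation_rate` ($\alpha_F$) | 0.06 | per pulse | fear saturates within ~2 training trials |
| `anticipation_gain` ($\kappa$) | 0.35 | — | asymptotic ~+35% post-onset speed increase |
| `shock_speed_factor` ($f_s$) | 1.5 | — | shock-triggered speed increase |
| `quantize` | TRUE | — | sensor-grid discretization on by default |

The defaults were fixed once, as the package's study conditions, from the
assay's printed group-level behavior; the simulator's contract is the
qualitative pattern suite in `tests/testthat/test-acceptance.R`, not any
individual-level fidelity.

## The metric pipeline

* **Segmentation** cuts each bee's trace at the logged `light_on` times
  into slices covering [onset − 3 s, onset + 14 s); the focal (bee) side
  is recomputed from the trace position at the onset sample with the same
  rule the controller used (midline counts as left — a documented,
  configurable tie-break applied consistently to PI and shock counting).
* **Preference index.** Occupancy is accumulated per sample (rectangle
  rule at 16 Hz), not by interpolated crossing times; the error is bounded
  by one sample period. The denominator is $t_{\lambda^-} +
  t_{\lambda^+}$, which equals the analyzed stimulus duration when no
  samples are dropped and stays well-defined when some are. The sign
  convention is *positive = away from the bee-side (focal) stimulus*,
  i.e. toward the safe light in training trials; for the intensity
  experiment, `preference_table()` re-orients trial PIs so that positive
  means "toward the test light" (trials that placed the test light on the
  bee side flip sign), and the orientation is exposed as a `sign`
  argument because the raw logs do not dictate it.
* **Shock counts.** Actual = logged pulses. Fictive = scheduled pulse
  times (3 + k/4 s, k = 0..43) at which the position of the nearest
  preceding trace sample lies on the λ+ side — causal and deterministic.
* **Speeds.** `window_speed()` sums absolute inter-sample displacements of
  steps starting inside [t0, t1) and divides by the window length. Pre
  and post windows are the 3 s on either side of onset; ΔSpeed compares
  the first test trial with the first training trial, absolutely and as a
  percentage of the latter.
* **Exclusion.** A bee is discarded from summaries (never from the raw
  data) when its mean full-trial (onset to onset + 14 s) speed over the
  test trials is *strictly* below 2 cm/s; a bee at exactly 2 cm/s is
  retained. The full-trial window is this package's choice of screening
  window and is recorded with the outputs.
* **Summaries** are per (paradigm, protocol, phase, trial) means with
  SEM = sd/√n; single-bee cells carry NA SEM, empty cells are absent
  rather than zero.

## The intensity-preference fit

Per-intensity pooled mean PIs (both reciprocal presentations, both series
directions) are fitted with $y = a + b x / (c + x)$ by
Levenberg–Marquardt least squares (`minpack.lm`) with $c > 0$ enforced,
started from $a = y(0)$, $b = y(x_{\max}) - y(0)$, $c$ = midrange, and
tight convergence tolerances (1e−12 on the objective and parameters;
non-convergence is flagged on the object, never silent). Noiseless data
are recovered to machine precision. The zero-preference intensity is the
closed form $x_0 = -ac/(a+b)$, reported only when $a$ and the asymptote
$a + b$ have opposite signs and the root lies in the tested range — the
"preferred over all tested intensities" outcome otherwise — and is
cross-checked against a numeric root finder to 1e−9 in the tests. Fits are
unweighted by default (per-point SEMs are available in the preference
table for users who want weights). In Monte-Carlo recovery at σ = 0.05
the location parameters are unbiased; the half-saturation $c$ shows the
small positive median bias (≈ 10%) expected of a saturation constant
estimated from 11 noisy points, well inside its sampling spread.

## A known artifact: the focal-side offset, and the null calibration

Because λ+ is always presented on the half the bee already occupies, the
bee starts every trial on the "wrong" side, and vacating it costs a
measurable fraction of the 14 s window. Single-presentation PI therefore
carries an intrinsic *negative* offset even for a stimulus-blind,
non-learning walker — about −0.13 at the default mobility, and no motion
model at realistic speed can push it to zero (a perfectly ballistic
walker still shows ≈ −0.05). The assay's own design acknowledges this:
the intensity experiment presents every stimulus twice, reciprocally, to
cancel starting-position bias, and pooling the reciprocal presentations
removes the offset exactly by symmetry. Consequently:

* unreinforced learning-protocol PIs are near zero only through partial
  cancellation of this offset by innate attraction to the opposite-side
  light (the model reproduces the printed pattern: ≈ 0 when green is the
  safe light, clearly negative when green is the danger light);
* the package's null calibration measures a blind, non-learning cohort
  with the bias-controlled reciprocal design and checks that its pooled
  mean PI is statistically indistinguishable from zero, while the raw
  focal-side offset is separately asserted to be negative and bounded in
  the unit suite.

## What the generator does and does not emulate

Emulated: dark exploratory shuttling; intensity- and
wavelength-dependent phototaxis; the closed-loop side assignment; pulse
delivery contingent on position; shock-triggered speed increase and
escape; trial-wise acquisition of avoidance for shock-paired blue/yellow;
a green safety prior blocking expressed avoidance; rapid, protocol-
independent anticipatory arousal; sensor quantization.

Not emulated: photoreceptor transduction and color perception (the
attractiveness map is a behavioral stand-in, not a spectral model);
flight and vertical movement; fatigue and exhaustion dynamics (slow bees
for exclusion tests are produced by lowering `base_speed_cm_s`, not by a
fatigue process); alarm-pheromone or inter-individual effects;
generalization between similar wavelengths; any individual-level fit to
real trajectories. Passing tests therefore certify the *pipeline* —
scheduling, logging, metric arithmetic, fitting — and the qualitative
group-level phenomenology, not a quantitative model of bee behavior.

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 24–30 bees per
group for pattern checks (matching the assay's 28–36), 112 bees for the
fictive/actual equivalence sweep (≥ 1000 reinforced trials), 16 bees for
the intensity series, 200 Monte-Carlo replicates for fit recovery and
10,000 for the t-test size check — sizes chosen to keep every check
clearly powered while a full run stays in the minutes range. Every
stochastic component takes an explicit seed; per-bee seeds derive from
the cohort seed, so any cohort, trial or single trace can be regenerated
bit-identically.

## Limitations

* Group comparisons use per-bee summaries with t-tests; the repeated-
  measures mixed-model analyses appropriate for trial-level inference on
  real data are out of scope.
* Chamber length and sensor pitch are configurable defaults (26 cm, 1 cm),
  not measured values.
* The six-trial test battery's pseudorandomization is seeded per protocol;
  cohort halves (single-color vs dual-color triplet first) are balanced
  only in expectation unless `single_color_first` is forced.
* The zero-preference intensity is reported without a confidence
  interval; bootstrap over bees is straightforward on the preference
  table if needed.
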