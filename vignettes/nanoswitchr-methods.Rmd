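---
title: "Models and methods behind nanoswitchr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoswitchr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoswitchr)
```

## The sensing principle

A particle-nanoswitch biosensor tethers micrometer-sized particles to a
substrate by a short dsDNA leash. Each particle carries one antibody
fragment (Fab1) and the substrate carries a second (Fab2); when an analyte
molecule bridges the two, a transient *sandwich complex* forms and the
particle's Brownian excursions collapse from a tether-limited disc to a
tight, nearly immobile spot. Because both Fabs dissociate quickly, the
sandwich is reversible and each particle switches back and forth
indefinitely: the number of unbound-to-bound (UTB) switching events per
particle per minute is a continuous, reagent-free readout of analyte
concentration. `nanoswitchr` implements the full numerical pipeline for
this class of sensor — simulation, trajectory readout, calibration, and
performance metrics — so every stage can be validated without laboratory
data.

## The switching model

Each particle is a continuous-time two-state Markov chain. The
unbound-to-bound rate saturates hyperbolically with concentration $C$ (pM):

$$\lambda_{on}(C) = \lambda_{bg} + \lambda_{max}\,\frac{C}{EC50_{kin}+C},$$

and the bound-to-unbound rate is the sandwich dissociation rate
$k_{off}$. Dwell times in each state are exponential; the stationary
unbound fraction is $k_{off}/(\lambda_{on}+k_{off})$ and the long-run UTB
event rate per particle is
$\lambda_{on} k_{off}/(\lambda_{on}+k_{off})$ events/s. A useful
identity: because $\lambda_{on}$ is itself a Möbius function of $C$, the
stationary UTB rate is *exactly* a four-parameter logistic in $C$ with
slope 1 — the count-level dose-response has the same functional form as
the calibration model, with effective midpoint
$EC50_{kin}(k_{off}+\lambda_{bg})/(k_{off}+\lambda_{bg}+\lambda_{max})$.

Default parameters (all overridable through `kinetic_params()`):

| parameter | default | meaning |
|---|---|---|
| `k_off_sw` | 0.1 /s | sandwich lifetime ~10 s, set by the faster-dissociating Fab |
| `lambda_max` | 0.05 /s | per-particle binding rate at analyte saturation |
| `EC50_kin` | 1030 pM | binding-rate half-saturation |
| `lambda_bg` | 2e-4 /s | analyte-independent background switching |
| `D_free`, `D_bound` | 0.3, 0.05 um²/s | wall-hindered mobility of a 1-um sphere, free vs bound |
| `R_free`, `R_bound` | 0.28, 0.03 um | confinement radii (tether geometry vs sandwich) |
| `sigma_loc` | 0.02 um | localization noise per axis |
| `frame_rate` | 30 Hz | camera rate |

The kinetic and geometric defaults are declared modelling choices (the
original instrument's exact values are not public); they are chosen so
that bound and unbound states are separable on the diffusion scale, blank
samples show a small nonzero background, and the count-level dose
response spans the 30–1000 pM working range.

## Particle motion and its readout

`render_trajectory()` integrates overdamped Brownian motion
(Euler–Maruyama) with the state's diffusion coefficient, reflects radial
excursions at the state's confinement radius (multiple folds are handled
for steps larger than the confinement diameter), and adds independent
Gaussian localization noise per recorded frame.

The readout chain mirrors the experimental analysis:

1. `windowed_diffusion()` — apparent diffusion coefficient per sliding
   window, $\hat D = \langle \Delta x^2+\Delta y^2\rangle/(4\Delta t)$,
   50% window overlap. Localization noise adds $\sigma_{loc}^2/\Delta t$
   (0.012 um²/s at defaults); correction is off by default because the
   classification thresholds absorb the constant offset.
2. `classify_states()` — a hysteresis (Schmitt-trigger) classifier with
   thresholds (0.05, 0.15) um²/s and a minimum dwell of 2 windows. With
   the defaults, bound windows sit near 0.02 um²/s (confinement-limited,
   plus noise floor) and unbound windows near 0.21 um²/s, so the dead
   band is crossed only at genuine transitions.
3. `count_utb()` — only unbound→bound transitions are counted (the
   sensor's robust observable: a UTB event is a sharp, unambiguous
   collapse of mobility); events are assigned to half-open 1-min
   intervals by the bound interval's start time.

**Window length.** The window default is 16 frames (~0.53 s at 30 Hz),
not a full second. With a mean bound dwell of 10 s, dwells shorter than
about 2.5 window lengths are undetectable; a 1-s window therefore misses
~13% of events (the exponential dwell mass below ~1.3 s), which fails
the pipeline's own end-to-end target of ≥90% event recovery. At 16
frames the detection floor drops to ~0.8 s: measured on 200 particles ×
10 min at 1 nM, sensitivity is ~93% and precision ~100% (every inferred
event matches a true event within one window). Shorter windows (12
frames) buy little sensitivity and start costing precision because the
per-window $\hat D$ variance grows.

## Experiments, drift and the synthetic world

`sample_schedule()` lays injections on one clock: a flow period (no
records), *n* consecutive 1-min measurement intervals, an optional idle
gap. Raw activity decays multiplicatively over hours —
`drift_factor(t) = (1 - r)^{t/1h}` with `r = 0.05`/h by default —
emulating slow loss of binders; in counts mode the factor scales the
Poisson mean, in trajectories mode it scales the binding rates at the
start of each injection's measurement span (piecewise-constant within an
injection, a deliberate simplification).

`generate_experiment()` supports two fidelities. *Counts mode* draws
per-interval event counts from
$\mathrm{Poisson}(n_{particles}\cdot r(C)\cdot 60\cdot drift(t))$ —
fast enough for full multi-hour schedules at 4000 particles. *Trajectory
mode* simulates every particle's state sequence and x/y track and keeps
the ground-truth event log, which is what the readout chain is scored
against. The two modes agree on mean activity to within a few percent.

Three preset schedules mirror the sensor's benchmark experiments: an
ascending concentration series repeated five times over ~9 h
(`figure3_series`, 0–1000 pM, 1-min flow, 10 intervals), a milk-sample
imprecision study with normalization references at 125 and 506 pM
(`figure4_milk`, 3.5-min flow, 8 intervals), and a blind-quantification
run with five reference concentrations, four blind samples and periodic
normalization pairs (`figure5_blind`). The specific milk/blind
concentrations in the presets are synthetic choices inside the sensor's
125–719 pM working range; they are not measured values. What a green
test on this world establishes is internal consistency of the pipeline —
not the instrument's laboratory figures of merit, which depend on real
cartridge data.

## Calibration

The dose-response model is the four-parameter logistic

$$S = S_{min} + (S_{max}-S_{min})\,\frac{X^n}{EC50^n + X^n},$$

fit by unweighted nonlinear least squares (`nls`, port algorithm) with
starts $S_{min}=\min S$, $S_{max}=\max S$, $EC50$ at the concentration
nearest mid-signal, $n=1$, and bounds $EC50\in[1,10^6]$ pM,
$n\in[0.3,3]$. Zero-concentration points enter at $X=0$ exactly.
Inversion is closed-form; signals outside the plateaus are flagged
(`below_range` / `above_range`) and excluded from summaries, never
clipped.

**Normalization.** Raw activity drifts, so all quantification is done on
a normalized scale: repeated low/high reference samples (125 and 506 pM
in the milk experiments) anchor the scale at 0 and 1, and the anchor
levels are interpolated linearly in time between repeats (constant
beyond the ends). Each anchor series keeps its own timestamps; this
makes strategy-3 quantification exactly invariant to any drift factor
that is linear in time between repeats, and cancels geometric 5–8%/h
drift to well under 2% of concentration. Anchors use interval means
(not single frames) — the less noise in the anchor, the less noise
normalization injects into every sample.

**Three quantification strategies** (`apply_strategy()`): (1) refit the
4PL on the most recent block of five calibrant concentrations,
recalibrating as new blocks complete (~every 4 h); (2) fit once on the
first block; (3) use a fixed curve
($S_{min}=-0.5$, $S_{max}=4$, $EC50=1030$ pM, $n=1$,
`fixed_calibration_curve()`). Calibrant blocks are detected from the
data by time gaps (>45 min starts a new block), and a block is used from
the moment it completes — the "newest block" reading of repeated
recalibration. On noiseless data all three strategies coincide with the
truth to machine precision (the stationary dose-response being exactly
4PL makes this an algebraic identity, a strong internal check).

## Performance metrics

* `cv_c()` — imprecision of repeated 1-min determinations,
  $100\cdot s/\bar x$ with the $n-1$ sample SD (the convention is not
  universal; the choice is declared, and scale-invariance is tested).
* `lod()` — blank + 3σ inverted through the calibration curve; a level
  at or below the bottom plateau is flagged "below curve floor" rather
  than forced to a number.
* `loq_from_profile()` — lowest concentration where mean CV_C crosses
  below a threshold (10% default), interpolated linearly in
  log-concentration because the dose-response spans decades.
* `mard()` — mean absolute relative difference against reference
  concentrations, out-of-range pairs excluded and counted.
* `imprecision_distribution()` — normal and log-normal fits with
  Anderson–Darling goodness-of-fit p-values for the
  estimated-parameters case (Stephens' adjustment and the standard
  p-value polynomial, implemented in-package because no installed
  package provides it; the test's size is verified under the null in
  the suite).

## Numerical choices and edge cases

* Seeds are explicit everywhere; one master seed spawns per-particle
  substreams, and equal seeds give bit-identical output.
* State sequences are validated (contiguous, alternating, positive
  dwells); a truncated final dwell is dropped from distributional
  checks.
* The hysteresis classifier's initial state uses the first window's
  side of the dead-band midpoint; dwell filtering merges sub-minimum
  runs into their neighbours iteratively, shortest first.
* An exact (zero-residual) calibration fit reports NA standard errors
  rather than failing.
* Degenerate inputs error loudly: identical signals cannot be fit,
  anchors with high ≤ low are rejected, constant samples have no
  distribution fit.

## Known limitations

* No fluid-exchange kinetics: concentration changes are instantaneous,
  so the slow post-flush relaxation seen after large concentration drops
  in real experiments is outside the simulator's physics.
* No rebinding, mass transport, multivalent binding, tether
  polydispersity, tracking gaps or stage drift.
* Trajectory-mode drift is piecewise-constant per injection.
* The laboratory headline figures (MARD 8.2%, LoQ 180 pM, imprecision
  9.0 ± 1.6%) depend on real cartridge data and are deliberately not
  reproduced by the synthetic world; matched simulations land in
  plausible ranges (MARD vs truth of a few percent at 4000 particles)
  and the qualitative shapes (imprecision highest at the lowest
  concentration) are asserted in the test suite.
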