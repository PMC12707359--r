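# nanoswitchr

Simulation and quantification pipeline for **reversible particle-nanoswitch
biosensors** (biosensing by particle motion). Micrometer-sized particles,
tethered to a substrate by a short dsDNA leash and functionalized with one
half of a fast-dissociating antibody-fragment pair, transiently form
sandwich complexes when analyte bridges them to the substrate. Each binding
event collapses the particle's confined Brownian motion to a near-immobile
state; because the sandwich dissociates within seconds, particles switch
back and forth continuously, and the rate of **unbound-to-bound (UTB)
events per particle per minute** is a reversible, reagent-free readout of
analyte concentration — suitable for continuous monitoring over many hours.

The package is written for people developing or validating this class of
sensor: it provides the whole numeric chain from single-particle
trajectories to concentration reports, plus a synthetic-data generator so
every stage is testable without laboratory data.

## The model in brief

Each particle is a two-state continuous-time Markov chain with
concentration-dependent binding rate

    lambda_on(C) = lambda_bg + lambda_max * C / (EC50_kin + C)

and dissociation rate `k_off`. The stationary UTB event rate,
`lambda_on * k_off / (lambda_on + k_off)`, is exactly a slope-1 logistic
in `C`. Quantification uses the four-parameter logistic (4PL)
dose-response on a drift-normalized signal scale,

    S(X) = S_min + (S_max - S_min) * X^n / (EC50^n + X^n),

with repeated low/high reference samples anchoring `S = 0` and `S = 1`
over time (cancelling the sensor's ~5%/h multiplicative drift), and three
calibration strategies: repeated refits, a single initial fit, or a fixed
curve (`S_min = -0.5`, `S_max = 4`, `EC50 = 1030` pM, `n = 1`).
Performance metrics include per-sample CV, precision-profile LoQ,
blank + 3σ LoD, MARD against reference values, and normal/log-normal
imprecision-distribution fits with Anderson–Darling tests.

## Worked example

Simulate a 13-hour blind-quantification experiment (4000 tethered
particles, 5%/h drift, reference/normalization/blind/blank injections),
then quantify the blind samples with the fixed calibration curve:

```r
library(nanoswitchr)

e   <- generate_experiment(preset_schedule("figure5_blind"),
                           kinetic_params(), n_particles = 4000,
                           mode = "counts", seed = 7)
res <- apply_strategy(e, strategy = 3)
print(res$estimates[[1]])
#> Sample 8: 169.9 pM (SD 4.3, CV_C 2.5%, n=8)

truth <- vapply(res$estimates, function(x) x$true_conc_pM, numeric(1))
sens  <- vapply(res$estimates, function(x) x$mean, numeric(1))
mard(sens, truth)$mard
#> 3.7   # percent, over 20 blind measurements

lod(-0.38, 0.05, fixed_calibration_curve())$lod_pM
#> 65.7  # pM, from blank + 3 sigma through the curve
```

The first blind sample (true concentration 160 pM) is reported as
169.9 pM with 2.5% imprecision over its eight 1-min intervals; across all
20 blind measurements the mean absolute relative difference from the true
concentrations is 3.7%. A blank whose `signal + 3*sigma` level is −0.23
on the normalized scale corresponds to a 65.7 pM detection limit on the
fixed curve.

A full trajectory-level round trip (simulate tracks → windowed diffusion
→ state calls → UTB counts) is available through
`generate_experiment(..., mode = "trajectories")` and
`readout_experiment()`; with default settings the readout recovers ≥90%
of ground-truth switching events with essentially no false positives.

## Command line

```sh
Rscript inst/cli/nanoswitch.R simulate --schedule figure3_series --seed 1 --out activity.tsv
Rscript inst/cli/nanoswitch.R readout  --traj traj.tsv --edges 60,120,180 --out activity.tsv
Rscript inst/cli/nanoswitch.R quantify --activity activity.tsv --strategy 3 --out conc.tsv
Rscript inst/cli/nanoswitch.R metrics  --conc conc.tsv --out metrics.json
Rscript inst/cli/nanoswitch.R demo     --seed 1
```

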