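# rescuekit

Stochastic eco-evolutionary modelling of **evolutionary rescue in a
fluctuating environment**: will a declining population be saved by a
generalist mutation before it goes extinct?

`rescuekit` is aimed at theoretical population geneticists and modellers of
antimicrobial resistance or population viability. It implements, and
cross-validates against each other:

* an **exact Gillespie simulator** of a two-genotype, density-regulated
  birth–death process (logistic, Gompertz or Richards birth regulation with
  carrying capacity *K*) in an environment alternating between a harsh phase
  (wild-type birth rate *b*<sub>W,H</sub> < *d*<sub>W</sub>: decline) and a
  favourable phase (*b*<sub>W,F</sub> > *d*<sub>W</sub>: growth), with phase
  durations either fixed (periodic) or drawn from a zero-truncated normal
  (quasi-periodic), and mutants arising at birth events with probability *μ*;
* the matching **analytical theory**: master-equation extinction
  probabilities per phase (*p*<sub>0,H</sub>, *p*<sub>0,F</sub>), the
  geometric law of the number *q*<sub>F</sub> of favourable phases before
  extinction, the mean total extinction time *T*<sub>0</sub>, the fixation
  probability *p*<sub>fix</sub>(*t*<sub>0</sub>) of a mutant lineage in the
  time-varying background, rescue probabilities from de novo mutation
  (*p*<sub>r,DN</sub>) and standing genetic variation
  (*p*<sub>r,SGV</sub> = *p*<sub>fix</sub>(0)), and the mean appearance time
  *τ*<sub>af</sub> of the rescuing mutant.

The key control parameter is the environment duration *τ* relative to the
harsh-survival scale *τ*<sub>0,H</sub> ≈ log(*N*\*)/*d*<sub>W</sub>: rescue is
nearly certain for *τ* ≪ *τ*<sub>0,H</sub> and nearly impossible for
*τ* ≫ *τ*<sub>0,H</sub>, and duration stochasticity *shortens* persistence
(and rescue odds) whenever *τ* < *τ*<sub>0,H</sub>.

## A worked example

Baseline conditions: *b*<sub>W,F</sub> = 1, *b*<sub>W,H</sub> = 0,
*d*<sub>W</sub> = *d*<sub>M</sub> = 0.1, *b*<sub>M</sub> = 1, *K* = 100,
*μ* = 10⁻³, so *N*\* = 90 and *τ*<sub>0,H</sub> ≈ 45.

```r
library(rescuekit)

params <- model_params()            # the baseline set above
tau    <- 0.5 * tau0_harsh(params)  # fast-ish fluctuations, tau = 22.5
d      <- duration_dist(tau)        # deterministic durations (sigma = 0)

extinction_prediction(model_params(mu = 0), d)
#> <extinction_prediction>
#>   p0_H = 0.00004   p0_F = 0.00009   omega_F = 0.65762
#>   <q_F> = 7731.3482   tau0_H = 21.640   tau0_F = 10.000
#>   T0 = 347909.940

rescue_prediction(params, d)
#> <rescue_prediction>
#>   Sigma_H = 0   Sigma_F = 0.11639
#>   p_r_SGV = 0.68537  p_r_DN = 0.99882  p_r = 0.99963
#>   q_af_F = 9.0918   t_af = 10.066   tau_af = 396.680
```

Read: without mutants the population would persist ≈ 3.5·10⁵ time units
(≈ 7731 full cycles) before demographic noise kills it — two thirds of those
deaths striking just after a harsh-to-favourable switch — but a de novo
mutant appears and fixes long before that (probability 0.999; the successful
lineage arises on average in the 9th favourable phase, ≈ 10 time units into
it). A single pre-existing mutant alone would rescue with probability 0.685.

Simulation agrees:

```r
ens <- run_ensemble(params, d, n_reps = 1000, seed = 29)
ens
#> <ensemble_summary: 1000 replicates (seed 29)>
#>   P(rescue)        : 1.0000  [0.9963, 1.0000]
#>   E[T0 | extinct]  : NaN  [NaN, NaN]
#>   E[q_F]           : 9.729
#>   E[t_app | rescue]: 423.966  [397.585, 450.347]
```

All 1000 realizations were rescued (so there are no extinction times to
average); the rescuing lineages appeared at 424.0 (SE 13.4), within about
two standard errors of the predicted 396.7.

The per-event trajectory of a single run (for Fig-1-style plots):

```r
set.seed(1)
out <- simulate_realization(params, d, trajectory = TRUE)
head(out$trajectory)   # columns t, N_W, N_M, harsh
```

## Command-line interface

A thin CLI wraps the same functions:

```sh
inst/cli/rescuekit simulate  --tau 22.5 --reps 1000 --seed 1 --out reps.csv
inst/cli/rescuekit analytics --tau 22.5 --sigma 2.25 --out pred.json
inst/cli/rescuekit sweep     --preset fig3b --reps 1000 --seed 42 --out results/
```

Sweep presets (`fig1c`–`fig4b`) reproduce the figure-style experiments —
analytic curves plus simulated points with 95% CIs over log-spaced
*τ*/*τ*<sub>0,H</sub> grids — at 10³ replicates per point by default
(`--reps 10000` restores full scale).

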