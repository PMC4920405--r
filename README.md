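# gutsBayes

Bayesian calibration, uncertainty quantification and probabilistic
prediction for the **General Unified Threshold model of Survival (GUTS)**
— the standard toxicokinetic-toxicodynamic framework for survival of
organisms under time-varying stressor exposure (e.g. pulsed pesticide
exposure of aquatic invertebrates).

Exposure C(t) drives internal damage D(t) through first-order kinetics
(dominant rate constant k_e); an individual with tolerance threshold z
dies with hazard k_k·max(D−z, 0) + h_b; thresholds vary over the
population (lognormal with mean `mn`, s.d. `sd`). Population survival is

    S(t) = ∫ exp[ −k_k ∫₀ᵗ max(D(τ)−z, 0) dτ − h_b t ] f(z) dz,

and interval death counts are multinomial in the survival increments.
The package implements the three standard flavours — GUTS Proper, GUTS-SD
(shared threshold), GUTS-IT (instant death at first crossing) — with a
fast O(N)+O(M) C++ engine: exact closed-form damage for piecewise-linear
exposure, a deterministic log-uniform importance grid over thresholds,
and a suffix-sum recursion over threshold bins. On top of the engine sit
the multinomial log-likelihood, bounded Hooke–Jeeves MAP search, a robust
adaptive Metropolis sampler, posterior summaries and posterior-predictive
death-count tables. Slow independent reference implementations
(2-D quadrature, naive double sum, an individual-level simulator) ship in
the package for verification and synthetic-data studies.

Who it is for: ecotoxicologists and modellers calibrating survival models
to pulsed-exposure assay data, and anyone needing threshold-hazard
survival inference under a dynamic stressor.

## Worked example

The package ships the diazinon dataset: three pulsed-exposure experiments
on *Gammarus pulex*, 70 individuals each, daily survivor counts over 22
days (`loadDiazinon()`).

```r
library(gutsBayes)
exps <- loadDiazinon()

# total log-likelihood at a reference parameter vector
totalLogLikelihood(exps, c(hb = 0.05473022, ke = 0.09215698,
  kk = 1.80652237, mn = 15.63446045, sd = 6.01160431))$value
#> [1] -570.6043

# MAP, then 50k adaptive-Metropolis iterations (about 2 min)
map  <- findMAP(experiments = exps)
post <- runMCMC(map$par, exps, seed = 1)
summarisePosterior(post)
#>        maxpost     q0.025        q0.5      q0.975
#> hb  0.05475618 0.04541870  0.05700957  0.06984258
#> ke  0.09258041 0.04266109  0.10614508  0.19020254
#> kk  1.82189080 0.87372980  3.43777920 18.15609649
#> mn 15.71686554 9.00336551 18.56889951 28.96471609
#> sd  6.03049365 2.99228718  6.92158475 12.68946293
```

Reading: background mortality ≈ 0.057/day; damage tracks exposure with
rate ≈ 0.11/day; the median tolerance threshold is ≈ 18 nmol/l with
population spread ≈ 7 nmol/l; the killing-rate posterior is fat-tailed
(its 97.5% quantile sits an order of magnitude above the median), so the
data cannot sharply separate the Proper model from its
individual-tolerance limit.

Posterior-predictive death counts for a new exposure scenario:

```r
scen <- gutsExperiment(
  conc     = c(99.97824, 0, 103.88, 0, 0, 103.56, 0, 0, 100.58, 96.51,
               0, 2.35724),
  concTime = c(0, 1.03, 3.01, 4.02, 8, 8.01, 15, 16, 16.01, 17, 18.01,
               22.01),
  counts   = c(100, rep(0, 22)),   # n0 = 100, later counts unused
  countTime = 0:22)
head(predictDeaths(scen, post, seed = 1))
#>   ytd q0.025 q0.5 q0.975
#> 1   1      1    5     11
#> 2   2      2    5     10
#> 3   3      8   19     31
#> 4   4     19   31     44
#> 5   5      0    3      8
#> 6   6      0    2      5
```

A command-line wrapper for the same workflow (subcommands `loglik`,
`fit`, `predict`, `simulate`) lives at
`system.file("scripts", "guts.R", package = "gutsBayes")`.

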