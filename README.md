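# seedshadow

Hierarchical Bayesian inverse modelling of seed dispersal and fecundity
from seed-trap counts in mapped forest stands, with disturbance-regime
comparisons.

## The problem

Tropical seed-rain studies deploy small litter traps inside mapped
plots and count arriving seeds by species and year. The trees of the
stand are the sources; the traps are point detectors. Working backwards
from counts to processes requires a joint model of *how far seeds move*
and *how many seeds each tree makes* — two quantities that trade off
against each other and are only identified through the spatial
arrangement of trees and traps. `seedshadow` implements that inversion
for stands under contrasting disturbance histories (protected,
selectively logged, hunted and logged), for users who want to ask
whether decades-old disturbance still shapes dispersal or fecundity.

## The model

Seed density at distance `r` from a parent follows the single-parameter
2Dt kernel

    S(r; u) = 1 / (pi * u * (1 + r^2/u)^2),

with scale `u` (m^2) fitted per species and regime and reported as the
kernel mean distance `(pi/2) * sqrt(u)` (m). Tree fecundity is
`f = rho * psi`: a probit-in-size maturation status times a log-linear
conditional fecundity with diameter and regime fixed effects, per-tree
random intercepts and year-by-regime effects. Trap counts are
conditionally Poisson with intensity `A * sum_i S_si * f_i`
(effort `A` = trap area x season fraction), and marginally
overdispersed through the random effects. Inference is
Metropolis-within-Gibbs over the latent states and parameters
(`run_chain()`), with DIC and RMSPE for model assessment and
split-chain R-hat / ESS diagnostics. A forward simulator
(`simulate_dataset()`) generates stands, trap layouts and seed rain
with retained ground truth for recovery studies. Posterior analysis
(`classify_overlap()`, `group_mean_dispersal()`, `effect_sign_table()`)
reproduces the reporting conventions of the field: 95 % credible
intervals, interval-overlap classification of disturbance effects, and
group means by dispersal vector and regime.

See `vignettes/seed-shadow-methods.Rmd` for the full model, sampler and
design notes.

## Worked example

```r
library(seedshadow)

set.seed(4)
sim <- simulate_dataset(regimes = "protected", n_plots_per_regime = 1)
fit <- run_chain(sim$trees, sim$traps, sim$counts,
                 config = sampler_config(n_iter = 5000, burn_in = 1000,
                                         thin = 4, rng_seed = 1))
summarize_posterior(fit)$dispersal
#>   species    regime   mean_m ci_lo_m  ci_hi_m
#> 1     SP1 protected 30.08182 23.4803 37.30663
```

One 1-ha stand (155 stems/ha, seven of them the focal species), 21
traps, three years, 150 trapped seeds, true mean dispersal 30 m: the
fitted posterior mean distance is 30.1 m with a 95 % interval of
23.5–37.3 m that covers the generating value. The packaged reference
tables run the reporting stage in seconds:

```r
tab <- reference_dispersal_table()
count_affected(classify_overlap(tab), reference_traits())$total_affected
#> [1] 22
group_mean_dispersal(tab, "vector")
#> animal abiotic    both
#>   34.4    51.4    41.1
```

Of 33 species, 22 show a disturbance effect on dispersal by the
CI-overlap rule, and abiotically dispersed species travel farthest on
average.

## The analysis workflow

Numbered drivers under `analysis/` run the full study end to end and
write their tables under `results/`:

1. `01_simulate.R` — generate the three-regime synthetic data set and
   validate it
2. `02_fit.R` — fit the seed-shadow model, write draws, DIC/RMSPE and
   convergence diagnostics
3. `03_tables.R` — overlap classification, affected-species counts,
   group means and effect signs from the reference tables
4. `04_recovery.R` — quick parameter-recovery and regime-separation
   check against known truth

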