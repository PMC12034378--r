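# gmgts

Gradient-matching inference of mixed-effects ODE models for heterogeneous
cell populations.

## The problem

Single-cell time-series experiments produce hundreds of short, noisy
trajectories, one per cell. Each cell follows the same biochemical network,
but with its own kinetic parameters; the scientific target is the
*population distribution* of those parameters — its mean vector `b` and
random-effects covariance `D` — not any single cell's values. The standard
two-stage route (GTS, *global two-stage*) fits every cell by trajectory
matching: nonlinear least squares in which each objective evaluation
integrates the ODE system numerically, typically from many starting points
per cell. For hundreds of cells this is slow and fragile.

This package implements **GMGTS** (*gradient-matching global two-stage*),
which removes almost all numerical integration from the inner loop:

1. **Smoothing.** Each observed state of each cell is smoothed with penalized
   cubic B-splines (penalty = integrated squared second derivative, weight
   chosen by generalized cross-validation), giving state estimates,
   derivative estimates, and — via estimated additive-plus-multiplicative
   measurement noise — a full covariance of the spline coefficients.
2. **Gradient matching.** For mass-action-type networks the right-hand side
   is linear in the parameters, `dx/dt = g(x) β + h(x)`, so matching the
   smoothed derivatives to the right-hand side is a *linear* regression per
   cell. The residual covariance induced by the smoothing uncertainty is
   propagated by a first-order delta method and re-estimated in alternation
   with the estimate (feasible generalized least squares), yielding each
   cell's `β̂ᵢ` and covariance `Cᵢ` without integrating the ODE at all.
3. **Hidden states.** When some states are not measured (promoter complexes,
   immature protein, …) they are reconstructed by integrating the system at
   the current estimate, with forward sensitivities linearizing their
   parameter dependence into the regression. A handful of integrations per
   cell replaces the hundreds needed by trajectory matching.
4. **Population step.** An EM algorithm combines the `(β̂ᵢ, Cᵢ)` into `(b, D)`,
   deconvolving the first-stage uncertainty so that `D` estimates the true
   biological heterogeneity rather than heterogeneity plus estimation error.

A trajectory-matching GTS baseline (`gts_pipeline`) and a closed-form
Gaussian 2-Wasserstein accuracy metric (`w2_gaussian`, `recovery_report`)
are included for comparison.

## Worked example

```r
library(gmgts)

# simulate 40 cells from the 16-species Lotka-Volterra study condition
dataset <- generate_scenario("lotka_volterra_full", seed = 7,
                             overrides = list(N = 40))
dataset
#> <population_dataset> 40 cells, model 'lotka_volterra_m4' (K = 16, observed = 16), T = 21 time points

# two-stage gradient-matching fit (smoothing -> FGLS -> EM)
fit <- gmgts(dataset)
fit
#> <gmgts_fit> 40 cells, full observation, 9.22 s
#>   Stage I converged: 100% of cells
#> <population_estimate> family = normal
#>   b_hat: 0.02098, 0.02063, 0.02026, 0.02084
#>   sqrt(diag(D_hat)): 0.005062, 0.004638, 0.004099, 0.004246
#>   EM iterations: 4 (converged)

# compare against the generating distribution
report <- recovery_report(fit$population, dataset$generating_distribution,
                          runtime_seconds = fit$runtime_seconds)
report
#> <recovery_report>
#>   normalized W2:         0.05904
#>   mean rel. errors:      0.049, 0.0314, 0.0128, 0.042
#>   SD rel. errors:        0.0124, -0.0723, -0.18, -0.151
#>   runtime (s):           9.223
```

The generating values here are mean 0.02 and SD 0.005 for all four rate
parameters.

Partial observation works the same way; the fit below infers both the
synthesis and the maturation rate of a fluorescent protein from the mature
(fluorescent) species alone:

```r
dataset <- generate_scenario("fp_one_step", seed = 7,
                             overrides = list(N = 50))
fit <- gmgts(dataset)
fit
#> <gmgts_fit> 50 cells, partial observation, 10.7 s
#>   Stage I converged: 90% of cells
#> <population_estimate> family = normal
#>   b_hat: 0.02579, 0.05199
#>   sqrt(diag(D_hat)): 0.006063, 0.01234
#>   EM iterations: 13 (converged)

mean(vapply(fit$individual, `[[`, integer(1), "n_integrations"))
#> [1] 9.18
```

(Generating values: k_p mean 0.025, k_m mean 0.05, both CV 0.25.) Nine ODE
integrations per cell — a GTS trajectory-matching fit of the same cells needs
roughly an order of magnitude more.

## Built-in systems and study conditions

| scenario id              | system                                             | observed                  |
|--------------------------|----------------------------------------------------|---------------------------|
| `lotka_volterra_full`    | 16-species cyclic Lotka-Volterra, 4 tied rates     | all 16 states             |
| `lotka_volterra_partial` | same                                               | states 5–16 (4 hidden)    |
| `repressilator`          | 3-gene repressilator, mass-action expansion (9 states) | mRNAs + proteins; promoter complexes hidden |
| `fp_one_step`            | fluorescent-protein maturation (dark → mature)     | mature protein only       |
| `fp_two_step`            | two maturation steps                               | mature protein only       |

`generate_scenario(name, seed, overrides)` reproduces the full study
conditions (population distributions, sampling grids, 5% multiplicative
measurement noise); custom systems plug in through `ode_model()` +
`population_dataset()`.

## Command line

A thin wrapper around the exported entry points lives at
`inst/cli/gmgts.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gmgts.R", package = "gmgts"))')" \
    simulate --scenario fp_one_step --seed 1 --out data/fp
# ... fit --data data/fp --out results/fp --method gmgts
# ... evaluate --data data/fp --estimate results/fp_population.json --out results/fp
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "gmgts",
                   load_package = "installed")
```

The methods vignette (`vignettes/gmgts-methods.Rmd`) documents the model,
the numerical choices, and the design decisions in detail.
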