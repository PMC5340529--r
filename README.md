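# seasipm

Seasonal eco-evolutionary integral projection model (IPM) for body-size
driven multigenerational population cycles, with the statistical toolkit to
document them.

## The problem

In strongly seasonal environments, selection can reverse between seasons:
large individuals produce more offspring in the breeding season, but at high
density small individuals survive the resource-poor non-breeding season
better. When the strength of that viability selection depends on density,
ecology and evolution close a feedback loop — crowding selects for small
flies, small flies have low fecundity, the population declines, fecundity
selection takes over, sizes and numbers rise again — that can generate
sustained multigenerational cycles in both population size and mean body
size. `seasipm` implements a quantitative-genetic IPM of this loop for a
*Drosophila*-like system with non-overlapping generations, plus the analysis
procedures used to document it in replicated laboratory populations.

## The model

A generation is a breeding season then a non-breeding season. Body size `z`
(female dry weight, mg) has breeding-value variance `VA = 0.003` mg² and
environmental variance `VE = 0.007` mg² (`h² = 0.30`), both constant.
Per-capita fecundity and non-breeding survival are

    f(z) = (φ1 + (φ2 z)^4) · exp(−(φ3 + φ4 z^4)(X0 + φ5 Y1 + φ6 X0 Y1))

    s(z) = [1 − z(υ1(X1+Y1) + υ2(X2+Y2))] / [1 + (z(Y0 + υ3 Y0 z e^z υ4)/υ6)^υ5]

where `X`/`Y` are breeding/non-breeding season-start abundances and the
subscripts are generation lags. Each season update projects abundance, mean
breeding value and mean phenotype through truncated-normal quadrature;
density also shifts mean phenotype directly through linear environmental
effects `eX(N) = −λX N`, `eY(N) = −λY N`. All parameter values ship as the
package defaults (`model_params()`, `inst/extdata/default_params.yaml`).

Beyond the engine, the package provides: a scenario simulator with crash
detection (`run_scenario()`: full model, stop-selection, no viability
selection, no delayed density dependence, near-zero heritability);
detrended-ACF cycle classification (`cycle_stats()`); standardized viability
selection differentials, Welch tests, a logistic survival fit and the
random-intercept regressions of selection on density and of fecundity /
survival on lagged densities (`selection_differential()`, `welch_t()`,
`fit_logistic_survival()`, `fit_selection_density_model()`,
`fit_delayed_density_models()`); and an individual-based generator of
experiment-shaped data — replicate populations, 5% female dry-weight
subsamples at 0.001 mg resolution, survival counts — so every analysis is
exercisable without external data (`generate_experiment()`,
`emulate_stop_selection()`).

## Worked example

```r
library(seasipm)

params <- model_params()
heritability(params)
#> [1] 0.3

# Full model from the packaged calibrated initial state: cycles
full <- run_scenario(scenario("full", n_generations = 40), params)
cs <- cycle_stats(full$X0)
cs$cycling; cs$period_estimate
#> [1] TRUE
#> [1] 7

# Remove viability selection (keep delayed density dependence): crash
nv <- run_scenario(scenario("no_viability", n_generations = 40), params)
detect_crash(nv)
#> [1] 10

# Synthetic stop-selection experiment and the logistic survival refit
cfg <- experiment_config(n_populations = 45, n_generations = 43, seed = 20170206)
ex <- emulate_stop_selection(cfg)
fit_logistic_survival(data.frame(N = ex$survival$N,
                                 survivors = ex$survival$survivors,
                                 total = ex$survival$N))
#> Logistic survival fit: v = 374.93 (se 1.82), w = 1.826 (se 0.0244)
```

The full model's breeding-season abundance oscillates between ~26 and ~106
individuals with a period of about 7 generations, and the correlogram decays
with alternating significant troughs and peaks — the formal signature of
cycling. Without size-dependent survival the trade-off collapses: large,
fecund flies dominate, densities overshoot, and the deterministic population
falls below one individual at generation 10. The logistic refit recovers the
generating half-survival abundance (375.22 individuals) and shape exponent
(1.83) to within ~1 standard error on a 45-population × 43-generation
design.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the full set of results and
write tables to `results/`:

| script | what it does |
|---|---|
| `01_scenarios.R` | runs the five scenarios, writes trajectories + summary |
| `02_cycles.R` | detrended ACFs and cycling classification per scenario |
| `03_synthetic_experiment.R` | generates control and stop-selection experiments |
| `04_selection_analysis.R` | Welch tests, selection differentials, S-on-density mixed models |
| `05_density_dependence.R` | lagged fecundity/survival mixed models, logistic survival refit |

Run them in order with `Rscript analysis/01_scenarios.R` etc. On the
packaged seeds the control emulation shows strongly negative,
density-dependent selection (mean S ≈ −0.63; slope of S on non-breeding
density ≈ −0.0022, p < 1e-40) and significant lagged survival effects,
while the stop-selection emulation shows neither (slope p ≈ 0.3, all four
lag terms p > 0.2) — the qualitative contrast the experimental design is
built to expose.

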