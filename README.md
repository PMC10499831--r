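# densel

Density-dependent phenotypic selection from individual fitness and
mark-recapture data.

`densel` is for population ecologists asking whether the phenotype that
maximises fitness shifts with population density — the situation of a
capital-breeding bird whose body condition (mass adjusted for structural
size) governs reproduction and survival, in a population whose size is set
by resource competition and predation. The package takes four tables —
individual measurements (id, year, mass, tarsus), annual fitness components
(survival indicator *I*, recruit count *B*), encounter histories, and a
population/covariate series — and returns posterior estimates of
directional, stabilising, and density-dependent selection, the
fitness-maximising condition as a function of population size, vital-rate
models with AICc selection, and lagged trophic-chain correlations.

## The model

Female annual fitness is *W* = *I* + *B*/2; the doubled fitness
2*W* = 2*I* + *B* is an integer and is modelled as Poisson with log link:

    ln E(2W | x, N, eps) = beta1' + beta2 x + beta3 x^2 - N e^(alpha1 + alpha2 x) + eps,
    eps ~ N(0, sigma_e^2)  (one random effect per year)

where *x* is the normalised body-condition index (residual of mass on
tarsus, scaled to mean 0, sd 1) and *N* the population size. The term
−*N* e^(α₁+α₂x) enforces strictly negative density dependence; α₂ < 0 means
high-condition females suffer less from crowding, so the optimal phenotype
x\*(N) — where ∂/∂x of the predictor vanishes — increases with *N*.
β₁' = β₁ + ln 2 keeps the intercept on the doubled-fitness scale.

The posterior is sampled with a compiled Hamiltonian Monte Carlo sampler
(analytic gradients, non-centred year effects; flat priors on the β's and on
σₑ, normal(−1, sd 2) on the α's), with rank-normalised split-R̂ ≤ 1.01 and
effective sample size ≥ 400 enforced before a fit is reported. A two-period
variant fits ln E(2W) = b₁' + b₂x + b₃x² + ε separately to the low- and
high-density halves of the series and classifies the selection regime from
the credible intervals. Survival is modelled in a Cormack–Jolly–Seber
framework with condition × density effects, reproduction with binomial and
(zero-truncated) Poisson GLMMs, and candidates are compared by AICc. A
seeded synthetic-cohort generator reproduces the assumed data structure so
the whole pipeline is testable without field data. The methods vignette
(`vignettes/density-dependent-selection.Rmd`) documents every model and
design decision.

## Worked example

Simulate a cohort under the study conditions (nine years, 250 females per
year, population stepping from 566 to 1071) and fit the selection model:

```r
library(densel)
cfg <- sim_config(seed = 7, years = 1991:1999, n_females_per_year = 250,
                  pop_mode = "custom", pop_custom = c(rep(566, 5), rep(1071, 4)))
cohort <- simulate_cohort(cfg)
fit <- fit_dd_selection(cohort$fitness,
                        mcmc = mcmc_config(n_iter = 6000, burn_in = 3000,
                                           thin = 3, seed = 7))
fit
#> Density-dependent selection model fit: 2250 records, 9 years, 4000 draws
#> Post-warmup divergences: 0
#>  parameter     mean   median     q2.5    q97.5  rhat  ess
#>     beta1p  0.94076  0.94851  0.63663  1.20783 1.002 1625
#>      beta2  0.08087  0.08011 -0.07073  0.24395 1.001 2827
#>      beta3 -0.01588 -0.01741 -0.07029  0.04612 1.002 2399
#>     alpha1 -7.08503 -7.04513 -7.65228 -6.73253 1.001 1610
#>     alpha2 -0.48381 -0.47479 -0.79724 -0.23311 1.003 1785
#>    sigma_e  0.10426  0.09626  0.03216  0.22044 1.003 1594
```

Each row is a posterior summary: the directional (β₂) and stabilising (β₃)
coefficients, the density-dependence parameters (α₁, α₂ — here α₂'s 95%
interval is entirely negative, i.e. density-dependent selection on
condition), the year-effect sd, and the convergence diagnostics. The
generating values (β₁′ = 1, β₂ = 0.2, β₃ = −0.05, α₁ = −7, α₂ = −0.3,
σₑ = 0.1) sit inside their intervals. The optimal condition and its
credible band at the minimum, mean and maximum population size:

```r
posterior_optima(fit, N = c(566, 800, 1071))
#>      N    xstar     q2.5    q97.5
#> 1  566 3.548203 1.877296 4.611575
#> 2  800 3.837632 2.142940 4.696885
#> 3 1071 4.109316 2.359960 4.737383
```

The optimum rises with density, as α₂ < 0 implies; intervals are wide at
this sample size because the curvature β₃ is weakly determined. The full
pipeline — condition index, trend tests, both selection models, vital rates,
correlations — runs from one config via `run_pipeline(pipeline_config(...))`
(a thin CLI over the same functions is in `inst/cli/densel.R`), and
`write_report()` emits JSON or markdown.

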