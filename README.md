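# glmqc — qualitatively constrained GLMs for treatment-effect targeting

`glmqc` is an R package for estimating **heterogeneous treatment effects
(HTE)** from observational survey data with a model that decision makers
can audit: a generalized linear model whose effects obey **qualitative
constraints** — signs and monotonicity known from domain theory — imposed
through an incremental-coding reparameterization and a box-constrained
maximum-likelihood solver.  Around that core it provides the full
targeting workflow: S-learner effect estimation for an ordinal treatment
(one-level increase, capped at the top level), a consensus rule for
combining two black-box effect estimators, log-odds-ratio explanation of
those estimators via an additive surrogate with pairwise terms,
budget-constrained benefit-to-cost targeting with capture curves, and a
synthetic confounded-survey generator with exact ground truth.

It is aimed at biostatisticians and health-economics/uplift analysts who
need to allocate a limited intervention budget (the running example:
incentives to raise physical activity, to reduce diabetes and ischemic
heart disease prevalence) and must justify the allocation with a model
whose effects have the theoretically expected shape.

## The model

For outcome `y` with link `g` (identity or logit), covariate blocks `X_j`
(continuous, or discretized into ordered bands) and an interaction set χ:

```
g(E(y | X)) = α + Σ_j X_j β_j + Σ_{(k,j) ∈ χ} X_j · X_k γ_jk
```

Each term can be constrained: *monotone increasing/decreasing* over its
ordered levels and/or *sign-restricted* relative to its reference level.
Levels are coded as cumulative step indicators, so the constraint becomes
a sign bound on each step coefficient; the model is fitted by cyclic
coordinate descent on the IRLS quadratic under those bounds (compiled,
survey-scale fits take well under a second), and original-scale
coefficients are recovered through the triangular coding matrices
(`β_j = A_j ζ_j`; Kronecker products `A_j ⊗ A_k` for interaction
surfaces, whose working coefficients are the surface's double
increments).

Treatment effects are S-learner differences
`τ̂_i = g⁻¹(η_i | w = w_i + 1) − g⁻¹(η_i | w = w_i)`, zero for
individuals already at the top treatment level; for binary outcomes the
corresponding log odds ratio is the link-scale difference.  Two external
effect estimates are combined by the consensus rule `0 if
|(a+b)/2| ≤ q·|a−b|/2, else (a+b)/2` (default `q = √2`).

## Worked example

```r
library(glmqc)

cfg <- synth_config(n = 20000)            # survey-like synthetic population
pop <- synth_population(cfg, seed = 7)
pop
#> Synthetic survey population: n = 20000, outcomes: diabetes, ihd
#>   treatment shares: 0.177 0.455 0.100 0.268

spec <- default_outcome_spec("diabetes")  # constraint catalogue for the fit
fit <- glmqc(pop$data, spec)
fit
#> Qualitatively constrained GLM fit (binomial)
#>   n = 20000, deviance = 14702.65, converged = TRUE
#>   intercept = -3.27144
#>   active sign bounds: 3 of 18

round(effect_curve(fit, "activity"), 3)   # nonpositive, decreasing by design
#> [1]  0.000 -0.448 -0.816 -0.893
round(effect_curve(fit, "age"), 3)        # nonnegative, increasing by design
#> [1] 0.000 0.729 1.132 1.491

hte <- tau_slearner(fit, pop$data)        # one-level activity increase
cor(hte$tau, pop$truth$diabetes$tau)
#> [1] 0.969
pct_positive(hte$lnor)                    # adverse-effect diagnostic
#> [1] 0

benefit <- -pop$truth$diabetes$tau        # true attainable reductions
rep_ <- efficiency_report(list(glm_qc = -hte$tau), benefit, fractions = 0.25)
rep_$table
#>     model fraction  captured
#> 1  glm_qc     0.25 0.6250816
#> 2 perfect     0.25 0.6277324
#> 3  random     0.25 0.2503431
```

Reading the numbers: the fitted activity and age curves have the declared
shape and sign exactly (the sign bounds make adverse estimated effects
impossible, hence the 0% diagnostic); per-individual effect estimates
correlate with the generator's exact truth at 0.97; and targeting the 25%
of individuals with the largest estimated benefit captures 62.5% of the
total attainable benefit — essentially the 62.8% captured by ranking on
the (normally unobservable) truth itself, against 25% for random
targeting.

A thin command-line wrapper over the same functions ships in
`inst/cli/glmqc` (subcommands `synth`, `fit`, `hte`, `ensemble`, `lnor`,
`explain`, `target`, `report`; every run writes a `.manifest.json` with
input fingerprints and the seed).

## Package layout

* `R/model-spec.R`, `R/coding.R`, `R/design.R` — declarations,
  discretization, incremental/dummy coding, design assembly.
* `src/cd_solver.cpp`, `R/fit.R` — box-constrained IRLS coordinate
  descent, prediction, effect curves and surfaces.
* `R/hte.R` — S-learner, consensus ensemble, component probabilities,
  log odds ratios.
* `R/explain.R` — additive surrogate with pairwise terms, candidate-term
  ranking.
* `R/targeting.R` — budget selection, captured benefit, capture curves,
  efficiency reports.
* `R/synth.R` — synthetic confounded populations with exact ground truth.
* `R/io.R`, `inst/cli/glmqc` — CSV/JSON/YAML interfaces, run manifests,
  comparison reports, command-line wrapper.
* `vignettes/constrained-hte-methods.Rmd` — the methods vignette: model,
  assumptions, numerical choices, generator design, limitations.
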