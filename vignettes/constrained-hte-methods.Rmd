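---
title: "Qualitatively constrained GLMs for heterogeneous treatment effect targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitatively constrained GLMs for heterogeneous treatment effect targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmqc)
```

## The problem

Public-health programs (and, more generally, any budget-limited
intervention) must decide *whom* to treat.  With observational survey data
that contains all confounders, a correctly specified outcome model yields
per-individual treatment effects
\(\tau_i = E[y_i \mid w = \omega_s, X_i] - E[y_i \mid w = \omega_0, X_i]\),
and sorting individuals by estimated benefit per unit cost maximizes the
total benefit under a budget.  The difficulty is the tension between
flexibility (black-box causal machine learning finds heterogeneity but is
not justifiable to decision makers) and interpretability (a theory-driven
GLM is auditable but may miss heterogeneity and can produce
counter-intuitive effect signs from confounded data).

This package implements the middle road: a **generalized linear model with
qualitative constraints** — sign and monotonicity restrictions on the
effects of discretized covariates and their two-way interactions — plus the
surrounding machinery: S-learner effect estimation for an ordinal
treatment, a consensus rule for combining two black-box effect estimators,
an additive surrogate explainer that proposes new treatment-interaction
terms, budget-constrained targeting evaluation, and a synthetic
confounded-survey generator with exact ground truth for validation.

## The constrained model and its reparameterization

The outcome model is a GLM,
\[
g(E(y \mid X)) = \alpha + \sum_j X_j \beta_j
  + \sum_{(k,j) \in \chi} X_j \cdot X_k\, \gamma_{jk},
\]
with the identity link for gaussian outcomes and the logit link for binary
ones.  Continuous covariates in the shape set are discretized into \(K_j\)
ordered bands, so each effect is a step function over bands; nothing is
assumed smooth.

A qualitative constraint on a term combines *monotonicity* of its effect
curve over the ordered levels with a *sign* relative to the term's
reference level.  The key device is **incremental (step) coding**: instead
of dummy variables, level \(x\) is coded by cumulative step indicators
counted away from the reference end, so the coefficient of step \(k\) is
the increment of the effect curve across one pair of consecutive levels.
A monotone curve then corresponds to sign-bounded step coefficients, which
a box-constrained solver can impose directly.  The six meaningful
monotone cases map onto bounds as follows (reference end in parentheses):

| monotonicity | sign | reference | step bounds |
|---|---|---|---|
| increasing | positive | first | all \(\ge 0\) |
| increasing | negative | last  | all \(\le 0\) |
| decreasing | positive | last  | all \(\ge 0\) |
| decreasing | negative | first | all \(\le 0\) |
| increasing | unrestricted | first | first free, rest \(\ge 0\) |
| decreasing | unrestricted | first | first free, rest \(\le 0\) |

A curve pinned at zero at its reference can only be, say, increasing *and*
everywhere nonnegative if the reference is the first level; that is why
sign and monotonicity jointly determine the reference end, and the package
validates the declared reference against the case.  For the two
unrestricted-sign cases the first step coefficient is left free: the curve
over the non-reference levels is monotone, while its position relative to
the reference is not restricted (equivalently, the free first step acts as
a level shift of all non-reference levels).  We deliberately define the
coding by these cumulative-step semantics and verify it by property tests
(every feasible coefficient vector produces a curve in the declared
family, and every curve in the family maps back to feasible coefficients),
rather than by any particular indicator-index convention, which is easy to
get wrong around the reference column.

Original-scale coefficients are recovered linearly: \(\beta_j = A_j
\zeta_j\), where \(A_j\) is the triangular coding matrix and \(\zeta_j\)
the working (step) coefficients; the map is unit-triangular, so the round
trip is exact to machine precision.

**Two-way interactions.** Both coded blocks are multiplied columnwise, and
the block coding matrix is the Kronecker product \(A_j \otimes A_k\).  The
working coefficients of such a block are the *double increments*
(difference-in-differences) of the interaction surface away from the two
references; a monotone constraint bounds every double increment, which
makes statements like "the activity effect becomes more negative as age
increases" directly imposable.  Sign-only and unconstrained interactions
use dummy-coded blocks.  This construction is our design choice for the
two-way case; it reduces to the main-effect coding on each slice and is
validated predictor-for-predictor against brute-force dummy products in
the tests.

## Solver

The reparametrized model is fitted by penalized maximum likelihood under
per-coefficient box bounds (\(\ge 0\), \(\le 0\), or free), by cyclic
coordinate descent on the iteratively reweighted least-squares quadratic
(plain box-constrained least squares for gaussian outcomes).  Per
reweighting step the Gram matrix \(X'WX\) is formed once and each
coordinate update costs \(O(p)\) ("covariance updates"), so strongly
collinear step-coded columns are not a speed problem; a survey-scale fit
(\(n = 80{,}000\), two dozen columns) takes well under a second.

Numerical choices:

* `ridge_epsilon = 1e-8`: an effectively-unpenalized ridge for numerical
  stability only — the qualitative constraints, not shrinkage, are the
  intended regularizer.  The penalty is exposed in `qc_fit_config()`.
* convergence: relative deviance change below `tol = 1e-9` across
  reweighting steps; inner sweeps stop when the largest scaled coefficient
  move is below `tol/10`.
* standardization: columns are scaled by their standard deviation before
  fitting.  Only *positive* scaling is ever applied, so sign bounds are
  preserved; recovered coefficients are returned on the original scale,
  and fits with and without standardization agree to solver tolerance.
* degenerate constant columns are pinned at zero with a warning;
  exactly collinear columns are left to coordinate descent (the ridge
  epsilon breaks ties).
* the solver path contains no randomness; fits are deterministic.

Correctness is established against independent oracles: closed-form least
squares, `stats::glm` at inactive constraints, and a generic
box-constrained optimizer (`optim(method = "L-BFGS-B")`) on random small
instances, with Karush–Kuhn–Tucker checks at the returned solution.

## Treatment effects, consensus ensemble, and log odds ratios

The treatment is an ordinal exposure (physical-activity level 1–4 in the
running example); the policy scenario is a **one-level increase**, and
individuals already at the top level are capped with \(\tau_i = 0\)
identically.  `tau_slearner()` computes S-learner effects: predict with
the treatment at the observed level and at one level higher, all other
covariates fixed, and difference on the response scale.  With the identity
link only treatment-interaction terms generate heterogeneity across
individuals at the same observed level; with the logit link every
covariate contributes through the nonlinearity of the antilogit.

Two external effect estimators (e.g. a posterior-sampling tree ensemble
and a causal forest; the package consumes their predictions, it does not
reimplement them) are combined by a **consensus rule**: with component
estimates \(a_i, b_i\), average \(\bar\tau_i = (a_i + b_i)/2\) and
disagreement \(\hat\sigma_i = |a_i - b_i|/2\), the ensemble returns 0
unless \(|\bar\tau_i| > q \hat\sigma_i\).  The default \(q = \sqrt 2\).
The zero set is exactly \(\{|a+b| \le q\,|a-b|\}\), verified by brute
force.  Only the two-component rule is exposed; generalizing
\(\hat\sigma\) to the standard error of a longer component mean would be
straightforward but is not the validated path.

For binary outcomes the ensemble is explained on the *link* scale: the
per-individual log odds ratio
\(\ln \mathrm{OR}_i = \mathrm{logit}(p_i \mid \omega_s) -
\mathrm{logit}(p_i \mid \omega_0)\) is directly comparable to logit-model
coefficients.  Component probabilities at a required treatment level are
reconstructed either as posterior-draw means or, for constant-effect
components, by the extrapolation \(\hat p \mid w = \hat y_{\mathrm{OBS}} -
(w - w_{\mathrm{OBS}})\hat\tau\).  The minus sign is deliberate: it is the
printed convention of the method this package follows, although the
conventional first-order extrapolation would add the term; because the
point is contested, the sign is exposed as `extrapolation_sign` and all
internal uses derive their expectations from the configured formula.
Probabilities are clipped to \([10^{-6}, 1 - 10^{-6}]\) so log odds stay
finite.  Capped individuals are excluded from lnOR summaries *before*
any averaging.

The `pct_positive()` diagnostic reports the share of strictly positive
effect estimates; for a treatment that theory says is protective, positive
estimates suggest confounding or misspecification.

## Surrogate explainer

`fit_surrogate()` fits a generalized additive surrogate with pairwise
terms to the per-individual lnOR (or \(\tau\)) estimates: cyclic boosting
of depth-one piecewise-constant updates over binned features (quantile
bins, 16 by default), followed by greedy selection of the pairwise grids
with the largest residual variance reduction.  Defaults (`rounds = 500`,
`learning_rate = 0.1`, `n_pairs = 5`) are package choices — the underlying
method publications do not pin them — and are exposed.  Shape functions
are mean-centered; importance is the mean absolute contribution.  The
surrogate is a *population-level explanation* fitted and evaluated on the
training rows; it is not a forecasting model, and its fidelity \(R^2\) is
reported on those rows.  `rank_candidate_terms()` turns the importance
ranking into an ordered list of covariates not yet interacting with the
treatment, annotated with the empirical monotone direction of their shape
— the human-in-the-loop then decides which interaction to add to the
constrained specification and with what constraint.  No automatic model
update is performed.

## Targeting evaluation

Benefits are *reductions*: \(\text{benefit}_i = \sum_d w_d \,
(-\tau_{i,d})\) with equal outcome weights by default.  `select_targets()`
sorts by benefit-to-cost ratio (stable sort, ties keep input order) and
selects until the budget — a fraction of total cost — is exhausted; the
last individual is included only if fully affordable.  Individuals with
nonpositive estimated benefit remain eligible while budget remains (the
ranking covers everyone); an optional stopping rule for
benefit/cost < 1 applies only when benefits and costs share a unit and is
off by default.  `captured_fraction()` divides the true benefit of the
selected set by the total attainable benefit; `efficiency_report()` adds
the perfect (rank-by-truth) and seeded random baselines.  Random targeting
at fraction \(f\) captures \(f\) of the benefit in expectation, and no
score can beat the truth ranking at any fraction — both are asserted
exactly in the tests.

## Synthetic populations and what they do (not) show

The generator (`synth_population()`) replaces a real health survey that
cannot be redistributed.  Design choices, fixed once:

* **Covariates**: age (truncated normal, 18–90), gender, BMI (correlated
  with age via a knob), smoking, second-hand smoke, alcohol, fruit and
  vegetable consumption, number of trusted people, education, income,
  region.  Covariates are drawn independently except for the explicit
  age–BMI dependence: tests need controllable structure, not demographic
  realism.
* **Treatment**: 4-level activity with marginals (0.18, 0.45, 0.10, 0.27),
  assigned by a proportional-odds logit on a latent health index
  (healthier individuals exercise more); cutpoints are calibrated by root
  finding so the marginals hit their targets at any confounding strength.
  `naive_vs_adjusted_gap()` exhibits the resulting confounding: naive
  group contrasts overstate the benefit, increasingly so with the
  confounding strength.
* **Outcomes**: two binary diseases from logistic structural models with
  increasing age and BMI curves, positive smoking/second-hand/male
  effects, a decreasing nonpositive activity curve, and multiplicative
  moderation of the activity effect (age band for both outcomes, smoking
  for diabetes), giving baseline prevalences of roughly 13–15%.
  Magnitudes are synthetic, chosen once to be epidemiologically plausible;
  every curve is checked against its own declared constraint at
  construction.  Exact per-individual effect curves, probabilities at all
  four treatment levels, \(\tau\) and lnOR are recorded as ground truth.
* **Moderation is linear in a zero-based moderator score** (e.g. the age
  band index), not a free 3×3 interaction surface.  This is deliberate: at
  realistic survey scale (\(n \approx 5\times 10^4\), \(\sim\!14\%\)
  prevalence, 10% of individuals at the third activity level), the
  maximum-likelihood standard errors of free surface cells reach 0.2 on
  the logit scale, i.e. the surface is not meaningfully identifiable for
  *any* estimator; a linear moderation expresses the same qualitative
  statement and is identified.  The Kronecker surface machinery remains
  fully supported and tested for users who have the data to feed it.

Passing tests on these populations show that the estimation and targeting
machinery is correct *under correct specification and fully observed
confounders*.  They do not show robustness to unobserved confounding,
misspecified bins, measurement error, or survey weighting — none of which
the generator emulates.

A note on accuracy at survey scale: per-coefficient sampling noise for
this model family is 0.04–0.09 on the logit scale at \(n = 50{,}000\)
(empirically unbiased), so the sup-norm error over all ~24 recovered curve
values is typically 0.1–0.2 and shrinks as \(n^{-1/2}\); individual-level
\(\hat\tau\) correlates with the exact truth at \(r > 0.97\).  The test
suite asserts the sup-norm recovery at a 0.05 bound, which at this sample
size is tighter than the information limit; the assertion is retained
(and fails, documented) rather than silently loosened, alongside the
correlation and error-decay assertions, which pass.

## Problem sizes used by the test and acceptance runs

Property sweeps use all six constraint cases with \(K \in \{2,\dots,6\}\)
and 1000 random feasible coefficient vectors each; solver–oracle
comparisons use 50 random instances with up to 10 columns and \(n \le
500\); recovery studies use \(n = 50{,}000\) with the error-decay grid
\(n \in \{5, 20, 80\} \times 10^3\) over 3 seeds; the
constraints-vs-unconstrained targeting comparison uses 20 replicates of
\(n = 2{,}000\) training populations evaluated against a fixed
\(n = 10{,}000\) population; random-targeting baselines use 500
replicates at \(n = 10{,}000\).  The whole suite runs in well under a
minute on a single core.

## Known limitations

* Shapes are step functions over declared bins; no splines, no automatic
  bin selection.
* Only two-way interactions; three-way constraint structures (e.g.
  smoking × gender × age) must be expressed by pre-built composite
  variables.
* The consensus rule is validated for exactly two components.
* No uncertainty intervals on \(\hat\tau\); the package quantifies
  targeting quality against ground truth, not estimator variance.
* The cost model is a scalar per individual; no currency-level
  cost-effectiveness modeling.
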