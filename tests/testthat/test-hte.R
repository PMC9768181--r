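# S-learner effects, consensus ensemble, component probabilities, lnOR.

make_activity_fit <- function(dat, family = "binomial", with_interaction = TRUE) {
  vars <- list(qc_variable("w", "ordinal", n_levels = 4),
               qc_variable("x1", "ordinal", n_levels = 3))
  terms <- list(qc_term("w", qc_constraint("decreasing", "negative")),
                qc_term("x1", qc_constraint("increasing", "positive")))
  if (with_interaction)
    terms <- c(terms, list(qc_term(c("w", "x1"),
                                   qc_constraint("decreasing", "negative"))))
  spec <- qc_model_spec(outcome = "y", family = family, treatment = "w",
                        variables = vars, terms = terms)
  glmqc(dat, spec)
}

test_that("capped individuals get zero effect; identity link is constant without interactions", {
  set.seed(31)
  dat <- tiny_survey(n = 300, seed = 31)
  dat$y <- rnorm(300, 1 - 0.2 * dat$w + 0.3 * dat$x1, 0.4)
  fit <- make_activity_fit(dat, family = "gaussian", with_interaction = FALSE)
  hte <- tau_slearner(fit, dat)
  expect_true(all(hte$tau[dat$w == 4] == 0))
  expect_true(all(hte$capped == (dat$w == 4)))
  # identity link, no treatment interactions: tau is a function of the
  # treatment contrast alone -- identical across individuals sharing an
  # observed level, regardless of their covariates
  for (w0 in 1:3)
    expect_lt(diff(range(hte$tau[dat$w == w0])), 1e-10)
  # and equal to the fitted step coefficient for that contrast
  cw <- effect_curve(fit, "w")
  expect_equal(unique(round(hte$tau[dat$w == 1], 10)),
               round(cw[2] - cw[1], 10))
})

test_that("logit S-learner effects match hand-computed antilogit differences", {
  dat3 <- data.frame(w = c(1, 3, 4), x1 = c(2, 1, 3), y = c(0, 1, 0))
  fit <- make_activity_fit(rbind(dat3, tiny_survey(60, 32)[, c("w", "x1", "y")]))
  hte <- tau_slearner(fit, dat3)
  for (i in 1:2) {
    d0 <- dat3[i, , drop = FALSE]
    d1 <- d0; d1$w <- d0$w + 1
    manual <- plogis(predict(fit, d1, type = "link")) -
      plogis(predict(fit, d0, type = "link"))
    expect_equal(hte$tau[i], unname(manual), tolerance = 1e-12)
    expect_equal(hte$lnor[i],
                 unname(predict(fit, d1, "link") - predict(fit, d0, "link")),
                 tolerance = 1e-12)
  }
  expect_identical(hte$tau[3], 0)
  expect_true(is.na(hte$lnor[3]))
})

test_that("consensus rule follows the two-branch formula", {
  expect_equal(ensemble_consensus(1.0, -0.5), 0)            # qs = 1.061 > .25
  expect_equal(ensemble_consensus(1.0, 0.5), 0.75)          # qs = .354 < .75
  expect_equal(ensemble_consensus(c(2, 2), c(2, 2)), c(2, 2))  # sigma = 0
  expect_error(ensemble_consensus(1:3, 1:2), "lengths")
})

test_that("consensus zero set is |a + b| <= q|a - b|, symmetric and scale-equivariant", {
  grid <- expand.grid(a = seq(-2, 2, by = 0.25), b = seq(-2, 2, by = 0.25),
                      q = c(0.5, 1, sqrt(2), 3))
  out <- ensemble_consensus(grid$a, grid$b, grid$q)
  # brute-force two-branch evaluation (element by element)
  brute <- mapply(function(a, b, q) {
    if (abs((a + b) / 2) <= q * abs(a - b) / 2) 0 else (a + b) / 2
  }, grid$a, grid$b, grid$q)
  expect_equal(out, unname(brute))
  zero <- out == 0
  expect_equal(zero, abs(grid$a + grid$b) <= grid$q * abs(grid$a - grid$b))
  # symmetry and positive scaling
  expect_equal(out, ensemble_consensus(grid$b, grid$a, grid$q))
  expect_equal(3.5 * out, ensemble_consensus(3.5 * grid$a, 3.5 * grid$b, grid$q))
})

test_that("component probabilities extrapolate per the printed convention", {
  pred <- component_predictions("constant-effect", w_obs = c(2L, 2L, 3L),
                                y_hat_obs = c(0.30, 0.30, 0.6),
                                tau_hat = c(-0.05, 0.1, 0))
  expect_equal(component_prob_at(pred, c(3L, 3L, 4L)),
               c(0.30 - (1) * (-0.05), 0.30 - 0.1, 0.6))
  # zero extrapolation at the observed level
  expect_equal(component_prob_at(pred, pred$w_obs), c(0.30, 0.30, 0.6))
  # the conventional sign is available as a switch
  pred2 <- component_predictions("constant-effect", w_obs = 2L,
                                 y_hat_obs = 0.30, tau_hat = -0.05,
                                 extrapolation_sign = +1)
  expect_equal(component_prob_at(pred2, 3L), 0.25)
  # posterior draws: mean over draws; identical draws return the constant
  dr <- list(`2` = matrix(0.4, 2, 5), `3` = matrix(c(0.2, 0.6), 2, 5))
  predd <- component_predictions("posterior-draw", w_obs = c(2L, 2L), draws = dr)
  expect_equal(component_prob_at(predd, 3L), c(0.2, 0.6))
  expect_equal(component_prob_at(predd, 2L), c(0.4, 0.4))
  expect_error(component_prob_at(predd, 4L), "level")
})

test_that("ensemble lnOR averages component probabilities and excludes capped rows", {
  plan <- treatment_plan("activity", 4)
  mk <- function(y0, tau) component_predictions(
    "constant-effect", w_obs = c(1L, 2L, 4L), y_hat_obs = y0, tau_hat = tau)
  # choose tau so that p at w+1 is p0 - (+1)*tau
  a <- mk(c(0.10, 0.2, 0.5), c(-0.10, 0, 0))
  b <- mk(c(0.10, 0.2, 0.5), c(-0.10, 0, 0))
  ln <- lnor_from_components(a, b, plan)
  expect_equal(ln[1], log((0.2 / 0.8) / (0.1 / 0.9)), tolerance = 1e-12)
  expect_equal(ln[2], 0)
  expect_true(is.na(ln[3]))
  # equal-component average equals the single-component lnOR
  a2 <- mk(c(0.15, 0.3, 0.4), c(-0.05, -0.02, 0))
  ln_single <- lnor_from_components(a2, a2, plan)
  p0 <- component_prob_at(a2, a2$w_obs); ps <- component_prob_at(a2, c(2L, 3L, 4L))
  expect_equal(ln_single[1:2],
               (log(ps / (1 - ps)) - log(p0 / (1 - p0)))[1:2])
})

test_that("lnOR of the logit S-learner equals its linear-predictor difference", {
  set.seed(33)
  dat <- tiny_survey(n = 400, seed = 33)
  dat$y <- rbinom(400, 1, plogis(-1 + 0.3 * dat$x1 - 0.2 * dat$w))
  fit <- make_activity_fit(dat)
  hte <- tau_slearner(fit, dat)
  ok <- !hte$capped
  d1 <- dat; d1$w <- pmin(dat$w + 1, 4)
  expect_equal(hte$lnor[ok],
               (predict(fit, d1, "link") - predict(fit, dat, "link"))[ok],
               tolerance = 1e-12)
})

test_that("pct_positive counts strict positives only", {
  expect_equal(pct_positive(c(-1, -2, -0.1)), 0)
  expect_equal(pct_positive(c(-1, 0, 2, 3)), 50)
  expect_equal(pct_positive(rep(0, 5)), 0)
  expect_equal(pct_positive(c(NA, 1, -1)), 50)
  expect_error(pct_positive(numeric(0)), "empty")
})
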