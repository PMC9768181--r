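# Box-constrained IRLS coordinate descent: closed-form and generic-optimizer
# oracles, KKT conditions, prediction, deviance comparison.

test_that("gaussian fits match closed-form least squares", {
  set.seed(21)
  g <- rep(c(0, 1), each = 40)
  y <- 2 + 1.5 * g + rnorm(80, 0, 0.3)
  des <- raw_design(cbind(g), "free", family = "gaussian")
  fit <- qc_fit(des, y, config = qc_fit_config(ridge_epsilon = 0))
  expect_equal(unname(fit$zeta), mean(y[g == 1]) - mean(y[g == 0]),
               tolerance = 1e-8)
  expect_equal(fit$alpha, mean(y[g == 0]), tolerance = 1e-8)

  # sign bound active: negative sample slope forced to zero
  y2 <- 2 - 1.0 * g + rnorm(80, 0, 0.3)
  des2 <- raw_design(cbind(g), "ge", family = "gaussian")
  fit2 <- qc_fit(des2, y2, config = qc_fit_config(ridge_epsilon = 0))
  expect_identical(unname(fit2$zeta), 0)
  expect_equal(fit2$alpha, mean(y2), tolerance = 1e-8)
  expect_true(fit2$active_bound)
})

test_that("binomial fit with inactive constraints matches unconstrained MLE", {
  set.seed(22)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  eta <- -0.5 + 0.8 * x1 + 0.6 * x2
  y <- rbinom(n, 1, plogis(eta))
  des <- raw_design(cbind(x1, x2), c("ge", "ge"))  # bounds inactive at MLE
  fit <- qc_fit(des, y, config = qc_fit_config(ridge_epsilon = 0))
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(fit$alpha, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$zeta), unname(coef(ref)[2:3]), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
})

test_that("solver matches the generic box-constrained oracle on random instances", {
  set.seed(23)
  for (r in 1:12) {
    n <- sample(100:400, 1)
    p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    family <- sample(c("gaussian", "binomial"), 1)
    beta_true <- rnorm(p)
    eta <- drop(X %*% beta_true)
    y <- if (family == "binomial") rbinom(n, 1, plogis(eta)) else eta + rnorm(n)
    bounds <- random_bounds(p)
    des <- raw_design(X, bounds, family = family)
    fit <- qc_fit(des, y, config = qc_fit_config(ridge_epsilon = 0))
    box <- bounds_to_box(bounds)
    orc <- oracle_box_fit(X, y, family, box$lower, box$upper)
    obj_fit <- objective_value(c(fit$alpha, fit$zeta), X, y, family, TRUE)
    expect_lte(obj_fit - orc$value, 1e-6 * (1 + abs(orc$value)))
    # bounds hold exactly
    expect_true(all(fit$zeta[bounds == "ge"] >= 0))
    expect_true(all(fit$zeta[bounds == "le"] <= 0))
  }
})

test_that("KKT conditions hold at the returned solution", {
  set.seed(24)
  for (r in 1:8) {
    n <- 300; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(drop(X %*% rnorm(p)) * 0.5))
    bounds <- random_bounds(p)
    des <- raw_design(X, bounds)
    fit <- qc_fit(des, y, config = qc_fit_config(ridge_epsilon = 0))
    g <- objective_grad(c(fit$alpha, fit$zeta), X, y, "binomial", TRUE)[-1]
    interior <- !fit$active_bound
    expect_true(all(abs(g[interior]) <= 1e-4 * n))
    # at an active lower bound 0 (ge), improving would need beta to go
    # negative: gradient must be nonnegative (up to tolerance); vice versa
    at_lo <- fit$active_bound & bounds == "ge"
    at_hi <- fit$active_bound & bounds == "le"
    expect_true(all(g[at_lo] >= -1e-4 * n))
    expect_true(all(g[at_hi] <= 1e-4 * n))
  }
})

test_that("predictions follow the link and match hand-computed fixtures", {
  dat <- data.frame(w = c(1, 2, 4, 3, 2), y = c(0, 1, 0, 1, 0))
  spec <- qc_model_spec(
    outcome = "y", family = "binomial", treatment = "w",
    variables = list(qc_variable("w", "ordinal", n_levels = 4)),
    terms = list(qc_term("w", qc_constraint("decreasing", "negative"))))
  des <- build_design(dat, spec)
  fit <- qc_fit(des, dat$y)
  # manual matrix product on the 5-row fixture
  eta_manual <- fit$alpha + drop(des$Z %*% fit$zeta)
  expect_equal(predict(fit, dat, type = "link"), eta_manual, tolerance = 1e-12)
  expect_equal(predict(fit, dat, type = "response"), plogis(eta_manual),
               tolerance = 1e-12)
  # all-zero coefficients -> response is antilogit(alpha) everywhere
  fit0 <- fit; fit0$zeta[] <- 0; fit0$alpha <- 0
  expect_equal(predict(fit0, dat, type = "response"), rep(0.5, 5))
})

test_that("constraints can only increase the deviance, measurably so when active", {
  set.seed(26)
  dat <- tiny_survey(n = 300, seed = 26)
  # force an active constraint: positive association but negative bound
  dat$y <- rbinom(300, 1, plogis(-0.5 + 0.8 * (dat$w > 2)))
  spec <- qc_model_spec(
    outcome = "y", family = "binomial", treatment = "w",
    variables = list(qc_variable("w", "ordinal", n_levels = 4)),
    terms = list(qc_term("w", qc_constraint("decreasing", "negative"))))
  des <- build_design(dat, spec)
  fc <- qc_fit(des, dat$y)
  fu <- qc_fit(des, dat$y, constrained = FALSE)
  gap <- deviance_compare(fc, fu)
  expect_gte(gap, -1e-6)
  expect_gt(gap, 1)          # constraints bind against the data here
  # identical bounds -> gap ~ 0
  expect_lt(abs(deviance_compare(fu, fu)), 1e-10)
  expect_error(deviance_compare(fc, qc_fit(des, rev(dat$y))), "same data")
})

test_that("standardization does not change recovered coefficients", {
  set.seed(27)
  dat <- tiny_survey(n = 500, seed = 27)
  dat$y <- rbinom(500, 1, plogis(-0.3 - 0.3 * dat$w + 0.2 * dat$x1))
  spec <- qc_model_spec(
    outcome = "y", family = "binomial", treatment = "w",
    variables = list(qc_variable("w", "ordinal", n_levels = 4),
                     qc_variable("x1", "ordinal", n_levels = 3)),
    terms = list(qc_term("w", qc_constraint("decreasing", "negative")),
                 qc_term("x1", qc_constraint("increasing", "positive"))))
  f1 <- glmqc(dat, spec, qc_fit_config(standardize = TRUE, ridge_epsilon = 0))
  f2 <- glmqc(dat, spec, qc_fit_config(standardize = FALSE, ridge_epsilon = 0))
  expect_equal(f1$zeta, f2$zeta, tolerance = 1e-6)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
})

test_that("fitted effect curves satisfy their declared constraints exactly", {
  set.seed(28)
  dat <- tiny_survey(n = 400, seed = 28)
  dat$y <- rbinom(400, 1, plogis(0.3 * dat$x1 - 0.2 * dat$w + rnorm(400, 0, 0.5)))
  spec <- qc_model_spec(
    outcome = "y", family = "binomial", treatment = "w",
    variables = list(qc_variable("w", "ordinal", n_levels = 4),
                     qc_variable("x1", "ordinal", n_levels = 3)),
    terms = list(qc_term("w", qc_constraint("decreasing", "negative")),
                 qc_term("x1", qc_constraint("increasing", "positive")),
                 qc_term(c("w", "x1"), qc_constraint("decreasing", "negative"))))
  fit <- glmqc(dat, spec)
  cw <- effect_curve(fit, "w")
  expect_true(all(diff(cw) <= 1e-12) && all(cw <= 1e-12))
  cx <- effect_curve(fit, "x1")
  expect_true(all(diff(cx) >= -1e-12) && all(cx >= -1e-12))
  S <- effect_surface(fit, "w:x1")
  expect_equal(dim(S), c(4L, 3L))
  expect_true(all(S[1, ] == 0) && all(S[, 1] == 0))
  # double increments bounded nonpositive
  dd <- diff(t(diff(S)))
  expect_true(all(dd <= 1e-12))
})
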