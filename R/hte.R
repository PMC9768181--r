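# Heterogeneous treatment effects from a fitted constrained GLM, the
# ordinal-treatment convention (one-level increase, capped at the top), the
# two-component consensus ensemble, and the log-odds-ratio construction
# that makes black-box component predictions comparable to logit-model
# coefficients.

#' Treatment plan: one-level increase of an ordinal treatment
#'
#' The scenario treatment level is the observed level plus one; individuals
#' already at the top level are "capped" and receive a treatment effect of
#' exactly zero.
#'
#' @param treatment Treatment variable name.
#' @param n_levels Number of ordinal treatment levels `K_w`.
#' @return An object of class `qc_treatment_plan`.
#' @export
treatment_plan <- function(treatment, n_levels) {
  stopifnot(is.character(treatment), length(treatment) == 1L, n_levels >= 2)
  structure(list(treatment = treatment, n_levels = as.integer(n_levels)),
            class = "qc_treatment_plan")
}

plan_levels <- function(plan, data) {
  w_obs <- data[[plan$treatment]]
  if (is.null(w_obs)) stop("treatment column '", plan$treatment, "' missing")
  w_obs <- as.integer(w_obs)
  if (any(w_obs < 1L | w_obs > plan$n_levels, na.rm = TRUE))
    stop("treatment level outside 1..", plan$n_levels)
  list(w_obs = w_obs,
       w_s = pmin(w_obs + 1L, plan$n_levels),
       capped = w_obs == plan$n_levels)
}

#' S-learner treatment effects from a fitted constrained GLM
#'
#' Predicts the outcome with the treatment set to the observed level and to
#' one level higher (all other covariates held fixed) and takes the
#' difference on the response scale.  Capped individuals get exactly zero.
#' For binomial outcomes the log odds ratio (the difference of linear
#' predictors) is also returned, `NA` for capped individuals.
#'
#' @param fit A `glmqc_fit` whose specification includes the treatment.
#' @param data Data frame to evaluate on.
#' @param plan A [treatment_plan()]; defaults to the fitted spec's treatment
#'   variable with its declared number of levels.
#' @return A data frame of class `qc_hte` with columns `tau` (response-scale
#'   effect), `lnor` (link-scale effect; binomial only), `w_obs`, `capped`.
#' @export
tau_slearner <- function(fit, data, plan = NULL) {
  spec <- fit$spec
  if (is.null(plan)) {
    tv <- spec$variables[[spec$treatment]]
    plan <- treatment_plan(spec$treatment, qc_n_levels(tv))
  }
  lv <- plan_levels(plan, data)
  data0 <- data
  data1 <- data
  data0[[plan$treatment]] <- lv$w_obs
  data1[[plan$treatment]] <- lv$w_s
  eta0 <- predict(fit, data0, type = "link")
  eta1 <- predict(fit, data1, type = "link")
  if (fit$family == "binomial") {
    tau <- stats::plogis(eta1) - stats::plogis(eta0)
    lnor <- eta1 - eta0
    lnor[lv$capped] <- NA_real_
  } else {
    tau <- eta1 - eta0
    lnor <- rep(NA_real_, length(tau))
  }
  tau[lv$capped] <- 0
  structure(data.frame(tau = tau, lnor = lnor, w_obs = lv$w_obs,
                       capped = lv$capped),
            class = c("qc_hte", "data.frame"),
            source = "glmqc_slearner")
}

#' Consensus combination of two effect-estimate vectors
#'
#' The ensemble prediction is the component average unless the average is
#' within `q` disagreement-based standard deviations of zero, in which case
#' it is set to 0: with `avg = (a + b)/2` and `sigma = |a - b|/2`, the
#' output is `0` where `|avg| <= q * sigma`, else `avg`.
#'
#' @param tau_a,tau_b Per-individual effect estimates from two components.
#' @param q Consensus constant (default `sqrt(2)`).
#' @return Numeric vector of consensus estimates.
#' @export
ensemble_consensus <- function(tau_a, tau_b, q = sqrt(2)) {
  if (length(tau_a) != length(tau_b))
    stop("component vectors have different lengths")
  stopifnot(q >= 0)
  avg <- (tau_a + tau_b) / 2
  sigma <- abs(tau_a - tau_b) / 2
  ifelse(abs(avg) <= q * sigma, 0, avg)
}

#' Component predictions container
#'
#' Two kinds of component outputs are supported when reconstructing outcome
#' probabilities at arbitrary treatment levels:
#' * `"posterior-draw"`: a named list `draws` mapping treatment level to an
#'   `n x n_draws` matrix of outcome-probability draws; the probability at a
#'   level is the mean over draws.
#' * `"constant-effect"`: fitted outcome `y_hat_obs` at the observed level
#'   plus a per-individual effect `tau_hat` constant across levels; the
#'   probability at level `w` is extrapolated as
#'   `y_hat_obs - (w - w_obs) * tau_hat` (the printed convention;
#'   `extrapolation_sign = +1` switches to the conventional first-order
#'   extrapolation `y_hat_obs + (w - w_obs) * tau_hat`).
#'
#' @param kind `"posterior-draw"` or `"constant-effect"`.
#' @param w_obs Observed treatment levels.
#' @param y_hat_obs Fitted outcome probability at the observed level
#'   (constant-effect kind).
#' @param tau_hat Per-individual constant effect (constant-effect kind).
#' @param draws Named list of `n x n_draws` probability matrices keyed by
#'   treatment level (posterior-draw kind).
#' @param extrapolation_sign `-1` (default, printed convention) or `+1`.
#' @return An object of class `qc_component`.
#' @export
component_predictions <- function(kind = c("constant-effect", "posterior-draw"),
                                  w_obs, y_hat_obs = NULL, tau_hat = NULL,
                                  draws = NULL, extrapolation_sign = -1) {
  kind <- match.arg(kind)
  w_obs <- as.integer(w_obs)
  if (kind == "constant-effect") {
    stopifnot(!is.null(y_hat_obs), !is.null(tau_hat),
              length(y_hat_obs) == length(w_obs),
              length(tau_hat) == length(w_obs))
    if (any(y_hat_obs < 0 | y_hat_obs > 1))
      stop("y_hat_obs must be probabilities in [0, 1]")
  } else {
    stopifnot(is.list(draws), length(draws) >= 1L)
    nd <- vapply(draws, ncol, integer(1))
    if (length(unique(nd)) != 1L)
      stop("draw counts must be equal across levels")
    if (any(vapply(draws, function(m) any(m < 0 | m > 1), logical(1))))
      stop("draws must be probabilities in [0, 1]")
  }
  if (!extrapolation_sign %in% c(-1, 1))
    stop("extrapolation_sign must be -1 or +1")
  structure(list(kind = kind, w_obs = w_obs, y_hat_obs = y_hat_obs,
                 tau_hat = tau_hat, draws = draws,
                 extrapolation_sign = extrapolation_sign),
            class = "qc_component")
}

#' Component outcome probability at a treatment level
#'
#' @param pred A [component_predictions()] object.
#' @param w Target treatment level: a scalar or per-individual vector.
#' @param clip Clip probabilities into `[clip, 1 - clip]` (default `1e-6`)
#'   so downstream log odds stay finite.
#' @return Probability vector.
#' @export
component_prob_at <- function(pred, w, clip = 1e-6) {
  if (!inherits(pred, "qc_component")) stop("pred must be a qc_component")
  n <- length(pred$w_obs)
  w <- as.integer(rep_len(w, n))
  if (pred$kind == "posterior-draw") {
    lv <- sort(unique(w))
    miss <- setdiff(as.character(lv), names(pred$draws))
    if (length(miss))
      stop("no posterior draws stored for level(s) ",
           paste(miss, collapse = ", "))
    p <- numeric(n)
    for (l in lv) {
      idx <- which(w == l)
      p[idx] <- rowMeans(pred$draws[[as.character(l)]][idx, , drop = FALSE])
    }
  } else {
    p <- pred$y_hat_obs +
      pred$extrapolation_sign * (w - pred$w_obs) * pred$tau_hat
  }
  pmin(pmax(p, clip), 1 - clip)
}

#' Log odds ratios of a two-component ensemble under a treatment plan
#'
#' Averages the two components' outcome probabilities at the observed and
#' one-higher treatment level and returns the per-individual log odds ratio
#' `ln[(p_s / (1 - p_s)) / (p_0 / (1 - p_0))]`.  Capped individuals (already
#' at the top level) are excluded (`NA`).
#'
#' @param pred_a,pred_b Two [component_predictions()] objects on the same
#'   individuals.
#' @param plan A [treatment_plan()].
#' @param clip Probability clipping bound (default `1e-6`).
#' @return Numeric vector of log odds ratios, `NA` for capped individuals.
#' @export
lnor_from_components <- function(pred_a, pred_b, plan, clip = 1e-6) {
  if (length(pred_a$w_obs) != length(pred_b$w_obs))
    stop("components cover different numbers of individuals")
  if (!identical(pred_a$w_obs, pred_b$w_obs))
    stop("components disagree on observed treatment levels")
  w_obs <- pred_a$w_obs
  capped <- w_obs == plan$n_levels
  w_s <- pmin(w_obs + 1L, plan$n_levels)
  p0 <- 0.5 * component_prob_at(pred_a, w_obs, clip) +
    0.5 * component_prob_at(pred_b, w_obs, clip)
  ps <- 0.5 * component_prob_at(pred_a, w_s, clip) +
    0.5 * component_prob_at(pred_b, w_s, clip)
  p0 <- pmin(pmax(p0, clip), 1 - clip)
  ps <- pmin(pmax(ps, clip), 1 - clip)
  lnor <- log(ps / (1 - ps)) - log(p0 / (1 - p0))
  if (anyNA(lnor)) stop("NaN produced in log odds ratio computation")
  lnor[capped] <- NA_real_
  lnor
}

#' Percentage of strictly positive values
#'
#' Diagnostic used on treatment-effect or log-odds-ratio vectors: estimated
#' positive effects of an activity increase on disease risk run against the
#' qualitative expectation and may indicate confounding.  Zeros do not
#' count as positive; `NA`s (e.g. capped individuals) are dropped.
#'
#' @param x Numeric vector.
#' @return Percentage in `[0, 100]`.
#' @export
pct_positive <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input")
  100 * sum(x > 0) / length(x)
}
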