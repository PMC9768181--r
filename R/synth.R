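# Synthetic confounded health-survey populations with an ordinal
# physical-activity treatment, binary disease outcomes from a known
# logistic structural model, and exact per-individual ground-truth
# treatment effects.  This is the test bed standing in for individual-level
# survey data that cannot be redistributed.

AGE_EDGES <- c(18, 35, 50, 65, 120)
BMI_EDGES <- c(10, 22.5, 25, 30, 60)

#' Default structural outcome models
#'
#' Two binary disease outcomes (`diabetes`, `ihd`) on the logit scale:
#' monotone increasing risk in age band and BMI band, positive smoking /
#' second-hand smoke / male effects, and a decreasing nonpositive
#' physical-activity curve whose effect is amplified multiplicatively by
#' moderators (age band for both outcomes, smoking for diabetes), so the
#' activity benefit grows with age and with smoking.  A moderator is either
#' a scalar coefficient on a zero-referenced moderator score (linear
#' moderation: `coef * score`, with score `age_band` in 0..3 or the 0/1
#' indicator itself) or a by-level vector.  All magnitudes are synthetic
#' (chosen to give realistic disease prevalences and effect sizes, not
#' estimated from any survey); every curve satisfies its own declared
#' qualitative constraint, which is checked at construction.
#'
#' @return Named list of outcome model definitions.
#' @export
default_outcome_models <- function() {
  list(
    diabetes = list(
      intercept = -3.4,
      age_curve = c(0, 0.7, 1.2, 1.6),     # increasing, positive
      bmi_curve = c(0, 0.4, 0.9, 1.4),     # increasing, positive
      gender = 0.15, smoking = 0.35, secondhand = 0.20,
      t_curve = c(0, -0.25, -0.45, -0.60), # decreasing, nonpositive
      moderators = list(age = 0.25, smoking = 0.50)),
    ihd = list(
      intercept = -3.8,
      age_curve = c(0, 0.8, 1.5, 2.1),
      bmi_curve = c(0, 0.3, 0.7, 1.1),
      gender = 0.35, smoking = 0.45, secondhand = 0.15,
      t_curve = c(0, -0.20, -0.40, -0.55),
      moderators = list(age = 0.20)))
}

check_outcome_model <- function(m, name) {
  stopifnot(is.finite(m$intercept))
  if (any(diff(m$age_curve) < 0) || any(m$age_curve < 0))
    stop("outcome '", name, "': age curve must be increasing and nonnegative")
  if (any(diff(m$bmi_curve) < 0) || any(m$bmi_curve < 0))
    stop("outcome '", name, "': bmi curve must be increasing and nonnegative")
  if (any(diff(m$t_curve) > 0) || any(m$t_curve > 0))
    stop("outcome '", name, "': treatment curve must be decreasing and nonpositive")
  for (nm in names(m$moderators)) {
    mod <- m$moderators[[nm]]
    if (any(mod < 0) || (length(mod) > 1L && any(diff(mod) < 0)))
      stop("outcome '", name, "': moderator '", nm,
           "' must be nonnegative (and nondecreasing if by-level)")
  }
  invisible(TRUE)
}

#' Synthetic-population configuration
#'
#' @param n Population size.
#' @param treatment_marginals Target marginal distribution of the 4-level
#'   physical-activity treatment (inactive, insufficiently active, active,
#'   very active); default `c(0.18, 0.45, 0.10, 0.27)`.
#' @param confounding Strength of the ordinal-logit dependence of treatment
#'   assignment on the latent health index (0 = randomized assignment;
#'   default 1: healthier individuals exercise more).
#' @param bmi_age_cor Scaling knob for the age slope inside the BMI
#'   generator (0 = independent; default 1).
#' @param outcomes Named list of structural outcome models (default
#'   [default_outcome_models()]).
#' @param seed Default seed used by [synth_population()] when none is given.
#' @return An object of class `qc_synth_config`.
#' @export
synth_config <- function(n, treatment_marginals = c(0.18, 0.45, 0.10, 0.27),
                         confounding = 1, bmi_age_cor = 1,
                         outcomes = default_outcome_models(), seed = 1L) {
  stopifnot(n >= 1, length(treatment_marginals) == 4L,
            all(treatment_marginals > 0),
            abs(sum(treatment_marginals) - 1) < 1e-8,
            confounding >= 0)
  for (nm in names(outcomes)) check_outcome_model(outcomes[[nm]], nm)
  structure(list(n = as.integer(n), treatment_marginals = treatment_marginals,
                 confounding = confounding, bmi_age_cor = bmi_age_cor,
                 outcomes = outcomes, seed = as.integer(seed)),
            class = "qc_synth_config")
}

# zero-referenced moderator score for linear moderation
moderator_score <- function(nm, cov) {
  switch(nm,
         age = cov$age_level - 1L,
         smoking = cov$smoking,
         secondhand = cov$secondhand,
         trust = cov$trust - 1L,
         stop("unknown moderator '", nm, "'"))
}

# linear predictor of the structural model at a fixed treatment level w
structural_eta <- function(m, cov, w) {
  modsum <- rep(0, nrow(cov))
  for (nm in names(m$moderators)) {
    mod <- m$moderators[[nm]]
    if (length(mod) == 1L) {
      modsum <- modsum + mod * moderator_score(nm, cov)
    } else {
      modsum <- modsum + mod[moderator_score(nm, cov) + 1L]
    }
  }
  m$intercept +
    m$age_curve[cov$age_level] + m$bmi_curve[cov$bmi_level] +
    m$gender * cov$gender + m$smoking * cov$smoking +
    m$secondhand * cov$secondhand +
    m$t_curve[w] * (1 + modsum)
}

#' Generate a synthetic confounded survey population
#'
#' Draws covariates, assigns the ordinal treatment through a
#' proportional-odds logit on a latent health index (intercepts calibrated
#' by root finding so the marginal treatment shares hit their targets at
#' any confounding strength), draws binary outcomes from the structural
#' logistic models, and records the exact ground truth: outcome
#' probabilities at every treatment level, per-individual treatment effects
#' of a one-level activity increase (zero at the cap), and the
#' corresponding log odds ratios.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to the config's seed).
#' @return An object of class `qc_population`: `data` (covariates,
#'   `activity` treatment, one 0/1 column per outcome) and `truth` (per
#'   outcome: `tau`, `lnor`, `prob` matrix `n x 4`).
#' @export
synth_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "qc_synth_config"))
  set.seed(as.integer(seed))
  n <- config$n

  age <- pmin(pmax(stats::rnorm(n, 45, 17), 18), 89.9)
  gender <- stats::rbinom(n, 1L, 0.5)
  bmi <- pmin(pmax(27 + config$bmi_age_cor * 0.08 * (age - 45) +
                     stats::rnorm(n, 0, 4.5), 16), 45)
  smoking <- stats::rbinom(n, 1L, 0.30)
  secondhand <- stats::rbinom(n, 1L, 0.25)
  alcohol <- sample.int(4L, n, replace = TRUE,
                        prob = c(0.60, 0.25, 0.10, 0.05))
  fruitveg <- sample.int(5L, n, replace = TRUE,
                         prob = c(0.10, 0.20, 0.30, 0.25, 0.15))
  trust <- sample.int(4L, n, replace = TRUE, prob = c(0.30, 0.40, 0.20, 0.10))
  education <- pmin(pmax(round(stats::rnorm(n, 9, 4)), 0), 18)
  income <- stats::runif(n)
  region <- sample.int(5L, n, replace = TRUE)

  # latent health index driving confounded treatment assignment
  h <- -0.6 * (age - 45) / 17 - 0.5 * (bmi - 27) / 4.5 - 0.5 * smoking +
    0.4 * (income - 0.5) + 0.3 * (education - 9) / 4
  h <- (h - mean(h)) / stats::sd(h)

  cum_target <- cumsum(config$treatment_marginals)[1:3]
  conf <- config$confounding
  theta <- vapply(cum_target, function(ct) {
    if (conf == 0) return(stats::qlogis(ct))
    stats::uniroot(function(t) mean(stats::plogis(t - conf * h)) - ct,
                   interval = c(-30, 30), tol = 1e-10)$root
  }, numeric(1))
  if (any(diff(theta) <= 0))
    stop("infeasible marginal calibration: achieved cutpoints not increasing")
  cumprob <- vapply(theta, function(t) stats::plogis(t - conf * h),
                    numeric(n))
  u <- stats::runif(n)
  activity <- 1L + rowSums(u > cumprob)

  cov <- data.frame(
    age = age, gender = gender, bmi = bmi, smoking = smoking,
    secondhand = secondhand, alcohol = alcohol, fruitveg = fruitveg,
    trust = trust, education = education, income = income, region = region,
    age_level = findInterval(age, AGE_EDGES, rightmost.closed = TRUE),
    bmi_level = findInterval(bmi, BMI_EDGES, rightmost.closed = TRUE))

  truth <- list()
  data <- cov[, c("age", "gender", "bmi", "smoking", "secondhand",
                  "alcohol", "fruitveg", "trust", "education", "income",
                  "region")]
  data$age_band <- cov$age_level - 1L   # zero-based band score (moderation)
  data$activity <- activity
  for (nm in names(config$outcomes)) {
    m <- config$outcomes[[nm]]
    eta <- vapply(1:4, function(w) structural_eta(m, cov, w), numeric(n))
    prob <- stats::plogis(eta)
    y <- stats::rbinom(n, 1L, prob[cbind(seq_len(n), activity)])
    capped <- activity == 4L
    ws <- pmin(activity + 1L, 4L)
    tau <- prob[cbind(seq_len(n), ws)] - prob[cbind(seq_len(n), activity)]
    tau[capped] <- 0
    lnor <- eta[cbind(seq_len(n), ws)] - eta[cbind(seq_len(n), activity)]
    lnor[capped] <- NA_real_
    data[[nm]] <- y
    truth[[nm]] <- list(tau = tau, lnor = lnor, prob = prob)
  }

  structure(list(data = data, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "qc_population")
}

#' @export
print.qc_population <- function(x, ...) {
  cat("Synthetic survey population: n = ", nrow(x$data),
      ", outcomes: ", paste(names(x$truth), collapse = ", "), "\n", sep = "")
  cat("  treatment shares:",
      paste(sprintf("%.3f", tabulate(x$data$activity, 4L) / nrow(x$data)),
            collapse = " "), "\n")
  invisible(x)
}

#' Naive outcome contrasts vs. true average treatment effects
#'
#' For each adjacent treatment pair, compares the naive observed outcome
#' rate difference between the two treatment groups with the true
#' population average effect of moving one level.  Under confounded
#' assignment the naive contrast is biased; the gap quantifies the
#' confounding the estimation methodology must overcome.
#'
#' @param population A `qc_population`.
#' @param outcome Outcome name (default: the first).
#' @return Data frame with one row per adjacent pair: `naive`, `true_ate`,
#'   `gap`.
#' @export
naive_vs_adjusted_gap <- function(population, outcome = NULL) {
  if (is.null(outcome)) outcome <- names(population$truth)[1L]
  y <- population$data[[outcome]]
  w <- population$data$activity
  prob <- population$truth[[outcome]]$prob
  out <- lapply(1:3, function(k) {
    n0 <- sum(w == k); n1 <- sum(w == k + 1L)
    if (n0 == 0L || n1 == 0L)
      stop("empty treatment stratum at level ", if (n0 == 0L) k else k + 1L)
    naive <- mean(y[w == k + 1L]) - mean(y[w == k])
    true_ate <- mean(prob[, k + 1L] - prob[, k])
    data.frame(from = k, to = k + 1L, naive = naive, true_ate = true_ate,
               gap = naive - true_ate)
  })
  do.call(rbind, out)
}

#' Model specification matching the synthetic structural model
#'
#' The "correctly specified" qualitatively constrained model for a default
#' synthetic outcome: discretized age and BMI with increasing positive
#' curves, positive binary risk factors, a decreasing nonpositive
#' physical-activity curve, and treatment-moderator interactions matching
#' the generator (the activity step increments scale linearly with the
#' zero-based moderator score, bounded so the activity effect gets more
#' negative as the moderator increases).
#'
#' @param outcome `"diabetes"` or `"ihd"`.
#' @param constrained Kept for convenience: `FALSE` returns the same terms
#'   with every constraint dropped (the unconstrained benchmark spec).
#' @return A [qc_model_spec()].
#' @export
default_outcome_spec <- function(outcome = c("diabetes", "ihd"),
                                 constrained = TRUE) {
  outcome <- match.arg(outcome)
  cc <- function(m, s) if (constrained) qc_constraint(m, s) else qc_constraint()
  variables <- list(
    qc_variable("activity", "ordinal", n_levels = 4),
    qc_variable("age", "continuous-discretized", bin_edges = AGE_EDGES),
    qc_variable("bmi", "continuous-discretized", bin_edges = BMI_EDGES),
    qc_variable("age_band", "continuous-linear"),
    qc_variable("gender", "binary"),
    qc_variable("smoking", "binary"),
    qc_variable("secondhand", "binary"))
  terms <- list(
    qc_term("activity", cc("decreasing", "negative")),
    qc_term("age", cc("increasing", "positive")),
    qc_term("bmi", cc("increasing", "positive")),
    qc_term("gender", cc("none", "positive")),
    qc_term("smoking", cc("none", "positive")),
    qc_term("secondhand", cc("none", "positive")),
    qc_term(c("age_band", "activity"), cc("decreasing", "negative")))
  if (outcome == "diabetes")
    terms <- c(terms, list(
      qc_term(c("smoking", "activity"), cc("decreasing", "negative"))))
  qc_model_spec(outcome = outcome, family = "binomial",
                treatment = "activity", variables = variables, terms = terms)
}

#' True effect curves of a default synthetic outcome, by model term
#'
#' Ground-truth values, on the link scale and relative to each term's
#' reference, of every term in [default_outcome_spec()] under a generator
#' configuration — the oracle for parameter-recovery checks.  Interaction
#' blocks are returned as the cumulative moderation curve (the extra
#' activity effect per unit moderator score at levels `2..K_w`).
#'
#' @param config A [synth_config()].
#' @param outcome Outcome name.
#' @return Named list of numeric vectors matching [effect_curve()] /
#'   recovered block coefficients.
#' @export
true_parameter_curves <- function(config, outcome) {
  m <- config$outcomes[[outcome]]
  if (is.null(m)) stop("no outcome '", outcome, "' in the configuration")
  out <- list(
    activity = m$t_curve,
    age = m$age_curve,
    bmi = m$bmi_curve,
    gender = m$gender, smoking = m$smoking, secondhand = m$secondhand)
  tx_steps <- m$t_curve[-1L]   # t(w) - t(ref), ref level 1
  for (nm in names(m$moderators)) {
    coef <- m$moderators[[nm]]
    if (length(coef) != 1L)
      stop("true_parameter_curves() supports linear (scalar) moderators")
    lab <- if (nm == "age") "age_band:activity" else paste0(nm, ":activity")
    out[[lab]] <- coef * tx_steps
  }
  out
}
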