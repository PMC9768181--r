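# Shared helpers: independent oracles and fixture builders.

# Penalized negative log-likelihood of the solver's objective (gaussian:
# half RSS) -- used both to evaluate solver output and inside the generic
# box-constrained oracle.
objective_value <- function(par, X, y, family, intercept, ridge = 0) {
  if (intercept) {
    alpha <- par[1L]; beta <- par[-1L]
  } else {
    alpha <- 0; beta <- par
  }
  eta <- drop(alpha + X %*% beta)
  base <- if (family == "gaussian") {
    0.5 * sum((y - eta)^2)
  } else {
    -sum(y * eta - log1p(exp(eta)))
  }
  base + 0.5 * ridge * sum(beta^2)
}

objective_grad <- function(par, X, y, family, intercept, ridge = 0) {
  if (intercept) {
    alpha <- par[1L]; beta <- par[-1L]
  } else {
    alpha <- 0; beta <- par
  }
  eta <- drop(alpha + X %*% beta)
  mu <- if (family == "gaussian") eta else stats::plogis(eta)
  gb <- -drop(crossprod(X, y - mu)) + ridge * beta
  if (intercept) c(-sum(y - mu), gb) else gb
}

# Generic box-constrained maximum-likelihood oracle via L-BFGS-B.
oracle_box_fit <- function(X, y, family, lower, upper, intercept = TRUE,
                           ridge = 0) {
  p <- ncol(X)
  lo <- if (intercept) c(-Inf, lower) else lower
  up <- if (intercept) c(Inf, upper) else upper
  start <- rep(0, p + as.integer(intercept))
  fit <- stats::optim(start, objective_value, gr = objective_grad,
                      X = X, y = y, family = family, intercept = intercept,
                      ridge = ridge, method = "L-BFGS-B",
                      lower = lo, upper = up,
                      control = list(maxit = 2000, factr = 1e3))
  fit
}

# Wrap a raw matrix + bounds as a minimal design so qc_fit can run on
# instances that do not come from a model specification.
raw_design <- function(Z, bounds, family = "binomial", intercept = TRUE) {
  colnames(Z) <- paste0("x", seq_len(ncol(Z)))
  structure(list(Z = Z, bounds = bounds, blocks = list(), n = nrow(Z),
                 spec = list(family = family, intercept = intercept)),
            class = "qc_design")
}

# Random sign-bound pattern
random_bounds <- function(p) sample(c("ge", "le", "free"), p, replace = TRUE)

# Effect curve implied by step coefficients under the coding used for a
# monotone case; independent re-derivation by enumeration over levels
# (cumulative sums away from the reference end).
curve_by_enumeration <- function(zeta, K, ref_end) {
  e <- numeric(K)
  if (ref_end == 1L) {
    for (l in 2:K) e[l] <- sum(zeta[seq_len(l - 1L)])
  } else {
    for (l in seq_len(K - 1L)) e[l] <- sum(zeta[seq_len(K - l)])
  }
  e
}

# Draw a feasible step-coefficient vector for a constraint case
random_feasible_zeta <- function(K, bounds) {
  z <- stats::runif(K - 1L, 0, 2)
  z[bounds == "le"] <- -z[bounds == "le"]
  z[bounds == "free"] <- stats::rnorm(sum(bounds == "free"))
  z
}

all_monotone_cases <- function() {
  list(qc_constraint("increasing", "positive"),
       qc_constraint("increasing", "negative"),
       qc_constraint("decreasing", "positive"),
       qc_constraint("decreasing", "negative"),
       qc_constraint("increasing", "unrestricted"),
       qc_constraint("decreasing", "unrestricted"))
}

# Small survey-like frame for design/fit fixtures
tiny_survey <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(
    x1 = sample(1:3, n, replace = TRUE),
    x2 = sample(1:3, n, replace = TRUE),
    w = sample(1:4, n, replace = TRUE),
    z = rnorm(n),
    b = rbinom(n, 1, 0.5),
    y = rbinom(n, 1, 0.4))
}
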