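#' Fitting configuration
#'
#' @param ridge_epsilon Small nonnegative ridge penalty added for numerical
#'   stability (default `1e-8`; the qualitative constraints, not shrinkage,
#'   are the intended regularizer).
#' @param tol Relative deviance-change convergence tolerance (default `1e-9`).
#' @param max_iter Cap on coordinate-descent sweeps per reweighting step
#'   (default 10000).
#' @param standardize Standardize columns by a positive scale before fitting
#'   (default `TRUE`).  Positive scaling preserves the sign bounds; recovered
#'   coefficients are returned on the original scale.
#' @return An object of class `qc_fit_config`.
#' @export
qc_fit_config <- function(ridge_epsilon = 1e-8, tol = 1e-9,
                          max_iter = 10000L, standardize = TRUE) {
  stopifnot(ridge_epsilon >= 0, tol > 0, max_iter >= 1)
  structure(list(ridge_epsilon = ridge_epsilon, tol = tol,
                 max_iter = as.integer(max_iter),
                 standardize = isTRUE(standardize)),
            class = "qc_fit_config")
}

bounds_to_box <- function(bounds) {
  lower <- ifelse(bounds == "ge", 0, -Inf)
  upper <- ifelse(bounds == "le", 0, Inf)
  list(lower = lower, upper = upper)
}

#' Fit a sign-bounded reparametrized GLM on a prebuilt design
#'
#' Low-level fitting routine: penalized maximum likelihood under
#' per-coefficient sign bounds, by cyclic coordinate descent on the IRLS
#' quadratic approximation (gaussian outcomes reduce to plain box-constrained
#' least squares).  Most users call [glmqc()] instead.
#'
#' @param design A `qc_design` from [build_design()].
#' @param y Outcome vector (0/1 for binomial).
#' @param family `"binomial"` or `"gaussian"`; defaults to the family of the
#'   design's spec.
#' @param config A [qc_fit_config()].
#' @param constrained If `FALSE`, drop every sign bound (unconstrained
#'   benchmark on the identical design).
#' @return An object of class `glmqc_fit`.
#' @export
qc_fit <- function(design, y, family = NULL, config = qc_fit_config(),
                   constrained = TRUE) {
  if (!inherits(design, "qc_design")) stop("design must be a qc_design")
  if (is.null(family)) family <- design$spec$family
  Z <- design$Z
  n <- nrow(Z); p <- ncol(Z)
  if (length(y) != n) stop("length(y) = ", length(y),
                           " does not match design rows ", n)
  if (anyNA(y)) stop("outcome contains missing values (row ",
                     which(is.na(y))[1L], ")")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial outcome must be coded 0/1")
  bounds <- design$bounds
  if (!constrained) bounds <- rep("free", p)
  box <- bounds_to_box(bounds)

  scales <- rep(1, p)
  if (config$standardize) {
    s <- apply(Z, 2L, stats::sd)
    scales[s > 0] <- s[s > 0]
  }
  const_col <- apply(Z, 2L, function(col) all(col == col[1L])) &
    apply(Z, 2L, function(col) any(col != 0))
  if (any(const_col)) {
    warning("degenerate constant column(s) dropped: ",
            paste(colnames(Z)[const_col], collapse = ", "))
    box$lower[const_col] <- 0
    box$upper[const_col] <- 0
  }
  Zs <- sweep(Z, 2L, scales, "/")

  fam_code <- if (family == "binomial") 1L else 0L
  has_int <- design$spec$intercept
  if (has_int) {
    Zs <- cbind(`(Intercept)` = 1, Zs)
    lower <- c(-Inf, box$lower); upper <- c(Inf, box$upper)
    ridge <- c(0, rep(config$ridge_epsilon, p))
  } else {
    lower <- box$lower; upper <- box$upper
    ridge <- rep(config$ridge_epsilon, p)
  }
  res <- cd_box_glm(Zs, as.numeric(y), fam_code, lower, upper, ridge,
                    config$tol, config$max_iter)
  if (!res$converged)
    warning("solver did not converge within iteration cap; ",
            "returning current iterate (deviance ", format(res$deviance), ")")
  coef_std <- res$beta
  alpha <- if (has_int) coef_std[1L] else 0
  zeta_std <- if (has_int) coef_std[-1L] else coef_std
  grad_std <- if (has_int) res$gradient[-1L] else res$gradient
  zeta <- zeta_std / scales          # original (unstandardized) column scale
  names(zeta) <- colnames(Z)
  # exact zeros on the boundary
  at_bound <- (bounds == "ge" & zeta_std <= 0) |
    (bounds == "le" & zeta_std >= 0)
  zeta[at_bound & abs(zeta) < 1e-12] <- 0

  blocks <- design$blocks
  beta <- lapply(blocks, function(blk)
    recover_coefficients(zeta[blk$cols], blk$A))

  fit <- structure(list(
    alpha = alpha, zeta = zeta, bounds = bounds, beta = beta,
    family = family, deviance = res$deviance, n_iter = res$n_outer,
    converged = res$converged, active_bound = at_bound & bounds != "free",
    gradient = grad_std * scales,  # d(objective)/d(original-scale coef)
    constrained = constrained, blocks = blocks,
    spec = design$spec, config = config,
    n = n,
    data_fingerprint = c(n = n, ybar = mean(y),
                         yhash = sum(as.numeric(y) * seq_len(n)) %% 1e9)),
    class = "glmqc_fit")
  fit
}

#' Fit a qualitatively constrained GLM
#'
#' Builds the reparametrized design from `data` and `spec` and fits it under
#' the declared sign and monotonicity constraints.  Original-scale
#' coefficients are recovered from the working (step) coefficients by
#' multiplying with the per-term coding matrices.
#'
#' @param data Data frame containing the outcome and all term variables.
#' @param spec A [qc_model_spec()].
#' @param config A [qc_fit_config()].
#' @param constrained If `FALSE`, fit the unconstrained benchmark GLM on the
#'   identical design.
#' @return An object of class `glmqc_fit`.
#' @examples
#' pop <- synth_population(synth_config(n = 2000), seed = 1)
#' spec <- default_outcome_spec("diabetes")
#' fit <- glmqc(pop$data, spec)
#' effect_curve(fit, "activity")
#' @export
glmqc <- function(data, spec, config = qc_fit_config(), constrained = TRUE) {
  if (!spec$outcome %in% names(data))
    stop("outcome column '", spec$outcome, "' is missing from the data")
  design <- build_design(data, spec)
  y <- data[[spec$outcome]]
  qc_fit(design, y, family = spec$family, config = config,
         constrained = constrained)
}

#' @export
print.glmqc_fit <- function(x, ...) {
  cat("Qualitatively constrained GLM fit (", x$family, ")\n", sep = "")
  cat("  n = ", x$n, ", deviance = ", format(x$deviance),
      ", converged = ", x$converged, "\n", sep = "")
  cat("  intercept = ", format(x$alpha), "\n", sep = "")
  cat("  active sign bounds: ", sum(x$active_bound), " of ",
      sum(x$bounds != "free"), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted constrained GLM
#'
#' @param object A `glmqc_fit`.
#' @param newdata Data frame to predict on (design rebuilt from the stored
#'   specification).
#' @param type `"link"` for the linear predictor, `"response"` for the
#'   identity/antilogit-transformed mean.
#' @param design Optionally a prebuilt `qc_design` (bypasses `newdata`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.glmqc_fit <- function(object, newdata = NULL,
                              type = c("link", "response"),
                              design = NULL, ...) {
  type <- match.arg(type)
  if (is.null(design)) {
    if (is.null(newdata)) stop("supply newdata or a prebuilt design")
    design <- build_design(newdata, object$spec)
  }
  if (ncol(design$Z) != length(object$zeta) ||
      !identical(colnames(design$Z), names(object$zeta)))
    stop("design columns do not match the fitted model")
  eta <- drop(object$alpha + design$Z %*% object$zeta)
  if (type == "link") return(eta)
  if (object$family == "binomial") stats::plogis(eta) else eta
}

#' Effect curve of a main-effect term
#'
#' Returns the fitted effect at every level of a coded main-effect term,
#' relative to (and pinned at zero at) its reference level.  For monotone
#' terms this is the cumulative sum of the fitted step coefficients.
#'
#' @param fit A `glmqc_fit`.
#' @param term Term label (the variable name for main effects).
#' @return Numeric vector of length `K` (levels in order); for single-column
#'   terms, the single slope coefficient.
#' @export
effect_curve <- function(fit, term) {
  blk <- fit$blocks[[term]]
  if (is.null(blk)) stop("term '", term, "' is not in the model")
  beta <- fit$beta[[term]]
  if (blk$type %in% c("main-linear", "int-linear")) return(unname(beta))
  if (!blk$type %in% c("main-step", "main-dummy"))
    stop("term '", term, "' is an interaction; use effect_surface()")
  curve_from_beta(beta, blk$K[1L], blk$ref[1L])
}

#' Interaction effect surface of a two-way coded term
#'
#' @param fit A `glmqc_fit`.
#' @param term Term label, e.g. `"activity:age"`.
#' @return Matrix `K1 x K2` of interaction effects (zero along both
#'   reference slices).
#' @export
effect_surface <- function(fit, term) {
  blk <- fit$blocks[[term]]
  if (is.null(blk)) stop("term '", term, "' is not in the model")
  if (blk$type != "int-kron")
    stop("term '", term, "' is not a coded two-way interaction")
  gam <- fit$beta[[term]]
  K1 <- blk$K[1L]; K2 <- blk$K[2L]
  G <- matrix(0, K1, K2)
  nr1 <- setdiff(seq_len(K1), blk$ref[1L])
  nr2 <- setdiff(seq_len(K2), blk$ref[2L])
  # gamma is vectorized with the first variable's index outer
  idx <- 0L
  for (a in nr1) for (b in nr2) {
    idx <- idx + 1L
    G[a, b] <- gam[idx]
  }
  G
}

#' Deviance gap between a constrained fit and its unconstrained benchmark
#'
#' The feasible set of the constrained fit is a subset of the unconstrained
#' one, so the gap is nonnegative up to solver tolerance; its size measures
#' how strongly the qualitative constraints regularize the fit.
#'
#' @param fit_constrained,fit_unconstrained Two `glmqc_fit`s on the same
#'   data and design.
#' @return The deviance difference (constrained minus unconstrained).
#' @export
deviance_compare <- function(fit_constrained, fit_unconstrained) {
  f1 <- fit_constrained$data_fingerprint
  f2 <- fit_unconstrained$data_fingerprint
  if (!isTRUE(all.equal(f1, f2)))
    stop("fits were not computed on the same data")
  gap <- fit_constrained$deviance - fit_unconstrained$deviance
  if (gap < -1e-6 * (abs(fit_unconstrained$deviance) + 1))
    warning("constrained deviance below unconstrained: solver tolerance issue")
  gap
}
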