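#' Declare a model variable
#'
#' A variable declaration describes how a raw data column enters the design:
#' as a single numeric column (`binary`, `continuous-linear`), or as a coded
#' block over ordered or unordered levels (`ordinal`, `categorical`,
#' `continuous-discretized`).
#'
#' @param name Column name in the data.
#' @param kind One of `"binary"`, `"categorical"`, `"ordinal"`,
#'   `"continuous-linear"`, `"continuous-discretized"`.
#' @param bin_edges Strictly increasing numeric cut points (length `K + 1`)
#'   for `continuous-discretized` variables.  Bins are half-open `[lo, hi)`
#'   with the last bin closed on the right; out-of-range values are clamped
#'   into the end bins with a warning.
#' @param levels Ordered level labels for `categorical`/`ordinal` variables.
#'   For `ordinal` variables declared without labels, `n_levels` may be given
#'   instead and levels are taken to be the integers `1..K`.
#' @param n_levels Number of ordinal levels when `levels` is not supplied.
#' @param reference Reference level (label, or level index for ordinal
#'   variables).  Defaults to the first level.  For monotone constraints the
#'   reference must be an end level compatible with the requested sign
#'   (see [qc_constraint()]).
#' @param transform For `continuous-linear` variables, a named univariate
#'   transform applied before design assembly: `"identity"` (default) or
#'   `"min-cap"` (values capped at `cap`, i.e. `pmin(x, cap)`).
#' @param cap Cap value when `transform = "min-cap"`.
#' @return An object of class `qc_variable`.
#' @export
qc_variable <- function(name,
                        kind = c("binary", "categorical", "ordinal",
                                 "continuous-linear", "continuous-discretized"),
                        bin_edges = NULL, levels = NULL, n_levels = NULL,
                        reference = NULL, transform = "identity", cap = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous-discretized") {
    if (is.null(bin_edges) || length(bin_edges) < 3L)
      stop("variable '", name, "': continuous-discretized needs >= 3 bin edges")
    if (any(diff(bin_edges) <= 0))
      stop("variable '", name, "': bin_edges must be strictly increasing")
    levels <- as.character(seq_len(length(bin_edges) - 1L))
  }
  if (kind == "ordinal" && is.null(levels)) {
    if (is.null(n_levels)) stop("variable '", name, "': ordinal needs levels or n_levels")
    levels <- as.character(seq_len(n_levels))
  }
  if (kind == "binary") levels <- c("0", "1")
  if (kind == "categorical" && (is.null(levels) || length(levels) < 2L))
    stop("variable '", name, "': categorical needs >= 2 levels")
  if (!is.null(levels)) {
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("variable '", name, "': duplicated levels")
    if (length(levels) < 2L) stop("variable '", name, "': needs K >= 2 levels")
  }
  if (kind == "continuous-linear") {
    if (!transform %in% c("identity", "min-cap"))
      stop("variable '", name, "': unknown transform '", transform, "'")
    if (transform == "min-cap" && (is.null(cap) || !is.finite(cap)))
      stop("variable '", name, "': min-cap transform needs a finite cap")
    levels <- NULL
  }
  ref_idx <- NULL
  if (!is.null(levels)) {
    if (is.null(reference)) reference <- levels[1L]
    ref_idx <- match(as.character(reference), levels)
    if (is.na(ref_idx))
      stop("variable '", name, "': reference '", reference,
           "' is not among the declared levels")
  }
  structure(list(name = name, kind = kind, bin_edges = bin_edges,
                 levels = levels, reference = ref_idx,
                 transform = transform, cap = cap),
            class = "qc_variable")
}

#' Qualitative constraint on a term's effect
#'
#' Combines a monotonicity requirement on the effect curve over ordered
#' levels with a sign requirement relative to the reference level.  The six
#' monotone combinations map onto sign bounds for incremental (step)
#' coefficients; `monotonicity = "none"` with a sign gives sign-bounded dummy
#' coding, and `("none", "unrestricted")` is the unconstrained case.
#'
#' For a monotone curve pinned at zero at its reference level, sign and
#' monotonicity jointly determine which end the reference must be:
#' an increasing positive (or decreasing negative) curve is referenced at the
#' first level; an increasing negative (or decreasing positive) curve at the
#' last.  Monotone-unrestricted constraints leave the first step free, so the
#' curve over the non-reference levels is monotone while its position
#' relative to the reference is not restricted.
#'
#' @param monotonicity `"none"`, `"increasing"` or `"decreasing"`.
#' @param sign `"unrestricted"`, `"positive"` or `"negative"`.
#' @return An object of class `qc_constraint`.
#' @export
qc_constraint <- function(monotonicity = c("none", "increasing", "decreasing"),
                          sign = c("unrestricted", "positive", "negative")) {
  monotonicity <- match.arg(monotonicity)
  sign <- match.arg(sign)
  structure(list(monotonicity = monotonicity, sign = sign),
            class = "qc_constraint")
}

#' Model term: main effect or two-way interaction
#'
#' @param variables Character vector of 1 (main effect) or 2 (interaction)
#'   declared variable names.
#' @param constraint A [qc_constraint()].  For interactions the constraint
#'   applies to the joint incremental surface: with a monotone constraint,
#'   every double increment (difference-in-difference) of the interaction
#'   surface away from the two references is sign-bounded.
#' @return An object of class `qc_term`.
#' @export
qc_term <- function(variables, constraint = qc_constraint()) {
  variables <- as.character(variables)
  if (!length(variables) %in% 1:2)
    stop("a term references 1 or 2 variables, got ", length(variables))
  if (length(variables) == 2L && variables[1L] == variables[2L])
    stop("interaction terms need two distinct variables")
  if (!inherits(constraint, "qc_constraint")) stop("constraint must be a qc_constraint")
  structure(list(variables = variables, constraint = constraint),
            class = "qc_term")
}

#' Full model specification
#'
#' @param outcome Outcome column name.  `binomial` outcomes are 0/1 and use
#'   the logit link; `gaussian` outcomes use the identity link.
#' @param family `"binomial"` or `"gaussian"`.
#' @param treatment Name of the ordinal treatment variable (levels `1..K_w`).
#'   Must appear in at least one term.
#' @param variables List of [qc_variable()] declarations.
#' @param terms List of [qc_term()]s.
#' @param intercept Include an intercept (default `TRUE`).
#' @return An object of class `qc_model_spec`.
#' @export
qc_model_spec <- function(outcome, family = c("binomial", "gaussian"),
                          treatment, variables, terms, intercept = TRUE) {
  family <- match.arg(family)
  if (inherits(variables, "qc_variable")) variables <- list(variables)
  if (inherits(terms, "qc_term")) terms <- list(terms)
  vnames <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(vnames)) stop("duplicated variable declarations")
  names(variables) <- vnames
  for (tm in terms) {
    miss <- setdiff(tm$variables, vnames)
    if (length(miss))
      stop("term references undeclared variable(s): ", paste(miss, collapse = ", "))
  }
  if (!treatment %in% vnames)
    stop("treatment variable '", treatment, "' is not declared")
  in_any <- any(vapply(terms, function(tm) treatment %in% tm$variables, logical(1)))
  if (!in_any)
    stop("treatment variable '", treatment, "' does not appear in any term")
  tv <- variables[[treatment]]
  if (!tv$kind %in% c("ordinal", "continuous-discretized", "binary"))
    stop("treatment variable must be ordinal (or binary)")
  structure(list(outcome = outcome, family = family, treatment = treatment,
                 variables = variables, terms = terms,
                 intercept = isTRUE(intercept)),
            class = "qc_model_spec")
}

#' @export
print.qc_model_spec <- function(x, ...) {
  cat("Qualitatively constrained GLM specification\n")
  cat("  outcome:  ", x$outcome, " (", x$family, ")\n", sep = "")
  cat("  treatment:", x$treatment, "\n")
  cat("  variables:", length(x$variables), " terms:", length(x$terms), "\n")
  for (tm in x$terms) {
    cc <- tm$constraint
    cat("   - ", paste(tm$variables, collapse = " x "),
        " [", cc$monotonicity, ", ", cc$sign, "]\n", sep = "")
  }
  invisible(x)
}

# number of levels of a coded variable (NULL for single-column kinds)
qc_n_levels <- function(v) {
  if (is.null(v$levels)) NULL else length(v$levels)
}

# TRUE if the variable enters as a coded block rather than a single column
qc_is_coded <- function(v) {
  v$kind %in% c("categorical", "ordinal", "continuous-discretized")
}
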