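#' Discretize a continuous variable into ordinal levels
#'
#' Maps values into the half-open bins `[edge_k, edge_{k+1})` defined by a
#' `continuous-discretized` variable declaration; the last bin is closed on
#' the right.  Values outside the outer edges are clamped into the end bins
#' with a warning (survey data routinely contain outliers).
#'
#' @param values Numeric vector; all values must be finite.
#' @param spec A [qc_variable()] with `kind = "continuous-discretized"`.
#' @return Integer vector of levels in `1..K`.
#' @export
discretize <- function(values, spec) {
  if (!inherits(spec, "qc_variable") || spec$kind != "continuous-discretized")
    stop("discretize() needs a continuous-discretized qc_variable")
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("variable '", spec$name, "': non-finite value at row ", bad[1L])
  edges <- spec$bin_edges
  K <- length(edges) - 1L
  lev <- findInterval(values, edges, rightmost.closed = TRUE)
  n_out <- sum(lev < 1L | lev > K)
  if (n_out > 0L) {
    warning("variable '", spec$name, "': ", n_out,
            " value(s) outside [", edges[1L], ", ", edges[K + 1L],
            ") clamped into end bins")
    lev <- pmin(pmax(lev, 1L), K)
  }
  as.integer(lev)
}

# Map raw data column -> integer levels 1..K for a coded variable.
qc_levels_of <- function(x, v) {
  if (v$kind == "continuous-discretized") return(discretize(x, v))
  lev <- match(as.character(x), v$levels)
  if (anyNA(lev)) {
    i <- which(is.na(lev))[1L]
    stop("variable '", v$name, "': unseen level '", as.character(x)[i],
         "' at row ", i)
  }
  as.integer(lev)
}

# Resolve the reference end and per-step sign bounds for a monotone case.
# Steps are counted *away from the reference end*: with reference at the
# first level, step m crosses from level m to m+1; with reference at the
# last level, step m crosses from level K-m+1 down to K-m.
#
# Returns list(ref_end = 1 or K, bounds = per-step "ge"/"le"/"free").
step_coding_info <- function(K, case, reference = NULL) {
  if (K < 2L) stop("monotone coding needs K >= 2")
  mono <- case$monotonicity
  sgn <- case$sign
  stopifnot(mono %in% c("increasing", "decreasing"))
  required_end <- switch(sgn,
    positive = if (mono == "increasing") 1L else K,
    negative = if (mono == "increasing") K else 1L,
    unrestricted = NA_integer_)
  ref_end <- reference
  if (is.null(ref_end) || is.na(ref_end)) {
    ref_end <- if (is.na(required_end)) 1L else required_end
  }
  if (!ref_end %in% c(1L, K))
    stop("monotone constraints require an end reference level (1 or K), got ",
         ref_end)
  if (!is.na(required_end) && ref_end != required_end)
    stop("a (", mono, ", ", sgn, ") effect pinned at zero at its reference ",
         "requires the reference to be level ", required_end,
         " of ", K, ", got ", ref_end)
  # direction of the curve as steps move away from the reference
  away_sign <- if (ref_end == 1L) {
    if (mono == "increasing") "ge" else "le"
  } else {
    if (mono == "increasing") "le" else "ge"
  }
  bounds <- rep(away_sign, K - 1L)
  if (sgn == "unrestricted") bounds[1L] <- "free"
  list(ref_end = as.integer(ref_end), bounds = bounds)
}

# Coding matrix A (K-1 x K-1) mapping step coefficients (away from the
# reference end) to effect-curve values at the non-reference levels, listed
# in level order.  beta = A %*% zeta.
step_coding_matrix <- function(K, ref_end) {
  m <- K - 1L
  A <- matrix(0, m, m)
  if (ref_end == 1L) {
    # non-reference levels 2..K; e(l) = sum_{k <= l-1} s_k
    A[lower.tri(A, diag = TRUE)] <- 1
  } else {
    # non-reference levels 1..K-1; e(l) = sum_{m <= K-l} s_m
    for (l in seq_len(m)) A[l, seq_len(K - l)] <- 1
  }
  A
}

#' Incremental (step) coding of an ordinal variable under a monotone case
#'
#' Codes levels `1..K` into `K - 1` cumulative step indicators counted away
#' from the constraint's reference end, so that each coefficient is the
#' increment of the effect curve across one pair of consecutive levels and a
#' sign bound on the coefficients enforces monotonicity of the curve.
#'
#' @param levels Integer vector of levels in `1..K`.
#' @param K Number of levels.
#' @param case A [qc_constraint()] with monotone `monotonicity`.
#' @param reference Optional end level (1 or `K`); defaults to the end
#'   implied by the case.
#' @return List with `Z` (n x K-1 matrix), `bounds` (per-column `"ge"`,
#'   `"le"` or `"free"`), `A` (coding matrix), `ref_end`.
#' @export
encode_incremental <- function(levels, K, case, reference = NULL) {
  if (K < 2L) stop("incremental coding needs K >= 2")
  if (!inherits(case, "qc_constraint") || case$monotonicity == "none")
    stop("encode_incremental() needs a monotone constraint case")
  levels <- as.integer(levels)
  if (any(levels < 1L | levels > K, na.rm = TRUE))
    stop("levels outside 1..", K)
  info <- step_coding_info(K, case, reference)
  n <- length(levels)
  Z <- matrix(0, n, K - 1L)
  if (info$ref_end == 1L) {
    for (m in seq_len(K - 1L)) Z[, m] <- as.numeric(levels > m)
  } else {
    for (m in seq_len(K - 1L)) Z[, m] <- as.numeric(levels <= K - m)
  }
  colnames(Z) <- paste0("step", seq_len(K - 1L))
  list(Z = Z, bounds = info$bounds,
       A = step_coding_matrix(K, info$ref_end), ref_end = info$ref_end)
}

#' Dummy (one-hot minus reference) coding of a categorical/ordinal variable
#'
#' @param levels Integer vector of levels in `1..K`.
#' @param K Number of levels.
#' @param reference Reference level in `1..K`.
#' @param sign `"unrestricted"`, `"positive"` or `"negative"`: a shared sign
#'   bound on every non-reference category effect relative to the reference.
#' @return List with `Z` (n x K-1), `bounds`, `A` (identity), `non_ref`
#'   (level index of each column).
#' @export
encode_dummy <- function(levels, K, reference = 1L,
                         sign = "unrestricted") {
  if (K < 2L) stop("dummy coding needs K >= 2")
  reference <- as.integer(reference)
  if (!reference %in% seq_len(K)) stop("reference must lie in 1..", K)
  levels <- as.integer(levels)
  if (any(levels < 1L | levels > K, na.rm = TRUE))
    stop("levels outside 1..", K)
  non_ref <- setdiff(seq_len(K), reference)
  Z <- vapply(non_ref, function(k) as.numeric(levels == k),
              numeric(length(levels)))
  Z <- matrix(Z, nrow = length(levels))
  colnames(Z) <- paste0("lvl", non_ref)
  bound <- switch(sign, positive = "ge", negative = "le", "free")
  list(Z = Z, bounds = rep(bound, K - 1L), A = diag(K - 1L),
       non_ref = non_ref)
}

#' Recover original-scale coefficients from working (step) coefficients
#'
#' Main-effect blocks recover `beta = A %*% zeta`; interaction blocks recover
#' the vectorized surface `gamma = (A_j %x% A_k) %*% eta`.  The inverse map
#' `zeta = solve(A, beta)` round-trips exactly (A is triangular with unit
#' diagonal).
#'
#' @param working Numeric vector of working coefficients for one block.
#' @param A Block coding matrix (possibly a Kronecker product).
#' @return Numeric vector of original-scale coefficients.
#' @export
recover_coefficients <- function(working, A) {
  if (length(working) != ncol(A))
    stop("working coefficient length ", length(working),
         " does not match block width ", ncol(A))
  drop(A %*% working)
}

# Effect curve over all K levels (reference pinned at 0) from the
# original-scale coefficients of a main-effect block.
curve_from_beta <- function(beta, K, ref_level) {
  e <- numeric(K)
  e[setdiff(seq_len(K), ref_level)] <- beta
  e
}
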