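# Budget-constrained selection by benefit-to-cost ratio, multi-outcome
# benefit aggregation, benefit-capture curves, and model-vs-truth
# targeting-efficiency reports.

#' Select individuals under a budget by benefit-to-cost ratio
#'
#' Sorts individuals by `score / cost` in decreasing order (stable: ties
#' keep input order) and selects down the list until the budget
#' (`budget_fraction * sum(costs)`) is exhausted.  The last individual is
#' included only if fully affordable.  Individuals with nonpositive
#' estimated benefit remain eligible while budget remains, unless
#' `stop_at_nonpositive = TRUE`.
#'
#' @param score Per-individual estimated total benefit (higher = target
#'   first).
#' @param budget_fraction Fraction of total cost available, in `(0, 1]`.
#' @param costs Per-individual positive costs (default all 1).
#' @param stop_at_nonpositive Stop selecting once the marginal score drops
#'   to zero or below (default `FALSE`: the ranking covers everyone).
#' @return Integer vector of selected row indices (in selection order).
#' @export
select_targets <- function(score, budget_fraction, costs = NULL,
                           stop_at_nonpositive = FALSE) {
  n <- length(score)
  if (any(!is.finite(score))) stop("scores must be finite")
  if (is.null(costs)) costs <- rep(1, n)
  if (length(costs) != n) stop("costs length mismatch")
  if (any(costs <= 0)) stop("costs must be positive")
  if (!(budget_fraction > 0 && budget_fraction <= 1))
    stop("budget_fraction must lie in (0, 1]")
  budget <- budget_fraction * sum(costs)
  ord <- order(-(score / costs))           # stable: ties keep input order
  cum <- cumsum(costs[ord])
  keep <- cum <= budget + 1e-9
  if (stop_at_nonpositive) keep <- keep & score[ord] > 0
  sel <- ord[keep]
  if (!length(sel))
    warning("budget too small to afford any individual: empty selection")
  sel
}

#' Fraction of attainable benefit captured by a selection
#'
#' @param truth Per-individual true benefits (nonnegative reductions).
#' @param selected Integer indices of the selected individuals.
#' @return `sum(truth[selected]) / sum(truth)`.
#' @export
captured_fraction <- function(truth, selected) {
  if (any(truth < 0)) stop("true benefits must be nonnegative reductions")
  tot <- sum(truth)
  if (tot <= 0) stop("zero total benefit: captured fraction undefined")
  sum(truth[selected]) / tot
}

#' Total per-individual benefit over multiple outcomes
#'
#' Benefits are reductions: an effect `tau < 0` (disease probability drops)
#' is a positive benefit, so the total is `sum_d weight_d * (-tau_d)`.
#'
#' @param tau_by_outcome List (or data frame) of per-outcome effect vectors.
#' @param weights Nonnegative outcome weights (default equal).
#' @return Numeric vector of total benefits.
#' @export
total_benefit <- function(tau_by_outcome, weights = NULL) {
  tau_by_outcome <- as.list(tau_by_outcome)
  d <- length(tau_by_outcome)
  if (is.null(weights)) weights <- rep(1, d)
  if (length(weights) != d) stop("one weight per outcome required")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  ns <- lengths(tau_by_outcome)
  if (length(unique(ns)) != 1L) stop("effect vectors have different lengths")
  out <- numeric(ns[1L])
  for (j in seq_len(d)) out <- out + weights[j] * (-tau_by_outcome[[j]])
  out
}

#' Benefit-capture curve of a score vector
#'
#' @param score Estimated per-individual benefit used for ranking.
#' @param truth True nonnegative benefits.
#' @param fractions Grid of budget fractions.
#' @param costs Per-individual costs (default unit).
#' @return Data frame `fraction`, `captured`.
#' @export
benefit_capture_curve <- function(score, truth,
                                  fractions = seq(0.05, 1, by = 0.05),
                                  costs = NULL) {
  captured <- vapply(fractions, function(f) {
    sel <- suppressWarnings(select_targets(score, f, costs))
    if (!length(sel)) 0 else captured_fraction(truth, sel)
  }, numeric(1))
  data.frame(fraction = fractions, captured = captured)
}

#' Targeting-efficiency report across models
#'
#' For each candidate score vector and each budget fraction, computes the
#' fraction of the total attainable benefit captured, together with a
#' "perfect" baseline (ranking by the truth itself) and a "random" baseline
#' (mean over seeded uniformly random selections).  A `pct_adverse`
#' diagnostic reports the percentage of individuals each model scores as
#' harmed (estimated benefit strictly negative).
#'
#' @param models Named list of per-individual benefit score vectors.
#' @param truth True nonnegative benefit vector.
#' @param fractions Budget-fraction grid (default `c(0.1, 0.25, 0.5)`).
#' @param costs Per-individual costs (default unit).
#' @param n_random Random-baseline replicates (default 100).
#' @param seed Seed for the random baseline (default 1).
#' @return List with `table` (model x fraction captured fractions, long
#'   format), `curves`, and `diagnostics`.
#' @export
efficiency_report <- function(models, truth, fractions = c(0.1, 0.25, 0.5),
                              costs = NULL, n_random = 100L, seed = 1L) {
  stopifnot(is.list(models), length(models) >= 1L,
            !is.null(names(models)), all(nzchar(names(models))))
  n <- length(truth)
  for (nm in names(models))
    if (length(models[[nm]]) != n)
      stop("model '", nm, "' score length does not match truth")
  all_scores <- c(models, list(perfect = truth))
  rows <- list()
  for (nm in names(all_scores)) {
    cc <- benefit_capture_curve(all_scores[[nm]], truth, fractions, costs)
    rows[[nm]] <- data.frame(model = nm, cc)
  }
  # random baseline: mean captured fraction over uniform selections
  if (is.null(costs)) costs_ <- rep(1, n) else costs_ <- costs
  rand <- vapply(fractions, function(f) {
    set.seed(seed)
    mean(vapply(seq_len(n_random), function(r) {
      sc <- stats::runif(n)
      sel <- suppressWarnings(select_targets(sc, f, costs_))
      if (!length(sel)) 0 else captured_fraction(truth, sel)
    }, numeric(1)))
  }, numeric(1))
  rows[["random"]] <- data.frame(model = "random",
                                 fraction = fractions, captured = rand)
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  diagnostics <- data.frame(
    model = names(models),
    pct_adverse = vapply(models, function(s) pct_positive(-s), numeric(1)))
  rownames(diagnostics) <- NULL
  list(table = table, curves = table, diagnostics = diagnostics)
}
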