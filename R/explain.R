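# Global additive surrogate of per-individual effect estimates (lnOR or
# tau) over covariates: piecewise-constant shape functions on binned
# features fitted by cyclic boosting, plus a small number of greedily
# selected pairwise terms on level grids.  The surrogate's importance
# ranking is what proposes new treatment-interaction terms for the
# constrained model.

# Bin a covariate column: factors/characters and low-cardinality numerics
# use their observed levels; continuous features are cut at quantiles.
surrogate_bin <- function(x, n_bins = 16L) {
  if (is.factor(x) || is.character(x) || length(unique(x)) <= n_bins) {
    lev <- sort(unique(x))
    list(index = match(x, lev), labels = as.character(lev),
         ordered = is.numeric(x))
  } else {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE, type = 7))
    idx <- findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
    list(index = idx, labels = paste0("[", format(qs[-length(qs)], digits = 4),
                                      ",", format(qs[-1], digits = 4), ")"),
         ordered = TRUE)
  }
}

group_means <- function(values, index, n_groups) {
  s <- numeric(n_groups); cnt <- numeric(n_groups)
  t1 <- tapply(values, index, sum)
  t2 <- tapply(values, index, length)
  ix <- as.integer(names(t1))
  s[ix] <- t1; cnt[ix] <- t2
  m <- numeric(n_groups)
  m[cnt > 0] <- s[cnt > 0] / cnt[cnt > 0]
  list(mean = m, count = cnt)
}

#' Fit a global additive surrogate with pairwise terms
#'
#' Cyclic boosting of depth-one piecewise-constant updates over binned
#' features (round-robin, shrunk by `learning_rate`), followed by greedy
#' addition of the `n_pairs` feature pairs with the highest
#' residual-variance reduction, fitted on their level grids.  Shape
#' functions are mean-centered over the training population; the constant
#' mass moves into the intercept.  Term importance is the mean absolute
#' contribution over the training rows.
#'
#' @param target Numeric vector to explain (per-individual lnOR or tau).
#' @param covariates Data frame of features (no missing values).
#' @param n_pairs Number of pairwise terms to add (default 5).
#' @param rounds Boosting rounds over the feature cycle (default 500).
#' @param learning_rate Shrinkage per update (default 0.1).
#' @param n_bins Quantile bins for continuous features (default 16).
#' @param seed Optional seed (the fit itself is deterministic; the seed
#'   guards any downstream permutation use).
#' @return An object of class `qc_surrogate`: shape functions, pairwise
#'   grids, intercept, importances, training fidelity R-squared.
#' @export
fit_surrogate <- function(target, covariates, n_pairs = 5L, rounds = 500L,
                          learning_rate = 0.1, n_bins = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(target))
  if (anyNA(target) || any(!is.finite(target)))
    stop("target contains missing or non-finite values")
  if (anyNA(covariates)) stop("covariates contain missing values")
  n <- length(target)
  feats <- names(covariates)
  bins <- lapply(covariates, surrogate_bin, n_bins = n_bins)
  nb <- vapply(bins, function(b) length(b$labels), integer(1))

  intercept <- mean(target)
  fitted <- rep(intercept, n)
  shapes <- lapply(nb, numeric)

  if (stats::var(target) == 0) {
    warning("constant target: surrogate has zero shapes and undefined ",
            "fidelity (reported as 0)")
    return(structure(list(features = feats, bins = bins, shapes = shapes,
                          pairs = list(), intercept = intercept,
                          importance = stats::setNames(rep(0, length(feats)), feats),
                          r_squared = 0, fitted = fitted),
                     class = "qc_surrogate"))
  }

  for (r in seq_len(rounds)) {
    for (j in seq_along(feats)) {
      resid <- target - fitted
      gm <- group_means(resid, bins[[j]]$index, nb[j])
      upd <- learning_rate * gm$mean
      shapes[[j]] <- shapes[[j]] + upd
      fitted <- fitted + upd[bins[[j]]$index]
    }
  }

  # greedy pairwise terms on the residual
  pairs <- list()
  if (n_pairs > 0L && length(feats) >= 2L) {
    resid <- target - fitted
    combs <- utils::combn(seq_along(feats), 2L)
    red <- numeric(ncol(combs))
    cell_index <- function(j, k)
      (bins[[j]]$index - 1L) * nb[k] + bins[[k]]$index
    for (ci in seq_len(ncol(combs))) {
      j <- combs[1L, ci]; k <- combs[2L, ci]
      idx <- cell_index(j, k)
      gm <- group_means(resid, idx, nb[j] * nb[k])
      red[ci] <- sum(gm$count * gm$mean^2)
    }
    take <- order(red, decreasing = TRUE)[seq_len(min(n_pairs, ncol(combs)))]
    for (ci in take) {
      j <- combs[1L, ci]; k <- combs[2L, ci]
      idx <- cell_index(j, k)
      resid <- target - fitted
      gm <- group_means(resid, idx, nb[j] * nb[k])
      grid <- matrix(gm$mean, nrow = nb[j], ncol = nb[k], byrow = TRUE)
      fitted <- fitted + gm$mean[idx]
      pairs[[paste(feats[j], feats[k], sep = ":")]] <-
        list(j = j, k = k, grid = grid)
    }
  }

  # mean-center every term over the training population
  contrib <- matrix(0, n, length(feats) + length(pairs))
  for (j in seq_along(feats)) {
    v <- shapes[[j]][bins[[j]]$index]
    mu <- mean(v)
    shapes[[j]] <- shapes[[j]] - mu
    intercept <- intercept + mu
    contrib[, j] <- v - mu
  }
  for (q in seq_along(pairs)) {
    pr <- pairs[[q]]
    idx <- (bins[[pr$j]]$index - 1L) * nb[pr$k] + bins[[pr$k]]$index
    v <- as.vector(t(pr$grid))[idx]
    mu <- mean(v)
    pairs[[q]]$grid <- pr$grid - mu
    intercept <- intercept + mu
    contrib[, length(feats) + q] <- v - mu
  }
  importance <- colMeans(abs(contrib))
  names(importance) <- c(feats, names(pairs))
  r2 <- 1 - stats::var(target - fitted) / stats::var(target)

  structure(list(features = feats, bins = bins, shapes = shapes,
                 pairs = pairs, intercept = intercept,
                 importance = importance, r_squared = r2, fitted = fitted),
            class = "qc_surrogate")
}

#' @export
print.qc_surrogate <- function(x, ...) {
  cat("Additive surrogate: ", length(x$features), " shape functions, ",
      length(x$pairs), " pairwise terms, R^2 = ",
      format(x$r_squared, digits = 4), "\n", sep = "")
  top <- sort(x$importance, decreasing = TRUE)
  top <- utils::head(top, 5L)
  cat("  top terms:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted surrogate (training rows)
#'
#' @param object A `qc_surrogate`.
#' @param ... Unused; the surrogate predicts its training rows (it is a
#'   population-level explanation, not a forecasting model).
#' @return Numeric vector.
#' @export
predict.qc_surrogate <- function(object, ...) object$fitted

#' Rank candidate treatment-interaction terms from a surrogate
#'
#' Orders features by surrogate importance, flags whether each already
#' interacts with the treatment in the current specification, and annotates
#' the empirical monotone direction of its shape function (sign of the
#' Spearman association between level index and shape value, for ordered
#' features).
#'
#' @param surrogate A `qc_surrogate` fitted on lnOR (or tau) over
#'   non-capped individuals.
#' @param current_spec A [qc_model_spec()].
#' @param include_existing Also list features that already interact with the
#'   treatment (default `FALSE`: candidates only, so the list is empty when
#'   every feature is already represented).
#' @return Data frame with columns `feature`, `importance`, `in_spec`,
#'   `direction` (`"increasing"`, `"decreasing"`, `"flat"`, or `NA` for
#'   unordered features), sorted by decreasing importance.
#' @export
rank_candidate_terms <- function(surrogate, current_spec,
                                 include_existing = FALSE) {
  feats <- surrogate$features
  tx <- current_spec$treatment
  interacts <- vapply(feats, function(f) {
    any(vapply(current_spec$terms, function(tm)
      length(tm$variables) == 2L && all(c(f, tx) %in% tm$variables),
      logical(1)))
  }, logical(1))
  direction <- vapply(seq_along(feats), function(j) {
    sh <- surrogate$shapes[[j]]
    if (!surrogate$bins[[j]]$ordered || length(sh) < 2L) return(NA_character_)
    if (all(sh == sh[1L])) return("flat")
    rho <- suppressWarnings(
      stats::cor(seq_along(sh), sh, method = "spearman"))
    if (is.na(rho) || rho == 0) "flat" else if (rho > 0) "increasing" else "decreasing"
  }, character(1))
  imp <- surrogate$importance[feats]
  out <- data.frame(feature = feats, importance = unname(imp),
                    in_spec = interacts, direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[out$feature != tx, , drop = FALSE]
  if (!include_existing) out <- out[!out$in_spec, , drop = FALSE]
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
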