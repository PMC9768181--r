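# Design assembly: turn a data table plus a qc_model_spec into the
# reparametrized (sign-bound) design matrix with per-term coding matrices.

term_label <- function(tm) paste(tm$variables, collapse = ":")

# Raw cumulative step indicators away from a reference end (no constraint
# semantics); used for interaction blocks where bounds live on the cells.
encode_steps_raw <- function(levels, K, ref_end) {
  n <- length(levels)
  Z <- matrix(0, n, K - 1L)
  if (ref_end == 1L) {
    for (m in seq_len(K - 1L)) Z[, m] <- as.numeric(levels > m)
  } else {
    for (m in seq_len(K - 1L)) Z[, m] <- as.numeric(levels <= K - m)
  }
  colnames(Z) <- paste0("step", seq_len(K - 1L))
  list(Z = Z, A = step_coding_matrix(K, ref_end), ref_end = ref_end)
}

# Single numeric column for binary / continuous-linear variables.
single_column_values <- function(x, v) {
  if (v$kind == "binary") {
    lev <- qc_levels_of(x, v)
    return(as.numeric(lev - 1L))
  }
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("variable '", v$name, "': non-finite value at row ", bad[1L])
  if (v$transform == "min-cap") pmin(x, v$cap) else as.numeric(x)
}

bound_from_sign <- function(sign) {
  switch(sign, positive = "ge", negative = "le", "free")
}

# Reference end used for a coded variable inside a monotone coding.  The
# declared reference is honoured; monotone *main* effects additionally
# require it to be the end compatible with the case (checked in
# step_coding_info).
declared_ref_end <- function(v, K) {
  r <- if (is.null(v$reference)) 1L else v$reference
  if (!r %in% c(1L, K))
    stop("variable '", v$name, "': monotone coding requires an end ",
         "reference level (1 or ", K, "), got ", r)
  r
}

# Build one term's block.  Returns list(Z, bounds, A, meta...).
build_term_block <- function(data, spec, tm) {
  cc <- tm$constraint
  vars <- lapply(tm$variables, function(nm) spec$variables[[nm]])
  for (nm in tm$variables) {
    if (!nm %in% names(data))
      stop("column '", nm, "' required by term '", term_label(tm),
           "' is missing from the data")
    x <- data[[nm]]
    bad <- which(is.na(x))
    if (length(bad))
      stop("variable '", nm, "': missing value at row ", bad[1L])
  }

  if (length(vars) == 1L) {
    v <- vars[[1L]]
    x <- data[[v$name]]
    if (!qc_is_coded(v)) {
      if (cc$monotonicity != "none")
        stop("variable '", v$name, "': a single-column (", v$kind,
             ") variable admits sign constraints only, not monotonicity")
      col <- single_column_values(x, v)
      return(list(Z = matrix(col, ncol = 1L,
                             dimnames = list(NULL, v$name)),
                  bounds = bound_from_sign(cc$sign),
                  A = matrix(1, 1L, 1L), type = "main-linear",
                  K = c(NA_integer_), ref = c(NA_integer_)))
    }
    K <- qc_n_levels(v)
    lev <- qc_levels_of(x, v)
    if (cc$monotonicity == "none") {
      ref <- if (is.null(v$reference)) 1L else v$reference
      enc <- encode_dummy(lev, K, reference = ref, sign = cc$sign)
      return(list(Z = enc$Z, bounds = enc$bounds, A = enc$A,
                  type = "main-dummy", K = K, ref = ref))
    }
    ref_end <- declared_ref_end(v, K)
    enc <- encode_incremental(lev, K, cc, reference = ref_end)
    return(list(Z = enc$Z, bounds = enc$bounds, A = enc$A,
                type = "main-step", K = K, ref = enc$ref_end))
  }

  ## two-way interaction
  coded <- vapply(vars, qc_is_coded, logical(1))
  xs <- lapply(vars, function(v) data[[v$name]])

  if (!any(coded)) {
    col <- single_column_values(xs[[1L]], vars[[1L]]) *
      single_column_values(xs[[2L]], vars[[2L]])
    if (cc$monotonicity != "none")
      stop("term '", term_label(tm),
           "': monotone constraints need at least one coded variable")
    return(list(Z = matrix(col, ncol = 1L,
                           dimnames = list(NULL, term_label(tm))),
                bounds = bound_from_sign(cc$sign),
                A = matrix(1, 1L, 1L), type = "int-linear",
                K = c(NA_integer_, NA_integer_),
                ref = c(NA_integer_, NA_integer_)))
  }

  if (sum(coded) == 1L) {
    vc <- vars[[which(coded)]]
    vl <- vars[[which(!coded)]]
    Kc <- qc_n_levels(vc)
    lev <- qc_levels_of(xs[[which(coded)]], vc)
    lin <- single_column_values(xs[[which(!coded)]], vl)
    if (cc$monotonicity == "none") {
      ref <- if (is.null(vc$reference)) 1L else vc$reference
      enc <- encode_dummy(lev, Kc, reference = ref, sign = cc$sign)
      Z <- enc$Z * lin
      colnames(Z) <- paste0(vl$name, ":", colnames(enc$Z))
      return(list(Z = Z, bounds = enc$bounds, A = enc$A,
                  type = "int-lin-dummy", K = c(NA_integer_, Kc),
                  ref = c(NA_integer_, ref)))
    }
    ref_end <- declared_ref_end(vc, Kc)
    enc <- encode_incremental(lev, Kc, cc, reference = ref_end)
    Z <- enc$Z * lin
    colnames(Z) <- paste0(vl$name, ":", colnames(enc$Z))
    return(list(Z = Z, bounds = enc$bounds, A = enc$A,
                type = "int-lin-step", K = c(NA_integer_, Kc),
                ref = c(NA_integer_, enc$ref_end)))
  }

  ## both coded
  K1 <- qc_n_levels(vars[[1L]]); K2 <- qc_n_levels(vars[[2L]])
  lev1 <- qc_levels_of(xs[[1L]], vars[[1L]])
  lev2 <- qc_levels_of(xs[[2L]], vars[[2L]])
  if (cc$monotonicity == "none") {
    r1 <- if (is.null(vars[[1L]]$reference)) 1L else vars[[1L]]$reference
    r2 <- if (is.null(vars[[2L]]$reference)) 1L else vars[[2L]]$reference
    e1 <- encode_dummy(lev1, K1, reference = r1, sign = cc$sign)
    e2 <- encode_dummy(lev2, K2, reference = r2, sign = cc$sign)
    A <- e1$A %x% e2$A
    refs <- c(r1, r2)
  } else {
    r1 <- declared_ref_end(vars[[1L]], K1)
    r2 <- declared_ref_end(vars[[2L]], K2)
    e1 <- encode_steps_raw(lev1, K1, r1)
    e2 <- encode_steps_raw(lev2, K2, r2)
    A <- e1$A %x% e2$A
    refs <- c(r1, r2)
  }
  p1 <- K1 - 1L; p2 <- K2 - 1L
  Z <- matrix(0, nrow(e1$Z), p1 * p2)
  cn <- character(p1 * p2)
  for (m in seq_len(p1)) for (l in seq_len(p2)) {
    idx <- (m - 1L) * p2 + l
    Z[, idx] <- e1$Z[, m] * e2$Z[, l]
    cn[idx] <- paste0(colnames(e1$Z)[m], ":", colnames(e2$Z)[l])
  }
  colnames(Z) <- cn
  if (cc$monotonicity == "none") {
    bounds <- rep(bound_from_sign(cc$sign), p1 * p2)
  } else {
    # cell bound = sign of the double increments of the surface; with an
    # unrestricted sign the cells touching either first step are free and
    # the remaining double increments follow the monotonicity direction
    cell <- if (cc$sign == "positive") "ge"
            else if (cc$sign == "negative") "le"
            else if (cc$monotonicity == "increasing") "ge" else "le"
    bounds <- rep(cell, p1 * p2)
    if (cc$sign == "unrestricted") {
      for (m in seq_len(p1)) for (l in seq_len(p2))
        if (m == 1L || l == 1L) bounds[(m - 1L) * p2 + l] <- "free"
    }
  }
  list(Z = Z, bounds = bounds, A = A, type = "int-kron",
       K = c(K1, K2), ref = refs)
}

#' Build the reparametrized design for a model specification
#'
#' Assembles, term by term, the sign-bounded design matrix of the
#' reparametrized model: monotone terms get incremental (step) coding,
#' unordered or shape-free terms dummy coding, and two-way interactions the
#' elementwise products of the two coded blocks with Kronecker-product
#' coding matrices.
#'
#' @param data Data frame with one row per individual.
#' @param spec A [qc_model_spec()].
#' @return An object of class `qc_design`: design matrix `Z`, per-column
#'   sign `bounds` (`"ge"`, `"le"`, `"free"`), per-term block metadata
#'   (coding matrix `A`, level counts, references, column indices).
#' @export
build_design <- function(data, spec) {
  if (!inherits(spec, "qc_model_spec")) stop("spec must be a qc_model_spec")
  if (!is.data.frame(data)) stop("data must be a data frame")
  if (nrow(data) == 0L) stop("data table is empty")
  blocks <- list()
  Zs <- list()
  bounds <- character(0)
  col_at <- 0L
  labels <- vapply(spec$terms, term_label, character(1))
  if (anyDuplicated(labels)) stop("duplicated terms: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  for (i in seq_along(spec$terms)) {
    tm <- spec$terms[[i]]
    blk <- build_term_block(data, spec, tm)
    p <- ncol(blk$Z)
    colnames(blk$Z) <- paste(labels[i], colnames(blk$Z), sep = ".")
    blk$cols <- col_at + seq_len(p)
    blk$label <- labels[i]
    blk$variables <- tm$variables
    blk$constraint <- tm$constraint
    col_at <- col_at + p
    Zs[[i]] <- blk$Z
    bounds <- c(bounds, blk$bounds)
    blk$Z <- NULL
    blocks[[labels[i]]] <- blk
  }
  Z <- do.call(cbind, Zs)
  structure(list(Z = Z, bounds = bounds, blocks = blocks,
                 n = nrow(Z), spec = spec),
            class = "qc_design")
}

#' @export
print.qc_design <- function(x, ...) {
  cat("Reparametrized design: ", x$n, " rows x ", ncol(x$Z), " columns, ",
      length(x$blocks), " term blocks\n", sep = "")
  invisible(x)
}
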