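# CSV / JSON / YAML readers and writers, specification serialization, run
# manifests, and the multi-model comparison report.

#' Read and validate an individual-level survey CSV
#'
#' Comma-separated, UTF-8, header mandatory, one row per individual.  When a
#' specification is supplied, all term and outcome columns must be present
#' and free of missing values, and categorical levels are validated.
#'
#' @param path File path.
#' @param spec Optional [qc_model_spec()] to validate against.
#' @return Data frame.
#' @export
read_survey_csv <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(data) == 0L) stop("empty survey file: ", path)
  if (!is.null(spec)) {
    needed <- unique(c(spec$outcome,
                       unlist(lapply(spec$terms, `[[`, "variables"))))
    miss <- setdiff(needed, names(data))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    for (nm in needed) {
      bad <- which(is.na(data[[nm]]))
      if (length(bad))
        stop("column '", nm, "': missing value at row ", bad[1L])
      v <- spec$variables[[nm]]
      if (!is.null(v) && qc_is_coded(v) && v$kind != "continuous-discretized")
        qc_levels_of(data[[nm]], v)     # errors on unseen levels
    }
  }
  data
}

## ---- specification serialization ----------------------------------------

spec_to_list <- function(spec) {
  list(
    outcome = spec$outcome, family = spec$family,
    treatment = spec$treatment, intercept = spec$intercept,
    variables = lapply(unname(spec$variables), function(v) {
      out <- list(name = v$name, kind = v$kind)
      if (!is.null(v$bin_edges)) out$bin_edges <- v$bin_edges
      if (!is.null(v$levels) && v$kind %in% c("categorical", "ordinal"))
        out$levels <- v$levels
      if (!is.null(v$reference) && !is.null(v$levels))
        out$reference <- v$levels[v$reference]
      if (!identical(v$transform, "identity")) {
        out$transform <- v$transform
        out$cap <- v$cap
      }
      out
    }),
    terms = lapply(spec$terms, function(tm)
      list(variables = tm$variables,
           monotonicity = tm$constraint$monotonicity,
           sign = tm$constraint$sign)))
}

spec_from_list <- function(x) {
  variables <- lapply(x$variables, function(v)
    qc_variable(name = v$name, kind = v$kind,
                bin_edges = unlist(v$bin_edges),
                levels = if (!is.null(v$levels)) unlist(v$levels),
                reference = v$reference,
                transform = if (is.null(v$transform)) "identity" else v$transform,
                cap = v$cap))
  terms <- lapply(x$terms, function(tm)
    qc_term(unlist(tm$variables),
            qc_constraint(tm$monotonicity, tm$sign)))
  qc_model_spec(outcome = x$outcome, family = x$family,
                treatment = x$treatment, variables = variables,
                terms = terms,
                intercept = if (is.null(x$intercept)) TRUE else x$intercept)
}

#' Read a model specification from JSON or YAML
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return A [qc_model_spec()].
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported spec format: .", ext)
  spec_from_list(x)
}

#' Write a model specification to JSON or YAML
#'
#' @param spec A [qc_model_spec()].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  x <- spec_to_list(spec)
  ext <- tolower(tools::file_ext(path))
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  if (ext == "json") {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, tmp)
  } else stop("unsupported spec format: .", ext)
  file.rename(tmp, path)
  invisible(path)
}

## ---- fitted-model serialization ------------------------------------------

#' Serialize a fitted model to JSON
#'
#' Stores the specification, working and original-scale coefficients,
#' bounds and diagnostics; [read_glmqc_fit()] restores an object usable for
#' prediction.
#'
#' @param fit A `glmqc_fit`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_glmqc_fit <- function(fit, path) {
  x <- list(
    spec = spec_to_list(fit$spec),
    alpha = fit$alpha,
    zeta = as.list(fit$zeta),
    bounds = fit$bounds,
    beta = lapply(fit$beta, as.numeric),
    family = fit$family, deviance = fit$deviance,
    n_iter = fit$n_iter, converged = fit$converged,
    constrained = fit$constrained, n = fit$n,
    data_fingerprint = as.list(fit$data_fingerprint))
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Restore a fitted model written by [write_glmqc_fit()]
#'
#' @param path `.json` path.
#' @return A `glmqc_fit` (block metadata rebuilt from the stored spec).
#' @export
read_glmqc_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- spec_from_list(x$spec)
  zeta <- unlist(x$zeta)
  # rebuild block metadata on a minimal two-row frame is fragile; instead
  # reconstruct coding matrices directly from the spec
  probe <- qc_design_skeleton(spec)
  fit <- structure(list(
    alpha = x$alpha, zeta = stats::setNames(zeta, names(x$zeta)),
    bounds = unlist(x$bounds),
    beta = lapply(x$beta, unlist),
    family = x$family, deviance = x$deviance, n_iter = x$n_iter,
    converged = isTRUE(x$converged), constrained = isTRUE(x$constrained),
    blocks = probe, spec = spec, n = x$n,
    data_fingerprint = unlist(x$data_fingerprint)),
    class = "glmqc_fit")
  fit
}

# Block metadata (coding matrices, widths, references) straight from the
# spec, without data: builds the design on a synthetic probe frame that
# contains every level.
qc_design_skeleton <- function(spec) {
  n_probe <- max(vapply(spec$variables, function(v)
    if (is.null(v$levels)) 2L else length(v$levels), integer(1)))
  probe <- list()
  for (v in spec$variables) {
    probe[[v$name]] <- switch(
      v$kind,
      binary = rep_len(c(0, 1), n_probe),
      categorical = ,
      ordinal = v$levels[rep_len(seq_along(v$levels), n_probe)],
      `continuous-linear` = seq_len(n_probe),
      `continuous-discretized` = {
        mids <- (utils::head(v$bin_edges, -1) + utils::tail(v$bin_edges, -1)) / 2
        rep_len(mids, n_probe)
      })
  }
  probe <- as.data.frame(probe)
  if (!is.null(spec$variables[[spec$treatment]]$levels) &&
      spec$variables[[spec$treatment]]$kind == "ordinal")
    probe[[spec$treatment]] <- as.numeric(probe[[spec$treatment]])
  build_design(probe, spec)$blocks
}

## ---- run manifests -------------------------------------------------------

#' Write a run manifest next to an output file
#'
#' Records the command, input-file fingerprints (MD5), seed and package
#' version so that deterministic runs can be audited and reproduced.
#'
#' @param out_path The output whose provenance is recorded; the manifest is
#'   written to `<out_path>.manifest.json`.
#' @param command Command label.
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed used (or `NA`).
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(out_path, command, inputs = character(0),
                           seed = NA_integer_) {
  fp <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    inputs = fp,
    seed = seed,
    package_version = as.character(utils::packageVersion("glmqc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- paste0(out_path, ".manifest.json")
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

## ---- comparison report ---------------------------------------------------

#' Multi-model targeting comparison report
#'
#' The machine-readable analogue of a model-comparison table: per model, a
#' summary of its terms and constraints, the captured benefit at each budget
#' fraction, and the adverse-effect percentage diagnostic.
#'
#' @param models Named list; each element is a list with `tau` (per-
#'   individual effect vector, reductions negative) and optionally `fit`
#'   (a `glmqc_fit`, used for the term/constraint summary).
#' @param truth True nonnegative benefit vector.
#' @param fractions Budget-fraction grid (default 0.25).
#' @return List of class `qc_report` with `table` (data frame) and
#'   `markdown` (character scalar).
#' @export
compare_report <- function(models, truth, fractions = 0.25) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  n <- length(truth)
  rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    tau <- m$tau
    if (length(tau) != n)
      stop("model '", nm, "': effect vector length ", length(tau),
           " does not match population size ", n)
    benefit <- -tau
    terms_summary <- constraint_summary <- NA_character_
    if (!is.null(m$fit)) {
      labs <- names(m$fit$blocks)
      terms_summary <- paste(labs, collapse = " + ")
      ccs <- vapply(m$fit$spec$terms, function(tm)
        paste0(tm$constraint$monotonicity, "/", tm$constraint$sign),
        character(1))
      constraint_summary <- if (m$fit$constrained)
        paste(unique(ccs), collapse = "; ") else "unconstrained"
    }
    for (f in fractions) {
      sel <- suppressWarnings(select_targets(benefit, f))
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, fraction = f,
        captured_benefit = if (length(sel)) captured_fraction(truth, sel) else 0,
        pct_adverse = pct_positive_or_zero(tau),
        terms = terms_summary, constraints = constraint_summary,
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  hdr <- "| model | fraction | captured benefit | % adverse |"
  sep <- "|---|---|---|---|"
  body <- sprintf("| %s | %.2f | %.1f%% | %.1f%% |", table$model,
                  table$fraction, 100 * table$captured_benefit,
                  table$pct_adverse)
  structure(list(table = table,
                 markdown = paste(c(hdr, sep, body), collapse = "\n")),
            class = "qc_report")
}

# pct_positive that tolerates an all-NA / empty vector (reports 0)
pct_positive_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(0)
  100 * sum(x > 0) / length(x)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}

#' Write a comparison report as JSON (lossless round trip)
#'
#' @param report A `qc_report`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(list(table = report$table), tmp, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read back a comparison report written by [write_report_json()]
#'
#' @param path `.json` path.
#' @return A `qc_report` (markdown regenerated).
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  table <- as.data.frame(x$table, stringsAsFactors = FALSE)
  for (col in c("terms", "constraints"))
    if (col %in% names(table)) table[[col]] <- as.character(table[[col]])
  hdr <- "| model | fraction | captured benefit | % adverse |"
  sep <- "|---|---|---|---|"
  body <- sprintf("| %s | %.2f | %.1f%% | %.1f%% |", table$model,
                  table$fraction, 100 * table$captured_benefit,
                  table$pct_adverse)
  structure(list(table = table,
                 markdown = paste(c(hdr, sep, body), collapse = "\n")),
            class = "qc_report")
}
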