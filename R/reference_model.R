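#' Prior sex probabilities
#'
#' Normalizes a prior specification into a named probability vector
#' `c(male = , female = )`. Accepts a ratio string such as `"1:1"` or
#' `"1.05:1"` (male:female), a numeric vector of two positive weights
#' (male, female), or an already-named vector.
#'
#' The default prior is 1:1, reflecting the adult sex ratio; a slightly
#' male-skewed 1.05:1 prior corresponds to the human sex ratio at birth and
#' changes posteriors only marginally.
#'
#' @param priors Ratio string, two positive weights, or named vector.
#' @return Named numeric vector `c(male, female)` summing to one.
#' @examples
#' parse_priors("1.05:1")
#' @export
parse_priors <- function(priors = "1:1") {
  if (is.character(priors)) {
    stopifnot(length(priors) == 1L)
    parts <- suppressWarnings(as.numeric(strsplit(priors, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2L || anyNA(parts)) {
      stop("prior ratio must look like \"1:1\" or \"1.05:1\"", call. = FALSE)
    }
    priors <- parts
  }
  priors <- as.numeric(priors)
  if (length(priors) != 2L || anyNA(priors) || any(priors <= 0)) {
    stop("priors must be two positive weights (male, female)", call. = FALSE)
  }
  p <- priors / sum(priors)
  names(p) <- c("male", "female")
  p
}

.group_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  list(
    n = n,
    mean = if (n >= 1L) mean(x) else NA_real_,
    sd = if (n >= 2L) stats::sd(x) else NA_real_,
    min = if (n >= 1L) min(x) else NA_real_,
    max = if (n >= 1L) max(x) else NA_real_
  )
}

#' Fit the per-sex reference distributions
#'
#' Computes, for every registry variable and each sex, the normal
#' distribution parameters (sample mean and standard deviation with
#' denominator n-1) on the model scale — i.e. after the natural-log
#' transform for log-flagged variables — together with the observation
#' count and range. These per-variable, per-sex normals are the shared
#' state of all three classifiers (Bayesian, logistic, cut-off).
#'
#' Measurement-level exclusions remove a single suspect value (for example
#' a presumed transcription error) from one variable's summary without
#' discarding the individual's other measurements. Variables ending up with
#' fewer than 2 observations in either sex remain in the registry but are
#' marked unusable and silently skipped during prediction.
#'
#' @param data Data frame, one row per individual, with a `sex` column
#'   (values `"M"`/`"F"`, or `"male"`/`"female"`), optionally `id`, and one
#'   column per observed variable (canonical registry names, mm scale,
#'   empty/NA = missing). Unknown columns other than `id`, `sex`, `site`,
#'   `grave` are rejected.
#' @param registry Variable registry; defaults to [variable_registry()].
#' @param exclusions Optional data frame with columns `case_id` and
#'   `variable`: those single measurements are omitted from the fit.
#' @param priors Prior specification, see [parse_priors()].
#' @param provenance Free-text description of the training data.
#' @return An object of class `sex_reference`: list with elements
#'   `registry`, `params` (long data frame: variable, sex, n, mean, sd,
#'   min, max — model scale), `priors`, `exclusions`, `provenance`.
#' @seealso [italian_reference()] for the built-in published-summaries
#'   model, [summarize_reference()], [save_reference()].
#' @examples
#' d <- data.frame(id = 1:4, sex = c("M", "M", "F", "F"),
#'                 radius_max_head_diameter = c(20, 22, 16, 18))
#' m <- fit_reference(d)
#' subset(m$params, variable == "radius_max_head_diameter")
#' @export
fit_reference <- function(data, registry = variable_registry(),
                          exclusions = NULL, priors = "1:1",
                          provenance = "user training data") {
  stopifnot(is.data.frame(data))
  meta_cols <- c("id", "case_id", "sex", "site", "grave")
  var_cols <- setdiff(names(data), meta_cols)
  unknown <- setdiff(var_cols, registry$name)
  if (length(unknown)) {
    stop("unknown measurement column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"sex" %in% names(data)) stop("training data needs a 'sex' column", call. = FALSE)
  sex <- .normalize_sex(data$sex)
  if (anyNA(sex)) stop("sex labels must be binary M/F", call. = FALSE)
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    if ("case_id" %in% names(data)) as.character(data$case_id) else
      as.character(seq_len(nrow(data)))

  if (!is.null(exclusions)) {
    stopifnot(all(c("case_id", "variable") %in% names(exclusions)))
    bad <- setdiff(exclusions$variable, registry$name)
    if (length(bad)) {
      stop("exclusion references unknown variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  params <- do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
    v <- registry$name[i]
    x <- if (v %in% names(data)) data[[v]] else rep(NA_real_, nrow(data))
    x <- as.numeric(x)
    if (!is.null(exclusions)) {
      drop <- exclusions$variable == v
      if (any(drop)) x[ids %in% as.character(exclusions$case_id[drop])] <- NA_real_
    }
    if (any(x <= 0, na.rm = TRUE)) {
      stop("non-positive measurement in variable '", v, "'", call. = FALSE)
    }
    t_x <- .to_model_scale(x, registry$log_transform[i])
    do.call(rbind, lapply(c("M", "F"), function(s) {
      g <- .group_summary(t_x[sex == s])
      data.frame(variable = v, sex = s, n = g$n, mean = g$mean, sd = g$sd,
                 min = g$min, max = g$max, stringsAsFactors = FALSE)
    }))
  }))
  rownames(params) <- NULL

  structure(
    list(registry = registry, params = params,
         priors = parse_priors(priors),
         exclusions = if (is.null(exclusions)) {
           data.frame(case_id = character(), variable = character(),
                      stringsAsFactors = FALSE)
         } else {
           data.frame(case_id = as.character(exclusions$case_id),
                      variable = as.character(exclusions$variable),
                      stringsAsFactors = FALSE)
         },
         provenance = provenance),
    class = "sex_reference"
  )
}

.normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("M", "MALE")] <- "M"
  out[s %in% c("F", "FEMALE")] <- "F"
  out
}

#' Construct a reference model directly from summary statistics
#'
#' Builds a `sex_reference` from already-computed per-variable, per-sex
#' parameters (for example a published table of group means and standard
#' deviations), without access to raw measurements. Parameters must be on
#' the model scale for log-flagged variables.
#'
#' @param params Data frame with columns `variable`, `sex` (`"M"`/`"F"`),
#'   `n`, `mean`, `sd` and optionally `min`, `max`.
#' @inheritParams fit_reference
#' @return A `sex_reference` object.
#' @export
reference_from_summaries <- function(params, registry = variable_registry(),
                                     priors = "1:1",
                                     provenance = "summary statistics") {
  stopifnot(all(c("variable", "sex", "n", "mean", "sd") %in% names(params)))
  bad <- setdiff(params$variable, registry$name)
  if (length(bad)) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"min" %in% names(params)) params$min <- NA_real_
  if (!"max" %in% names(params)) params$max <- NA_real_
  # complete to the full registry x sex grid; absent combinations get n = 0
  grid <- expand.grid(variable = registry$name, sex = c("M", "F"),
                      stringsAsFactors = FALSE)
  m <- merge(grid, params[, c("variable", "sex", "n", "mean", "sd", "min", "max")],
             by = c("variable", "sex"), all.x = TRUE, sort = FALSE)
  m$n[is.na(m$n)] <- 0L
  m <- m[order(match(m$variable, registry$name), match(m$sex, c("M", "F"))), ]
  rownames(m) <- NULL
  structure(
    list(registry = registry, params = m, priors = parse_priors(priors),
         exclusions = data.frame(case_id = character(), variable = character(),
                                 stringsAsFactors = FALSE),
         provenance = provenance),
    class = "sex_reference"
  )
}

#' Which variables can contribute to prediction?
#'
#' A variable is usable when it is flagged `included_in_model` and both
#' sexes have at least 2 observations with a positive, finite standard
#' deviation (a degenerate zero-spread group admits no density).
#'
#' @param model A `sex_reference`.
#' @return Character vector of usable variable names.
#' @export
usable_variables <- function(model) {
  stopifnot(inherits(model, "sex_reference"))
  p <- model$params
  ok <- vapply(model$registry$name, function(v) {
    if (!model$registry$included_in_model[model$registry$name == v]) return(FALSE)
    rows <- p[p$variable == v, ]
    all(rows$n >= 2L) && all(is.finite(rows$sd)) && all(rows$sd > 0)
  }, logical(1))
  model$registry$name[ok]
}

.param_row <- function(model, variable, sex) {
  r <- model$params[model$params$variable == variable & model$params$sex == sex, ]
  if (nrow(r) != 1L) stop("no parameters for ", variable, "/", sex, call. = FALSE)
  r
}

#' Tabulate a fitted reference model
#'
#' One row per (variable, sex) with the observation count and location and
#' spread on both the model scale and, for log-flagged variables, the
#' back-transformed display scale (geometric mean; the model-scale sd is
#' reported unchanged and flagged, not back-transformed).
#'
#' @param model A `sex_reference`.
#' @return Data frame with columns `variable`, `sex`, `n`, `mean`, `sd`,
#'   `min`, `max` (model scale), `log_scale` flag, and `display_mean`
#'   (mm scale).
#' @export
summarize_reference <- function(model) {
  stopifnot(inherits(model, "sex_reference"))
  out <- model$params
  out$log_scale <- model$registry$log_transform[match(out$variable, model$registry$name)]
  out$display_mean <- ifelse(out$log_scale, exp(out$mean), out$mean)
  out
}

#' @export
print.sex_reference <- function(x, ...) {
  cat("Per-sex osteometric reference model\n")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  cat("  priors: male ", signif(x$priors["male"], 4), ", female ",
      signif(x$priors["female"], 4), "\n", sep = "")
  u <- usable_variables(x)
  cat("  variables: ", nrow(x$registry), " registered, ", length(u),
      " usable for prediction\n", sep = "")
  if (nrow(x$exclusions)) {
    cat("  measurement-level exclusions: ", nrow(x$exclusions), "\n", sep = "")
  }
  invisible(x)
}

#' Save / load a reference model as JSON
#'
#' Persists all model state (registry, parameters, priors, exclusions,
#' provenance) in a versioned JSON schema; `load_reference(save_reference(m))`
#' reproduces every numeric parameter bit-identically.
#'
#' @param model A `sex_reference`.
#' @param path File path.
#' @return `save_reference` returns `path` invisibly; `load_reference`
#'   returns the restored `sex_reference`.
#' @export
save_reference <- function(model, path) {
  stopifnot(inherits(model, "sex_reference"))
  payload <- list(
    schema = "cremsex-reference",
    schema_version = 1L,
    provenance = model$provenance,
    priors = as.list(model$priors),
    registry = model$registry,
    params = model$params,
    exclusions = model$exclusions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("cannot parse reference JSON '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  req <- c("schema", "schema_version", "priors", "registry", "params")
  missing_blocks <- setdiff(req, names(payload))
  if (length(missing_blocks)) {
    stop("malformed reference file '", path, "': missing block(s) ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  if (!identical(payload$schema, "cremsex-reference")) {
    stop("not a cremsex reference file: ", path, call. = FALSE)
  }
  params <- as.data.frame(payload$params)
  for (col in c("mean", "sd", "min", "max")) {
    if (!col %in% names(params)) params[[col]] <- NA_real_
    params[[col]] <- as.numeric(params[[col]])
  }
  params$n <- as.integer(params$n)
  excl <- as.data.frame(payload$exclusions)
  if (!nrow(excl)) {
    excl <- data.frame(case_id = character(), variable = character(),
                       stringsAsFactors = FALSE)
  }
  structure(
    list(registry = as.data.frame(payload$registry),
         params = params,
         priors = parse_priors(unlist(payload$priors)[c("male", "female")]),
         exclusions = excl,
         provenance = payload$provenance),
    class = "sex_reference"
  )
}
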