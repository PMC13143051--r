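#' Posterior probability of male sex from a single measurement
#'
#' Evaluates the two per-sex normal densities of one variable at the
#' (model-scale) measurement and combines them with the priors:
#' `p_male = pi_M f_M / (pi_M f_M + pi_F f_F)`. Computation is carried out
#' with log-densities for numerical stability and the result is clamped to
#' `[1e-12, 1 - 1e-12]` so that a single extreme measurement can never
#' produce an exact 0/1 and silence the consistency diagnostics.
#'
#' @param x Measurement in mm (raw scale; the log transform, where flagged,
#'   is applied internally).
#' @param variable Canonical variable name.
#' @param model A `sex_reference`.
#' @param priors Prior specification (default: the model's priors).
#' @return Posterior probability of male, in (0, 1).
#' @examples
#' single_posterior(19.9, "radius_max_head_diameter", italian_reference())
#' @export
single_posterior <- function(x, variable, model, priors = model$priors) {
  stopifnot(inherits(model, "sex_reference"), length(x) == 1L)
  if (!variable %in% model$registry$name) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (!variable %in% usable_variables(model)) {
    stop("variable '", variable, "' is not usable for prediction ",
         "(excluded from the model or insufficient reference data)",
         call. = FALSE)
  }
  if (!is.finite(x) || x <= 0) stop("measurement must be positive", call. = FALSE)
  priors <- parse_priors(priors)
  lr <- .log_likelihood_ratio(x, variable, model)
  .clamp_p(stats::plogis(log(priors["male"] / priors["female"]) + lr))
}

# log f_M(t(x)) - log f_F(t(x)) for one variable
.log_likelihood_ratio <- function(x, variable, model) {
  i <- match(variable, model$registry$name)
  tx <- .to_model_scale(x, model$registry$log_transform[i])
  m <- .param_row(model, variable, "M")
  f <- .param_row(model, variable, "F")
  stats::dnorm(tx, m$mean, m$sd, log = TRUE) -
    stats::dnorm(tx, f$mean, f$sd, log = TRUE)
}

.clamp_p <- function(p) {
  unname(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' Joint posterior sex probability for one case
#'
#' Naive-Bayes combination of all observed, usable measurements of one
#' individual: per-variable likelihood ratios (male vs female normal
#' density on the model scale) are summed in the log domain and combined
#' with the prior log-odds; missing variables contribute nothing, so any
#' subset from 1 to 19 measurements yields a prediction. Conditional
#' independence between measurements is assumed.
#'
#' Measurements for registry variables that are excluded from the model or
#' unusable are accepted but skipped with a notice. Per-variable single
#' posteriors (always with equal priors, so they reflect the data alone)
#' and the three data-control warnings are attached.
#'
#' @param values Named numeric vector of measurements in mm (names =
#'   canonical variable names; `NA` = missing), or a one-row data frame.
#' @param model A `sex_reference`.
#' @param priors Prior specification (default: the model's priors).
#' @param threshold Classification threshold in \[0.5, 1); default 0.65.
#' @param case_id Identifier carried into the result.
#' @return Object of class `sex_posterior`: list with `case_id`, `p_male`,
#'   `p_female`, `per_variable` (named equal-prior single posteriors),
#'   `n_used`, `skipped` (observed but non-contributing variables),
#'   `warnings` (data frame from [case_warnings()]), `label`, `threshold`,
#'   `priors`.
#' @examples
#' m <- italian_reference()
#' joint_posterior(c(radius_max_head_diameter = 21,
#'                   talus_trochlea_width = 31), m)
#' @export
joint_posterior <- function(values, model, priors = model$priors,
                            threshold = 0.65, case_id = NA_character_) {
  stopifnot(inherits(model, "sex_reference"))
  values <- .as_measurement_vector(values, model$registry)
  priors <- parse_priors(priors)
  observed <- names(values)[!is.na(values)]
  if (any(values[observed] <= 0)) {
    stop("measurements must be positive (mm)", call. = FALSE)
  }
  usable <- intersect(observed, usable_variables(model))
  skipped <- setdiff(observed, usable)
  if (length(skipped)) {
    message("case ", case_id, ": skipping non-predictive variable(s): ",
            paste(skipped, collapse = ", "))
  }
  if (!length(usable)) {
    stop(structure(
      class = c("cremsex_no_prediction", "error", "condition"),
      list(message = paste0("case ", case_id,
                            ": no usable measurements, prediction not possible"),
           call = NULL)))
  }
  lrs <- vapply(usable, function(v)
    .log_likelihood_ratio(values[[v]], v, model), numeric(1))
  p_male <- .clamp_p(stats::plogis(log(priors["male"] / priors["female"]) + sum(lrs)))
  per_variable <- .clamp_p(stats::plogis(lrs))  # equal priors by construction
  names(per_variable) <- usable
  warn <- case_warnings(values, model, per_variable)
  structure(
    list(case_id = case_id, p_male = p_male, p_female = 1 - p_male,
         per_variable = per_variable, n_used = length(usable),
         skipped = skipped, warnings = warn,
         label = classify_sex(p_male, threshold),
         threshold = threshold, priors = priors),
    class = "sex_posterior"
  )
}

.as_measurement_vector <- function(values, registry) {
  if (is.data.frame(values)) {
    stopifnot(nrow(values) == 1L)
    keep <- intersect(names(values), registry$name)
    values <- stats::setNames(as.numeric(values[1, keep]), keep)
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("measurements must be a named vector (variable = mm value)",
         call. = FALSE)
  }
  unknown <- setdiff(names(values), registry$name)
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  values
}

#' Classify a posterior probability with an abstention threshold
#'
#' Assigns `male` or `female` when the larger posterior reaches the
#' threshold (inclusive, "65% or more"), otherwise `ambiguous`. An exact
#' 0.5 tie is `ambiguous` at any threshold.
#'
#' @param p_male Posterior probability (vectorized).
#' @param threshold Threshold in \[0.5, 1); default 0.65.
#' @return Character vector: `"male"`, `"female"` or `"ambiguous"`.
#' @export
classify_sex <- function(p_male, threshold = 0.65) {
  stopifnot(threshold >= 0.5, threshold < 1)
  out <- rep("ambiguous", length(p_male))
  out[p_male != 0.5 & p_male >= threshold] <- "male"
  out[p_male != 0.5 & (1 - p_male) >= threshold] <- "female"
  out[is.na(p_male)] <- NA_character_
  out
}

#' Data-control warnings for one case
#'
#' Implements the three warning mechanisms that flag measurement errors
#' and possible commingling of more than one individual:
#'
#' * `outlier` — a measurement's model-scale value falls outside the
#'   3-standard-deviation band of *both* sexes' reference distributions
#'   (a value extreme for one sex but typical for the other is
#'   informative, not suspect); flags typos and measurement error.
#' * `inconsistency_few` — with 2 to 4 contributing measurements, a pair
#'   of equal-prior single posteriors differing by more than 0.33.
#' * `inconsistency_several` — with 5 or more contributing measurements,
#'   any single posterior deviating from the median single posterior by
#'   more than 0.25.
#'
#' Warnings never block prediction; they prompt re-examination of the
#' deposit for a possible second individual.
#'
#' @param values Named measurement vector (mm).
#' @param model A `sex_reference`.
#' @param per_variable Named equal-prior single posteriors of the
#'   contributing variables; computed internally if `NULL`.
#' @return Data frame with columns `kind`, `variables`, `magnitude`,
#'   `message` (zero rows when no warning fires).
#' @export
case_warnings <- function(values, model, per_variable = NULL) {
  values <- .as_measurement_vector(values, model$registry)
  observed <- names(values)[!is.na(values)]
  warn <- data.frame(kind = character(), variables = character(),
                     magnitude = numeric(), message = character(),
                     stringsAsFactors = FALSE)

  # (a) 3 SD outlier, against both sexes' reference bands
  for (v in observed) {
    i <- match(v, model$registry$name)
    m <- .param_row(model, v, "M")
    f <- .param_row(model, v, "F")
    if (m$n < 2 || f$n < 2 || !is.finite(m$sd) || !is.finite(f$sd) ||
        m$sd <= 0 || f$sd <= 0) next
    tx <- .to_model_scale(values[[v]], model$registry$log_transform[i])
    z <- c(abs(tx - m$mean) / m$sd, abs(tx - f$mean) / f$sd)
    if (all(z > 3)) {
      warn <- rbind(warn, data.frame(
        kind = "outlier", variables = v, magnitude = min(z),
        message = paste0("Measurement of ", v, " falls outside of three ",
                         "standard deviations of both reference distributions!"),
        stringsAsFactors = FALSE))
    }
  }

  if (is.null(per_variable)) {
    usable <- intersect(observed, usable_variables(model))
    per_variable <- vapply(usable, function(v)
      .clamp_p(stats::plogis(.log_likelihood_ratio(values[[v]], v, model))),
      numeric(1))
  }
  k <- length(per_variable)

  # (b) pairwise inconsistency for 2-4 contributing features
  if (k >= 2L && k <= 4L) {
    vn <- names(per_variable)
    for (a in seq_len(k - 1L)) {
      for (b in seq((a + 1L), k)) {
        d <- abs(per_variable[[a]] - per_variable[[b]])
        if (d > 0.33) {
          warn <- rbind(warn, data.frame(
            kind = "inconsistency_few",
            variables = paste(vn[a], vn[b], sep = "|"),
            magnitude = d,
            message = paste0("Inconsistency for few features! (",
                             vn[a], " vs ", vn[b], ": discrepancy ",
                             sprintf("%.2f", d), ")"),
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  # (c) deviation from the median posterior for >= 5 features
  if (k >= 5L) {
    med <- stats::median(per_variable)
    dev <- abs(per_variable - med)
    hit <- which(dev > 0.25)
    for (j in hit) {
      warn <- rbind(warn, data.frame(
        kind = "inconsistency_several",
        variables = names(per_variable)[j],
        magnitude = dev[[j]],
        message = paste0("Inconsistency for several features! (",
                         names(per_variable)[j], " deviates ",
                         sprintf("%.2f", dev[[j]]),
                         " from the median posterior)"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(warn) <- NULL
  warn
}

#' @export
print.sex_posterior <- function(x, ...) {
  cat("Case ", ifelse(is.na(x$case_id), "<unnamed>", x$case_id), ": ",
      sprintf("p(male) = %.4f, p(female) = %.4f", x$p_male, x$p_female),
      "\n", sep = "")
  cat("  classification (threshold ", x$threshold * 100, "%): ", x$label,
      "\n", sep = "")
  cat("  variables used: ", x$n_used, "\n", sep = "")
  if (nrow(x$warnings)) {
    cat("  warnings:\n")
    for (m in x$warnings$message) cat("    - ", m, "\n", sep = "")
  }
  invisible(x)
}

#' Batch sex prediction for a measurement table
#'
#' Applies [joint_posterior()] to every row of a measurement table.
#' Cases without any usable measurement are retained with `NA`
#' probabilities and label `"no_prediction"` (distinct from `ambiguous`).
#'
#' @param model A `sex_reference`.
#' @param newdata Data frame, one row per case, registry-named measurement
#'   columns plus optional `id`.
#' @param priors,threshold Passed to [joint_posterior()].
#' @return Data frame: `case_id`, `p_male`, `p_female`, `label`, `n_used`,
#'   `warnings` (kinds and magnitudes, `;`-separated).
#' @export
predict_sex <- function(model, newdata, priors = model$priors,
                        threshold = 0.65) {
  stopifnot(is.data.frame(newdata))
  ids <- if ("id" %in% names(newdata)) as.character(newdata$id) else
    as.character(seq_len(nrow(newdata)))
  keep <- intersect(names(newdata), model$registry$name)
  rows <- lapply(seq_len(nrow(newdata)), function(r) {
    vals <- stats::setNames(as.numeric(newdata[r, keep]), keep)
    post <- tryCatch(
      suppressMessages(joint_posterior(vals, model, priors = priors,
                                       threshold = threshold,
                                       case_id = ids[r])),
      cremsex_no_prediction = function(e) NULL)
    if (is.null(post)) {
      return(data.frame(case_id = ids[r], p_male = NA_real_,
                        p_female = NA_real_, label = "no_prediction",
                        n_used = 0L, warnings = "", stringsAsFactors = FALSE))
    }
    w <- if (nrow(post$warnings)) {
      paste(sprintf("%s[%s:%.2f]", post$warnings$kind, post$warnings$variables,
                    post$warnings$magnitude), collapse = ";")
    } else ""
    data.frame(case_id = ids[r], p_male = post$p_male,
               p_female = post$p_female, label = post$label,
               n_used = post$n_used, warnings = w, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
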