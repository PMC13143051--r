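#' Derive a univariate cut-off rule from the reference model
#'
#' The threshold is the crossing point of the two fitted per-sex normal
#' densities lying between the two means — the equal-prior Bayes-optimal
#' univariate decision boundary. In the equal-variance limit this is the
#' midpoint of the means. If no crossing falls between the means
#' (pathological parameters), the midpoint is used and flagged.
#'
#' @param model A `sex_reference`.
#' @param variable Canonical variable name (must be usable).
#' @return Object of class `cutoff_rule`: list with `variable`,
#'   `threshold` (model scale), `male_side` (`"above"`/`"below"`),
#'   `log_scale`, `fallback` flag.
#' @examples
#' derive_cutoff(italian_reference(), "mandible_condyle_width")
#' @export
derive_cutoff <- function(model, variable) {
  stopifnot(inherits(model, "sex_reference"))
  if (!variable %in% usable_variables(model)) {
    stop("variable '", variable, "' is not usable", call. = FALSE)
  }
  m <- .param_row(model, variable, "M")
  f <- .param_row(model, variable, "F")
  male_side <- if (m$mean > f$mean) "above" else "below"
  lo <- min(m$mean, f$mean)
  hi <- max(m$mean, f$mean)
  fallback <- FALSE
  if (abs(m$sd - f$sd) < 1e-12 * (m$sd + f$sd)) {
    threshold <- (m$mean + f$mean) / 2
  } else {
    cross <- attr(normal_overlap(m$mean, m$sd, f$mean, f$sd), "crossings")
    inside <- cross[cross > lo & cross < hi]
    if (length(inside) == 1L) {
      threshold <- inside
    } else {
      threshold <- (m$mean + f$mean) / 2
      fallback <- TRUE
      warning("no density crossing between the means for '", variable,
              "'; falling back to the midpoint", call. = FALSE)
    }
  }
  structure(
    list(variable = variable, threshold = threshold, male_side = male_side,
         log_scale = model$registry$log_transform[
           match(variable, model$registry$name)],
         fallback = fallback),
    class = "cutoff_rule"
  )
}

#' Binary classification by cut-off
#'
#' Always produces a label (never abstains, no probability). Values
#' exactly at the threshold are assigned to the female side: the rule is
#' total and deterministic.
#'
#' @param x Measurements in mm (raw scale; log transform applied
#'   internally for log-flagged variables). Vectorized.
#' @param rule A `cutoff_rule`.
#' @return Character vector `"male"`/`"female"`.
#' @export
classify_cutoff <- function(x, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  tx <- .to_model_scale(x, rule$log_scale)
  is_male <- if (rule$male_side == "above") tx > rule$threshold
             else tx < rule$threshold
  out <- ifelse(is_male, "male", "female")
  out[is.na(x)] <- NA_character_
  out
}

#' Combine several cut-off votes for one case
#'
#' Each observed variable casts a binary vote; the case is classified only
#' when all votes agree, otherwise it is `ambiguous` (the only way the
#' cut-off approach abstains).
#'
#' @param values Named measurement vector (mm).
#' @param rules List of `cutoff_rule` objects (e.g. from
#'   [derive_cutoff()] over the usable variables).
#' @return `"male"`, `"female"` or `"ambiguous"`.
#' @export
multi_cutoff_vote <- function(values, rules) {
  names(rules) <- vapply(rules, `[[`, character(1), "variable")
  observed <- names(values)[!is.na(values)]
  observed <- intersect(observed, names(rules))
  if (!length(observed)) {
    stop("no observed variable has a cut-off rule", call. = FALSE)
  }
  votes <- vapply(observed, function(v)
    classify_cutoff(values[[v]], rules[[v]]), character(1))
  u <- unique(votes)
  if (length(u) == 1L) u else "ambiguous"
}

#' @export
print.cutoff_rule <- function(x, ...) {
  scale_note <- if (x$log_scale) " (log scale)" else " mm"
  cat("Cut-off rule for ", x$variable, ": male ", x$male_side, " ",
      sprintf("%.3f", x$threshold), scale_note,
      if (x$fallback) " [midpoint fallback]" else "", "\n", sep = "")
  invisible(x)
}
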