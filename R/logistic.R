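#' Univariate binary logistic regression for one variable
#'
#' Fits `P(male | x) = logistic(beta0 + beta1 * x)` by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]), with male
#' coded 1 (positive class) and the measurement on the model scale (log
#' where flagged). Complete separation is detected — non-convergence or a
#' slope magnitude exceeding 50 per model-scale unit — and reported via
#' `converged = FALSE` rather than silently returning divergent
#' coefficients.
#'
#' @param x Numeric measurements (raw mm scale).
#' @param sex Sex labels (`"M"`/`"F"` or `"male"`/`"female"`).
#' @param variable Optional canonical variable name; when given, the
#'   registry's log flag is applied.
#' @param registry Variable registry (used only when `variable` is given).
#' @return Object of class `sex_logistic`: list with `variable`, `beta0`,
#'   `beta1`, `se0`, `se1`, `converged`, `n`, `log_scale`,
#'   `positive_class = "male"` and the underlying `glm` fit.
#' @examples
#' f <- fit_logistic(c(18, 20, 14, 16), c("M", "M", "F", "F"))
#' predict_logistic(f, 17)  # p = 0.5 by symmetry
#' @export
fit_logistic <- function(x, sex, variable = NULL,
                         registry = variable_registry()) {
  sex <- .normalize_sex(sex)
  keep <- !is.na(x) & !is.na(sex)
  x <- as.numeric(x[keep])
  sex <- sex[keep]
  if (length(unique(sex)) < 2L) {
    stop("both sexes must be present to fit a logistic model", call. = FALSE)
  }
  if (length(x) < 4L) stop("need at least 4 observations", call. = FALSE)
  log_scale <- FALSE
  if (!is.null(variable)) {
    row <- variable_registry(variable)
    log_scale <- row$log_transform
  }
  tx <- .to_model_scale(x, log_scale)
  y <- as.integer(sex == "M")
  fit <- suppressWarnings(
    stats::glm(y ~ tx, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # complete separation: the classes do not overlap on the model scale, so
  # the likelihood has no interior maximum (IRLS drifts to the boundary)
  separated <- min(tx[y == 1]) > max(tx[y == 0]) ||
    max(tx[y == 1]) < min(tx[y == 0])
  converged <- isTRUE(fit$converged) && is.finite(beta[2]) &&
    abs(beta[2]) <= 50 && !separated
  structure(
    list(variable = if (is.null(variable)) NA_character_ else row$name,
         beta0 = unname(beta[1]), beta1 = unname(beta[2]),
         se0 = unname(se[1]), se1 = unname(se[2]),
         converged = converged, n = length(x), log_scale = log_scale,
         positive_class = "male", fit = fit),
    class = "sex_logistic"
  )
}

#' Predict from a univariate logistic model with a 95% band
#'
#' Returns the fitted male probability and a Wald confidence band computed
#' on the linear-predictor scale (point estimate +/- 1.96 standard errors)
#' and transformed through the logistic function, so the band endpoints
#' always bracket the point estimate.
#'
#' @param object A converged `sex_logistic`.
#' @param x Measurements (raw mm scale). Vectorized.
#' @param level Confidence level, default 0.95.
#' @return Data frame with columns `x`, `p`, `lower`, `upper`.
#' @export
predict_logistic <- function(object, x, level = 0.95) {
  stopifnot(inherits(object, "sex_logistic"))
  if (!object$converged) {
    stop("model did not converge (possible complete separation); ",
         "prediction refused", call. = FALSE)
  }
  tx <- .to_model_scale(as.numeric(x), object$log_scale)
  pr <- stats::predict(object$fit, newdata = data.frame(tx = tx),
                       type = "link", se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    x = as.numeric(x),
    p = stats::plogis(pr$fit),
    lower = stats::plogis(pr$fit - z * pr$se.fit),
    upper = stats::plogis(pr$fit + z * pr$se.fit)
  )
}

#' @export
print.sex_logistic <- function(x, ...) {
  cat("Univariate logistic sex model",
      if (!is.na(x$variable)) paste0(" (", x$variable, ")"), "\n", sep = "")
  cat(sprintf("  logit p(male) = %.4f + %.4f * x%s   (n = %d)\n",
              x$beta0, x$beta1, if (x$log_scale) " [log mm]" else " [mm]",
              x$n))
  if (!x$converged) cat("  NOT converged (possible complete separation)\n")
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Standard receiver operating characteristic over all score thresholds
#' (male = positive class), with the AUC computed by the trapezoidal rule.
#'
#' @param scores Predicted male probabilities (or any monotone score).
#' @param labels Sex labels (`"M"`/`"F"` or `"male"`/`"female"`).
#' @return List with `points` (data frame `threshold`, `tpr`, `fpr`,
#'   sorted by increasing fpr) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  sex <- .normalize_sex(labels)
  keep <- !is.na(scores) & !is.na(sex)
  scores <- scores[keep]
  sex <- sex[keep]
  if (length(unique(sex)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = sex, predictor = as.numeric(scores),
                 levels = c("F", "M"), direction = "<", quiet = TRUE)
  pts <- data.frame(threshold = r$thresholds,
                    tpr = r$sensitivities,
                    fpr = 1 - r$specificities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(pROC::auc(r)))
}
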