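#' Leave-one-out cross-validation of a sex predictor
#'
#' For every case in a labelled measurement table, the chosen predictor is
#' refitted on all remaining cases and applied to the held-out case:
#'
#' * `"bayes"` — the reference model is refitted per fold (all variables)
#'   and the joint posterior computed from the case's observed subset;
#'   variables left with fewer than 2 reference observations in a fold are
#'   skipped for that fold.
#' * `"logistic"` — a univariate logistic model for `variable`, refitted
#'   on the remaining cases observed for that variable.
#' * `"cutoff"` — the cut-off rule for `variable`, re-derived per fold;
#'   the binary vote is stored as a degenerate probability (1 male,
#'   0 female) so the same downstream metrics apply.
#'
#' Cases that cannot be predicted (no usable measurement, or the fold's
#' training data is degenerate) are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param data Measurement table with `sex` and optionally `id` columns.
#' @param predictor `"bayes"`, `"logistic"` or `"cutoff"`.
#' @param variable Variable name, required for the univariate predictors.
#' @param registry Variable registry.
#' @param exclusions Measurement-level exclusions applied to every fold's
#'   training data (see [fit_reference()]).
#' @param priors Prior specification for the Bayesian predictor.
#' @return Data frame of prediction records: `case_id`, `true_sex`,
#'   `p_male`, `n_used`; attribute `n_excluded`.
#' @export
loocv <- function(data, predictor = c("bayes", "logistic", "cutoff"),
                  variable = NULL, registry = variable_registry(),
                  exclusions = NULL, priors = "1:1") {
  predictor <- match.arg(predictor)
  stopifnot(is.data.frame(data), "sex" %in% names(data))
  if (predictor != "bayes" && is.null(variable)) {
    stop("the '", predictor, "' predictor needs a variable", call. = FALSE)
  }
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  true_sex <- .normalize_sex(data$sex)
  n <- nrow(data)
  keep_cols <- intersect(names(data), registry$name)

  rows <- vector("list", n)
  n_excluded <- 0L
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    rec <- switch(predictor,
      bayes = {
        model <- fit_reference(train, registry = registry,
                               exclusions = exclusions, priors = priors)
        vals <- stats::setNames(as.numeric(data[i, keep_cols]), keep_cols)
        post <- tryCatch(
          suppressMessages(joint_posterior(vals, model, priors = priors,
                                           case_id = ids[i])),
          cremsex_no_prediction = function(e) NULL)
        if (is.null(post)) NULL else
          data.frame(case_id = ids[i], true_sex = true_sex[i],
                     p_male = post$p_male, n_used = post$n_used,
                     stringsAsFactors = FALSE)
      },
      logistic = {
        x_i <- suppressWarnings(as.numeric(data[i, variable]))
        if (is.na(x_i)) NULL else {
          fold <- tryCatch(
            fit_logistic(suppressWarnings(as.numeric(train[[variable]])),
                         train$sex, variable = variable,
                         registry = registry),
            error = function(e) NULL)
          if (is.null(fold) || !fold$converged) NULL else
            data.frame(case_id = ids[i], true_sex = true_sex[i],
                       p_male = predict_logistic(fold, x_i)$p,
                       n_used = 1L, stringsAsFactors = FALSE)
        }
      },
      cutoff = {
        x_i <- suppressWarnings(as.numeric(data[i, variable]))
        if (is.na(x_i)) NULL else {
          rule <- tryCatch({
            model <- fit_reference(train, registry = registry,
                                   exclusions = exclusions, priors = priors)
            derive_cutoff(model, variable)
          }, error = function(e) NULL)
          if (is.null(rule)) NULL else
            data.frame(case_id = ids[i], true_sex = true_sex[i],
                       p_male = as.numeric(
                         classify_cutoff(x_i, rule) == "male"),
                       n_used = 1L, stringsAsFactors = FALSE)
        }
      })
    if (is.null(rec)) n_excluded <- n_excluded + 1L else rows[[i]] <- rec
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(case_id = character(), true_sex = character(),
                      p_male = numeric(), n_used = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Confusion metrics at a probability threshold
#'
#' Classifies each record with [classify_sex()] at the given threshold
#' (male = positive class) and computes percentage metrics over the
#' classified (non-ambiguous) cases only, as is conventional for post-hoc
#' filtered evaluation.
#'
#' @param records Prediction records (`true_sex`, `p_male`), e.g. from
#'   [loocv()].
#' @param threshold Classification threshold; 0.5 gives the raw (unfiltered)
#'   metrics.
#' @return List: `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1` (percent), counts `tp`, `fp`, `tn`, `fn`, `n_classified`,
#'   `n_ambiguous`, and `threshold`.
#' @export
confusion_metrics <- function(records, threshold = 0.5) {
  stopifnot(all(c("true_sex", "p_male") %in% names(records)))
  label <- classify_sex(records$p_male, threshold)
  classified <- label %in% c("male", "female")
  if (!any(classified)) {
    stop("no case classified at threshold ", threshold,
         ": metrics undefined", call. = FALSE)
  }
  truth <- records$true_sex[classified]
  pred <- label[classified]
  tp <- sum(pred == "male" & truth == "M")
  fp <- sum(pred == "male" & truth == "F")
  tn <- sum(pred == "female" & truth == "F")
  fn <- sum(pred == "female" & truth == "M")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
       sensitivity = 100 * sens, specificity = 100 * spec,
       precision = 100 * prec, f1 = 100 * f1,
       tp = tp, fp = fp, tn = tn, fn = fn,
       n_classified = sum(classified),
       n_ambiguous = sum(label == "ambiguous"),
       threshold = threshold)
}

#' Post-hoc probability filtering across thresholds
#'
#' For each threshold, cases whose maximum posterior does not reach it are
#' declared ambiguous and excluded; the summary reports the retained
#' counts per (true) sex, the percentage of the total sample excluded,
#' and the accuracy among the retained cases. Raising the threshold can
#' only shrink the classified set.
#'
#' @param records Prediction records.
#' @param thresholds Probability thresholds; default the conventional
#'   ladder 0.50, 0.65, 0.75, 0.85, 0.90.
#' @return Data frame: `threshold`, `n_male`, `n_female`, `n_ambiguous`,
#'   `pct_ambiguous`, `accuracy`.
#' @export
posthoc_filter <- function(records,
                           thresholds = c(0.50, 0.65, 0.75, 0.85, 0.90)) {
  total <- nrow(records)
  out <- lapply(thresholds, function(th) {
    label <- classify_sex(records$p_male, th)
    classified <- label %in% c("male", "female")
    acc <- if (any(classified)) {
      confusion_metrics(records, th)$accuracy
    } else NA_real_
    data.frame(threshold = th,
               n_male = sum(classified & records$true_sex == "M"),
               n_female = sum(classified & records$true_sex == "F"),
               n_ambiguous = sum(!classified),
               pct_ambiguous = 100 * sum(!classified) / total,
               accuracy = acc)
  })
  do.call(rbind, out)
}

#' Reliability (calibration) curve
#'
#' Bins the predicted male probabilities into `n_bins` equal-width bins on
#' \[0, 1\] and reports, per non-empty bin, the mean prediction against
#' the observed male fraction. A well-calibrated model tracks the
#' diagonal.
#'
#' @param records Prediction records.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Data frame: `bin_mid`, `mean_predicted`, `observed_male_fraction`,
#'   `n` (empty bins omitted).
#' @export
reliability_curve <- function(records, n_bins = 10) {
  stopifnot(n_bins >= 1)
  p <- records$p_male
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_mid = (breaks[b] + breaks[b + 1]) / 2,
               mean_predicted = mean(p[sel]),
               observed_male_fraction = mean(records$true_sex[sel] == "M"),
               n = sum(sel))
  })
  do.call(rbind, out)
}
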