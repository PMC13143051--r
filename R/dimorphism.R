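#' Two-sample t tests from group summaries
#'
#' Classic pooled-variance (Student) and Welch two-sample t tests computed
#' from group summary statistics (n, mean, sd) rather than raw vectors, as
#' needed when only published summaries are available.
#'
#' @param n1,n2 Group sizes (each at least 2).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group sample standard deviations (denominator n-1).
#' @return List of class `htest_summary` with `statistic` (t), `df`,
#'   `p_value` (two-sided) and `method`.
#' @examples
#' pooled_t_test(27, 19.77, 1.29, 39, 17.07, 1.28)  # t about 8.4
#' @export
pooled_t_test <- function(n1, mean1, sd1, n2, mean2, sd2) {
  .check_t_input(n1, sd1, n2, sd2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance: t statistic undefined", call. = FALSE)
  df <- n1 + n2 - 2
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       method = "pooled")
}

#' @rdname pooled_t_test
#' @export
welch_t_test <- function(n1, mean1, sd1, n2, mean2, sd2) {
  .check_t_input(n1, sd1, n2, sd2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 <= 0) stop("zero variance: t statistic undefined", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       method = "welch")
}

.check_t_input <- function(n1, sd1, n2, sd2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
}

#' Overlapping coefficient of two normal distributions
#'
#' Computes the overlapping coefficient OVL = integral of min(f1, f2) for
#' two normal densities, analytically: the log-densities are equated,
#' giving a quadratic whose real roots are the crossing points; the OVL is
#' then the sum of the appropriate normal tail/interval probabilities.
#' With equal standard deviations there is a single crossing at the
#' midpoint and OVL = 2 * pnorm(-|mu1 - mu2| / (2 * sd)). Each group keeps
#' its own standard deviation; no pooling.
#'
#' @param mu1,sd1 Mean and standard deviation of the first normal
#'   (`sd1 > 0`).
#' @param mu2,sd2 Mean and standard deviation of the second normal.
#' @return OVL in \[0, 1\]; attribute `"crossings"` holds the crossing
#'   points used.
#' @examples
#' normal_overlap(0, 1, 0, 1)   # identical: 1
#' normal_overlap(14.23, 1.12, 12.01, 2.10)  # unequal variance, two crossings
#' @export
normal_overlap <- function(mu1, sd1, mu2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) {
    stop("standard deviations must be strictly positive", call. = FALSE)
  }
  if (isTRUE(all.equal(sd1, sd2)) || abs(sd1 - sd2) < 1e-12 * (sd1 + sd2)) {
    s <- (sd1 + sd2) / 2
    if (mu1 == mu2) {
      return(structure(1, crossings = numeric()))
    }
    cross <- (mu1 + mu2) / 2
    ovl <- 2 * stats::pnorm(-abs(mu1 - mu2) / (2 * s))
    return(structure(ovl, crossings = cross))
  }
  # log f1(x) = log f2(x)  =>  A x^2 + B x + C = 0
  A <- 1 / (2 * sd2^2) - 1 / (2 * sd1^2)
  B <- mu1 / sd1^2 - mu2 / sd2^2
  C <- mu2^2 / (2 * sd2^2) - mu1^2 / (2 * sd1^2) + log(sd2 / sd1)
  disc <- B^2 - 4 * A * C
  if (disc < 0) disc <- 0  # numerically tangent densities
  # numerically stable quadratic roots (A can be tiny for near-equal sds)
  q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  roots <- if (q == 0) c(-B / (2 * A), -B / (2 * A)) else sort(c(q / A, C / q))
  # integrate min(f1, f2) piecewise; pick the smaller density per interval
  bounds <- c(-Inf, roots, Inf)
  ovl <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    probe <- if (is.infinite(lo) && is.infinite(hi)) (mu1 + mu2) / 2 else
      if (is.infinite(lo)) hi - 1 else
        if (is.infinite(hi)) lo + 1 else (lo + hi) / 2
    # compare in the log domain: far in the tails both densities underflow
    use1 <- stats::dnorm(probe, mu1, sd1, log = TRUE) <=
      stats::dnorm(probe, mu2, sd2, log = TRUE)
    mu <- if (use1) mu1 else mu2
    s <- if (use1) sd1 else sd2
    ovl <- ovl + (stats::pnorm(hi, mu, s) - stats::pnorm(lo, mu, s))
  }
  structure(min(max(ovl, 0), 1), crossings = roots)
}

#' Chakraborty-Majumder non-overlap index D
#'
#' D = 1 - OVL, where OVL is the exact overlapping coefficient of the two
#' per-sex normal distributions fitted with their own standard deviations
#' (see [normal_overlap()]). D is 0 for identical distributions and
#' approaches 1 for fully separated ones; it quantifies the sexual
#' dimorphism of a measurement independent of sample size. For reporting,
#' round to 2 decimals.
#'
#' @inheritParams normal_overlap
#' @return D in \[0, 1\].
#' @examples
#' round(cm_dvalue(16.95, 1.44, 14.77, 1.58), 2)  # mandibular condyle: 0.53
#' @export
cm_dvalue <- function(mu1, sd1, mu2, sd2) {
  1 - as.numeric(normal_overlap(mu1, sd1, mu2, sd2))
}

#' Per-variable dimorphism screening
#'
#' For every registry variable of a fitted reference model, computes the
#' two-sample t test between the sexes (on the model scale, so log-flagged
#' variables are screened on the log scale), the Chakraborty-Majumder D,
#' and an inclusion decision: a variable is included when it is flagged
#' for modelling, has enough observations, and its two-sided p-value is
#' below `alpha`.
#'
#' @param model A `sex_reference`.
#' @param alpha Significance level for inclusion (default 0.05).
#' @param method `"pooled"` (Student, default) or `"welch"`.
#' @return Data frame with one row per variable: `variable`, `n_male`,
#'   `n_female`, `mean_male`, `mean_female`, `statistic`, `df`, `p_value`,
#'   `d_value`, `included`, `reason`.
#' @export
screen_variables <- function(model, alpha = 0.05, method = c("pooled", "welch")) {
  stopifnot(inherits(model, "sex_reference"))
  method <- match.arg(method)
  tfun <- if (method == "pooled") pooled_t_test else welch_t_test
  rows <- lapply(model$registry$name, function(v) {
    m <- .param_row(model, v, "M")
    f <- .param_row(model, v, "F")
    out <- data.frame(variable = v, n_male = m$n, n_female = f$n,
                      mean_male = m$mean, mean_female = f$mean,
                      statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                      d_value = NA_real_, included = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    if (m$n < 2 || f$n < 2) {
      out$reason <- "insufficient n"
      return(out)
    }
    if (!is.finite(m$sd) || !is.finite(f$sd) || m$sd <= 0 || f$sd <= 0) {
      out$reason <- "degenerate spread"
      return(out)
    }
    tt <- tfun(m$n, m$mean, m$sd, f$n, f$mean, f$sd)
    out$statistic <- tt$statistic
    out$df <- tt$df
    out$p_value <- tt$p_value
    out$d_value <- cm_dvalue(m$mean, m$sd, f$mean, f$sd)
    if (!model$registry$included_in_model[model$registry$name == v]) {
      out$reason <- "excluded from model"
    } else if (tt$p_value >= alpha) {
      out$reason <- "not significant"
    } else {
      out$included <- TRUE
    }
    out
  })
  do.call(rbind, rows)
}
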