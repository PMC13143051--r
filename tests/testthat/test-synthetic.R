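test_that("generation is seed-deterministic with the documented layout", {
  a <- generate_individuals(8, 7, seed = 5)
  b <- generate_individuals(8, 7, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 15L)
  expect_equal(sum(a$sex == "M"), 8L)
  expect_true(all(variable_registry()$name %in% names(a)))
  # observed counts follow the missingness support (1-5 by default)
  k <- rowSums(!is.na(a[, variable_registry()$name]))
  expect_true(all(k >= 1 & k <= 5))
  # empty request yields an empty table with full header
  e <- generate_individuals(0, 0)
  expect_equal(nrow(e), 0L)
  expect_true(all(variable_registry()$name %in% names(e)))
})

test_that("requests beyond the usable variable count are capped with notice", {
  expect_message(
    d <- generate_individuals(3, 3, missingness = c("25" = 1), seed = 6),
    "capped")
  k <- rowSums(!is.na(d[, variable_registry()$name]))
  expect_true(all(k == 19))
})

test_that("large samples reproduce the generating means within CLT bounds", {
  n <- 600
  d <- generate_individuals(n, n, missingness = NULL, seed = 7)
  truth <- italian_reference()
  reg <- truth$registry
  for (v in c("radius_max_head_diameter", "patella_max_height",
              "mt1_mediolateral_head_width")) {
    for (s in c("M", "F")) {
      p <- truth$params[truth$params$variable == v & truth$params$sex == s, ]
      x <- d[[v]][d$sex == s]
      if (reg$log_transform[reg$name == v]) x <- log(x)
      expect_lt(abs(mean(x) - p$mean), 3 * p$sd / sqrt(n))
    }
  }
})

test_that("log-flagged variables are generated on the mm scale", {
  d <- generate_individuals(200, 0, missingness = NULL, seed = 8)
  x <- d$mt1_mediolateral_head_width
  expect_true(all(x > 5))  # back-transformed from the log scale, not ~2.9
  expect_equal(mean(log(x)), log(18.88), tolerance = 0.05)
})

test_that("within-sex correlation is injected by the shared factor", {
  d <- generate_individuals(800, 0, missingness = NULL, correlation = 0.6,
                            seed = 9)
  r <- cor(d$radius_max_head_diameter, d$talus_trochlea_width)
  expect_equal(r, 0.6, tolerance = 0.1)
  d0 <- generate_individuals(800, 0, missingness = NULL, seed = 9)
  expect_lt(abs(cor(d0$radius_max_head_diameter, d0$talus_trochlea_width)),
            0.12)
})

test_that("commingled cases mix both donors and keep ground truth", {
  cm <- generate_commingled(25, seed = 10)
  expect_equal(nrow(cm), 25L)
  expect_true(all(cm$commingled))
  k <- rowSums(!is.na(cm[, variable_registry()$name]))
  expect_true(all(k >= 2))
  expect_true(all(cm$n_from_male >= 1 & cm$n_from_male <= k - 1))
  expect_equal(nrow(generate_commingled(0)), 0L)
})

test_that("opposing single posteriors in a mixed case raise the warning", {
  m <- toy_model(list(radius_max_head_diameter = c(20, 1, 10, 16, 1, 10),
                      talus_trochlea_width = c(30, 1, 10, 26, 1, 10)))
  # male-typical radius with female-typical talus: posteriors near 1 and 0
  post <- joint_posterior(c(radius_max_head_diameter = 20,
                            talus_trochlea_width = 26), m)
  expect_true("inconsistency_few" %in% post$warnings$kind)
})

test_that("commingling triggers inconsistency warnings more often", {
  m <- italian_reference()
  # same observed-variable regime for both groups (2-4 measurements)
  singles <- generate_individuals(
    60, 60, missingness = c("2" = 0.4, "3" = 0.35, "4" = 0.25), seed = 11)
  mixed <- generate_commingled(120, n_observed = 2:4, seed = 12)
  inconsistent <- function(df) {
    keep <- intersect(names(df), m$registry$name)
    vapply(seq_len(nrow(df)), function(i) {
      vals <- stats::setNames(as.numeric(df[i, keep]), keep)
      w <- suppressMessages(joint_posterior(vals, m))$warnings
      any(w$kind %in% c("inconsistency_few", "inconsistency_several"))
    }, logical(1))
  }
  rate_single <- mean(inconsistent(singles))
  rate_mixed <- mean(inconsistent(mixed))
  expect_gt(rate_mixed, rate_single)
})

test_that("multivariate combination beats the best single variable", {
  # full observation: the joint posterior should clearly outperform the
  # best univariate rule (analytic ceiling (1 + max D)/2 ~ 0.89)
  d <- generate_individuals(250, 250, missingness = NULL, seed = 13)
  rec <- loocv(d, "bayes")
  acc_joint <- confusion_metrics(rec, 0.5)$accuracy
  scr <- screen_variables(italian_reference())
  best_single <- 100 * (1 + max(scr$d_value[scr$included])) / 2
  expect_gt(acc_joint, best_single)
})
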