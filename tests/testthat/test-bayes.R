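test_that("single-measurement posterior follows the density-ratio formula", {
  m <- toy1(muM = 20, sdM = 1, muF = 17, sdF = 1)
  # x at the male mean: likelihood ratio exp(4.5)
  expect_equal(single_posterior(20, "radius_max_head_diameter", m),
               exp(4.5) / (exp(4.5) + 1), tolerance = 1e-12)
  # x at the density crossing: equal likelihoods
  expect_equal(single_posterior(18.5, "radius_max_head_diameter", m), 0.5)
  # skewed priors scale the ratio
  m2 <- toy1(priors = "1.05:1")
  expect_equal(single_posterior(20, "radius_max_head_diameter", m2),
               1.05 * exp(4.5) / (1.05 * exp(4.5) + 1), tolerance = 1e-12)
  # unusable variable is an error, not a silent 0.5
  expect_error(
    single_posterior(18, "talus_head_neck_length", italian_reference()),
    "not usable")
  expect_error(single_posterior(-2, "radius_max_head_diameter", m),
               "positive")
})

test_that("joint posterior multiplies likelihood ratios and normalizes", {
  m <- toy_model(list(radius_max_head_diameter = c(20, 1, 10, 17, 1, 10),
                      talus_trochlea_width = c(30, 1, 10, 27, 1, 10)))
  # single observed variable reduces to the single posterior
  p1 <- joint_posterior(c(radius_max_head_diameter = 19.2), m)
  expect_equal(p1$p_male,
               single_posterior(19.2, "radius_max_head_diameter", m))
  expect_equal(p1$n_used, 1L)
  # two measurements at the male means: ratio exp(4.5) each
  p2 <- joint_posterior(c(radius_max_head_diameter = 20,
                          talus_trochlea_width = 30), m)
  expect_equal(p2$p_male, exp(9) / (exp(9) + 1), tolerance = 1e-12)
  expect_equal(p2$p_male + p2$p_female, 1)
  # opposing evidence of equal strength cancels
  p3 <- joint_posterior(c(radius_max_head_diameter = 20,
                          talus_trochlea_width = 27), m)
  expect_equal(p3$p_male, 0.5, tolerance = 1e-12)
  # order of variables is irrelevant
  p4 <- joint_posterior(c(talus_trochlea_width = 30,
                          radius_max_head_diameter = 20), m)
  expect_equal(p4$p_male, p2$p_male)
  # adding a measurement at its crossing changes nothing
  p5 <- joint_posterior(c(radius_max_head_diameter = 20,
                          talus_trochlea_width = 28.5), m)
  expect_equal(p5$p_male,
               joint_posterior(c(radius_max_head_diameter = 20), m)$p_male,
               tolerance = 1e-12)
})

test_that("log-domain computation agrees with direct density products", {
  set.seed(23)
  reg <- variable_registry()
  cand <- reg$name[reg$included_in_model & !reg$log_transform]
  for (i in 1:200) {
    k <- sample(1:4, 1)
    vars <- sample(cand, k)
    spec <- lapply(vars, function(v)
      c(runif(1, 10, 40), runif(1, 0.5, 3), 10,
        runif(1, 10, 40), runif(1, 0.5, 3), 10))
    names(spec) <- vars
    m <- toy_model(spec)
    x <- vapply(spec, function(p) runif(1, min(p[1], p[4]) - 2,
                                        max(p[1], p[4]) + 2), numeric(1))
    names(x) <- vars
    post <- joint_posterior(x, m)
    fM <- prod(vapply(vars, function(v)
      dnorm(x[[v]], spec[[v]][1], spec[[v]][2]), numeric(1)))
    fF <- prod(vapply(vars, function(v)
      dnorm(x[[v]], spec[[v]][4], spec[[v]][5]), numeric(1)))
    expect_equal(post$p_male, fM / (fM + fF), tolerance = 1e-10)
    expect_equal(post$p_male + post$p_female, 1)
  }
})

test_that("posterior is monotone in a male-larger measurement", {
  m <- toy1()
  xs <- seq(12, 25, by = 0.25)
  ps <- vapply(xs, single_posterior, numeric(1),
               variable = "radius_max_head_diameter", model = m)
  expect_true(all(diff(ps) >= 0))
})

test_that("unusable measurements are skipped; none usable refuses prediction", {
  it <- italian_reference()
  expect_message(
    p <- joint_posterior(c(radius_max_head_diameter = 21,
                           talus_head_neck_length = 18), it),
    "skipping")
  expect_equal(p$n_used, 1L)
  expect_equal(p$skipped, "talus_head_neck_length")
  expect_error(joint_posterior(c(talus_head_neck_length = 18), it),
               class = "cremsex_no_prediction")
  expect_error(joint_posterior(c(femur_length = 40), it), "unknown")
})

test_that("threshold classification is inclusive with ambiguous ties", {
  expect_equal(classify_sex(0.64, 0.65), "ambiguous")
  expect_equal(classify_sex(0.65, 0.65), "male")
  expect_equal(classify_sex(0.35, 0.65), "female")
  expect_equal(classify_sex(0.5, 0.5), "ambiguous")
  expect_equal(classify_sex(0.5, 0.9), "ambiguous")
  expect_equal(classify_sex(c(0.91, 0.09, 0.7), 0.9),
               c("male", "female", "ambiguous"))
  expect_error(classify_sex(0.7, 0.4))
})

test_that("outlier warning needs exceedance of both sexes' 3 sd bands", {
  m <- toy1(muM = 20, sdM = 1, muF = 17, sdF = 1)
  w <- case_warnings(c(radius_max_head_diameter = 25), m)
  expect_equal(w$kind, "outlier")
  expect_gt(w$magnitude, 3)
  # extreme for females only: informative, not suspect
  w2 <- case_warnings(c(radius_max_head_diameter = 21), m)
  expect_equal(nrow(w2), 0L)
})

test_that("pairwise inconsistency fires for 2-4 features above 0.33", {
  m <- toy1()
  vals <- c(radius_max_head_diameter = 19)
  w <- case_warnings(vals, m,
                     per_variable = c(a = 0.95, b = 0.55))
  expect_equal(w$kind[w$kind != "outlier"], "inconsistency_few")
  expect_equal(w$magnitude[w$kind == "inconsistency_few"], 0.40,
               tolerance = 1e-12)
  expect_match(w$message[w$kind == "inconsistency_few"],
               "Inconsistency for few features!")
  # deviation just below the rule stays silent
  w2 <- case_warnings(vals, m, per_variable = c(a = 0.85, b = 0.55))
  expect_false(any(w2$kind == "inconsistency_few"))
})

test_that("median-deviation inconsistency fires for 5+ features above 0.25", {
  m <- toy1()
  vals <- c(radius_max_head_diameter = 19)
  pv <- c(v1 = 0.90, v2 = 0.88, v3 = 0.87, v4 = 0.85, v5 = 0.50)
  w <- case_warnings(vals, m, per_variable = pv)
  sev <- w[w$kind == "inconsistency_several", ]
  expect_equal(sev$variables, "v5")
  expect_equal(sev$magnitude, 0.37, tolerance = 1e-12)
  # the pairwise rule is not applied at 5 features
  expect_false(any(w$kind == "inconsistency_few"))
})

test_that("batch prediction keeps unpredictable cases with a distinct label", {
  it <- italian_reference()
  d <- data.frame(id = c("u1", "u2"),
                  radius_max_head_diameter = c(21, NA),
                  talus_head_neck_length = c(NA, 18))
  pred <- predict_sex(it, d)
  expect_equal(pred$label[1], "male")
  expect_equal(pred$label[2], "no_prediction")
  expect_true(is.na(pred$p_male[2]))
  expect_equal(pred$n_used, c(1L, 0L))
})
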