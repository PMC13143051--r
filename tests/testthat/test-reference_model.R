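test_that("registry defines 21 unique variables with the documented flags", {
  reg <- variable_registry()
  expect_equal(nrow(reg), 21L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_setequal(reg$name[reg$log_transform],
                  c("mt1_mediolateral_head_width", "axis_transverse_diameter"))
  expect_setequal(reg$name[!reg$included_in_model],
                  c("axis_transverse_diameter", "talus_head_neck_length"))
  expect_equal(sum(reg$included_in_model), 19L)
  # display-name resolution
  expect_equal(variable_registry("Radius: maximum head diameter")$name,
               "radius_max_head_diameter")
  expect_error(variable_registry("femur_length"), "unknown variable")
})

test_that("fitting computes per-sex summaries with sample sd (n-1)", {
  d <- data.frame(id = 1:4, sex = c("M", "M", "F", "F"),
                  radius_max_head_diameter = c(20, 22, 16, 18))
  m <- fit_reference(d)
  p <- subset(m$params, variable == "radius_max_head_diameter")
  expect_equal(p$n, c(2L, 2L))
  expect_equal(p$mean, c(21, 17))
  expect_equal(p$sd, c(sqrt(2), sqrt(2)))
  expect_true("radius_max_head_diameter" %in% usable_variables(m))
})

test_that("measurement-level exclusion drops one value, not the case", {
  d <- data.frame(id = c("a", "b", "c", "d"), sex = c("M", "M", "F", "F"),
                  radius_max_head_diameter = c(20, 22, 16, 18),
                  talus_trochlea_width = c(30, 31, 25, 26))
  m <- fit_reference(d, exclusions = data.frame(
    case_id = "a", variable = "radius_max_head_diameter"))
  p <- subset(m$params, variable == "radius_max_head_diameter" & sex == "M")
  expect_equal(p$n, 1L)
  expect_false("radius_max_head_diameter" %in% usable_variables(m))
  # the case's other measurement still contributes
  q <- subset(m$params, variable == "talus_trochlea_width" & sex == "M")
  expect_equal(q$n, 2L)
  expect_true("talus_trochlea_width" %in% usable_variables(m))
})

test_that("invalid training input is rejected with the offending name", {
  d <- data.frame(sex = c("M", "F"), femur_length = c(1, 2))
  expect_error(fit_reference(d), "femur_length")
  d2 <- data.frame(sex = c("M", "F"),
                   mt1_mediolateral_head_width = c(-3, 17))
  expect_error(fit_reference(d2), "non-positive")
})

test_that("fitting is invariant to row and column order, no cross-sex leakage", {
  set.seed(31)
  d <- data.frame(id = 1:30, sex = rep(c("M", "F"), 15),
                  radius_max_head_diameter = rnorm(30, 18, 1.5),
                  talus_trochlea_width = rnorm(30, 28, 2.5))
  m1 <- fit_reference(d)
  m2 <- fit_reference(d[sample(30), c(3, 4, 1, 2)])
  expect_equal(m1$params, m2$params)
  # per-sex fit on the per-sex subset matches the pooled-table fit
  males <- fit_reference(d[d$sex == "M", ])
  pm <- subset(m1$params, sex == "M")
  expect_equal(subset(males$params, sex == "M"), pm)
})

test_that("summary table reports both scales and degenerate rows", {
  m <- toy1()
  s <- summarize_reference(m)
  expect_equal(nrow(s), 42L)  # 21 variables x 2 sexes
  r <- subset(s, variable == "radius_max_head_diameter")
  expect_equal(r$mean, c(20, 17))
  expect_equal(r$display_mean, c(20, 17))
  empty <- subset(s, variable == "femur_vert_head_diameter")
  expect_equal(empty$n, c(0L, 0L))
  expect_true(all(is.na(empty$mean)))
  # log variable back-transforms the display mean only
  it <- summarize_reference(italian_reference())
  mt1 <- subset(it, variable == "mt1_mediolateral_head_width" & sex == "M")
  expect_true(mt1$log_scale)
  expect_equal(mt1$display_mean, 18.88, tolerance = 1e-12)
  expect_equal(mt1$mean, log(18.88), tolerance = 1e-12)
})

test_that("JSON round-trip reproduces every parameter bit-identically", {
  m <- fit_reference(
    data.frame(id = 1:6, sex = rep(c("M", "F"), 3),
               radius_max_head_diameter = c(20.13, 17.07, 21.9, 16.55,
                                            19.004, 17.77)),
    priors = "1.05:1")
  path <- withr::local_tempfile(fileext = ".json")
  save_reference(m, path)
  m2 <- load_reference(path)
  expect_identical(m$params$mean, m2$params$mean)
  expect_identical(m$params$sd, m2$params$sd)
  expect_identical(m$params$n, m2$params$n)
  expect_identical(unname(m$priors), unname(m2$priors))
  expect_equal(m$registry, m2$registry)
})

test_that("malformed persistence files are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "cremsex-reference",
                            schema_version = 1, registry = list(),
                            params = list()), path, auto_unbox = TRUE)
  expect_error(load_reference(path), "priors")
  writeLines("{not json", path)
  expect_error(load_reference(path), "parse")
})

test_that("priors parse ratios and reject degenerate input", {
  expect_equal(parse_priors("1:1"), c(male = 0.5, female = 0.5))
  p <- parse_priors("1.05:1")
  expect_equal(unname(p[1] / p[2]), 1.05, tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_error(parse_priors("1:0"), "positive")
  expect_error(parse_priors("a:b"), "ratio")
})

test_that("fit on generated data recovers the generating parameters", {
  n <- 500
  gen <- generate_individuals(n, n, missingness = NULL, seed = 91)
  fit <- fit_reference(gen, provenance = "synthetic")
  truth <- italian_reference()$params
  est <- fit$params
  for (v in usable_variables(fit)) {
    for (s in c("M", "F")) {
      tr <- truth[truth$variable == v & truth$sex == s, ]
      es <- est[est$variable == v & est$sex == s, ]
      expect_lt(abs(es$mean - tr$mean), 3 * tr$sd / sqrt(n))
      expect_lt(abs(es$sd - tr$sd) / tr$sd, 0.10)
    }
  }
})
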