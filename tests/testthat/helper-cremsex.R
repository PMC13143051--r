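# shared fixtures and independent oracles

# brute-force overlapping coefficient by adaptive quadrature over a finite
# bracket (an infinite range can miss a narrow overlap region entirely)
ovl_numeric <- function(mu1, sd1, mu2, sd2) {
  lo <- min(mu1 - 12 * sd1, mu2 - 12 * sd2)
  hi <- max(mu1 + 12 * sd1, mu2 + 12 * sd2)
  # split at the means, component supports, and the kinks of min(f1, f2):
  # sign changes of the log-density difference located by root bracketing
  g <- function(x) stats::dnorm(x, mu1, sd1, log = TRUE) -
    stats::dnorm(x, mu2, sd2, log = TRUE)
  grid <- seq(lo, hi, length.out = 801L)
  gv <- g(grid)
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  kinks <- vapply(flips, function(k)
    stats::uniroot(g, c(grid[k], grid[k + 1L]), tol = 1e-13)$root,
    numeric(1))
  brk <- sort(unique(pmin(pmax(
    c(lo, mu1 - 12 * sd1, mu1, mu1 + 12 * sd1,
      mu2 - 12 * sd2, mu2, mu2 + 12 * sd2, kinks, hi), lo), hi)))
  f <- function(x) pmin(stats::dnorm(x, mu1, sd1),
                        stats::dnorm(x, mu2, sd2))
  total <- 0
  for (k in seq_len(length(brk) - 1L)) {
    if (brk[k + 1L] > brk[k]) {
      total <- total + stats::integrate(f, brk[k], brk[k + 1L],
                                        subdivisions = 2000L,
                                        rel.tol = 1e-10,
                                        abs.tol = 1e-13)$value
    }
  }
  total
}

# reference model with explicit parameters for chosen variables;
# vars: list(name = c(mu_M, sd_M, n_M, mu_F, sd_F, n_F))
toy_model <- function(vars, priors = "1:1") {
  params <- do.call(rbind, lapply(names(vars), function(v) {
    p <- vars[[v]]
    data.frame(variable = v, sex = c("M", "F"), n = c(p[3], p[6]),
               mean = c(p[1], p[4]), sd = c(p[2], p[5]),
               stringsAsFactors = FALSE)
  }))
  reference_from_summaries(params, priors = priors, provenance = "toy")
}

# prediction records with prescribed confusion counts
records_from_counts <- function(tp, fn, tn, fp, p_hi = 0.9, p_lo = 0.1) {
  data.frame(
    case_id = as.character(seq_len(tp + fn + tn + fp)),
    true_sex = c(rep("M", tp), rep("F", fp), rep("F", tn), rep("M", fn)),
    p_male = c(rep(p_hi, tp + fp), rep(p_lo, tn + fn)),
    n_used = 1L, stringsAsFactors = FALSE)
}

# one non-log variable used for most single-variable fixtures
toy1 <- function(muM = 20, sdM = 1, muF = 17, sdF = 1, nM = 10, nF = 10,
                 priors = "1:1") {
  toy_model(stats::setNames(
    list(c(muM, sdM, nM, muF, sdF, nF)), "radius_max_head_diameter"),
    priors = priors)
}
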