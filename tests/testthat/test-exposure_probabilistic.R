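# Builds a one-analyte dataset where every sample is a detection with the
# given concentrations.
all_detect_dataset <- function(values, analyte = "flonicamid") {
  ids <- sprintf("S%05d", seq_along(values))
  monitoring_dataset(
    data.frame(sample_id = ids, province = "X"),
    data.frame(sample_id = ids, analyte = analyte,
               concentration_mg_kg = values),
    panel = make_refs()$analyte)
}

test_that("method-of-moments fit recovers known log-normal parameters", {
  refs <- make_refs()
  set.seed(50)
  x <- rlnorm(2000, meanlog = -3, sdlog = 0.5)
  spec <- fit_distributions(all_detect_dataset(x), refs, policy = "LB")
  expect_equal(spec$residues$meanlog, -3, tolerance = 0.05)
  expect_equal(spec$residues$sdlog, 0.5, tolerance = 0.05)
  # the fitted law reproduces the sample moments exactly (MoM identity)
  expect_equal(exp(spec$residues$meanlog + spec$residues$sdlog^2 / 2),
               mean(x))
})

test_that("degenerate and invalid concentration vectors are handled", {
  refs <- make_refs()
  spec <- fit_distributions(all_detect_dataset(rep(0.05, 10)), refs)
  expect_equal(spec$residues$sdlog, 0)
  expect_equal(exp(spec$residues$meanlog), 0.05)
  one <- monitoring_dataset(
    data.frame(sample_id = "S1", province = "X"),
    data.frame(sample_id = "S1", analyte = "flonicamid",
               concentration_mg_kg = 0.05),
    panel = refs$analyte)
  expect_error(fit_distributions(one, refs), "at least 2")
  # a pure non-detect column under LB cannot be log-transformed
  ds2 <- all_detect_dataset(c(0.05, 0.06))
  expect_error(
    fit_distributions(ds2, refs, policy = "LB",
                      analytes = c("flonicamid", "azoxystrobin")),
    "MB or UB")
  # ... but works under MB, where non-detects take LOQ/2
  expect_s3_class(
    fit_distributions(ds2, refs, policy = "MB",
                      analytes = c("flonicamid", "azoxystrobin")),
    "distribution_spec")
})

test_that("zero-variance distributions collapse to the deterministic HIc", {
  refs <- make_refs()
  ds <- all_detect_dataset(rep(0.048, 20))
  adult <- exposure_params("adult")
  spec <- fit_distributions(ds, refs, policy = "MB", params = adult,
                            consumption_cv = 0, bw_cv = 0)
  res <- run_mcs(spec, mcs_config(2000, seed = 3))
  det <- hq_chronic(nedi(0.048, adult), 0.025)
  expect_lt(abs(res$summary$mean - det), 1e-9)
  expect_lt(abs(res$summary$p95 - det), 1e-9)
})

test_that("simulation is reproducible and ordered in its percentiles", {
  refs <- make_refs()
  set.seed(51)
  ds <- all_detect_dataset(rlnorm(50, -3, 0.4))
  spec <- fit_distributions(ds, refs)
  a <- run_mcs(spec, mcs_config(2000, seed = 9))
  b <- run_mcs(spec, mcs_config(2000, seed = 9))
  expect_identical(a$hi_samples, b$hi_samples)
  expect_identical(a$summary, b$summary)
  expect_lte(a$summary$p5, a$summary$median)
  expect_lte(a$summary$median, a$summary$p95)
})

test_that("doubling every ADI exactly halves the HIc distribution", {
  refs <- make_refs()
  set.seed(52)
  ds <- all_detect_dataset(rlnorm(50, -3, 0.4))
  spec <- fit_distributions(ds, refs)
  spec2 <- spec
  spec2$residues$adi <- 2 * spec2$residues$adi
  a <- run_mcs(spec, mcs_config(1000, seed = 13))
  b <- run_mcs(spec2, mcs_config(1000, seed = 13))
  expect_equal(b$hi_samples, a$hi_samples / 2)
  expect_equal(b$summary$p95, a$summary$p95 / 2)
})

test_that("tail probability matches the closed-form log-normal oracle", {
  refs <- make_refs()
  adult <- exposure_params("adult")
  # hand-built spec: one pesticide, fixed consumption and body weight
  meanlog <- log(0.025 * 70 / 0.0011)   # centre the threshold for a fat tail
  sdlog <- 0.8
  spec <- structure(list(
    residues = tibble::tibble(analyte = "flonicamid", meanlog = meanlog,
                              sdlog = sdlog, adi = 0.025),
    consumption = list(meanlog = log(0.0011), sdlog = 0),
    bw = list(mean = 70, sd = 0),
    population = "adult", policy = "MB"), class = "distribution_spec")
  n <- 10000
  res <- run_mcs(spec, mcs_config(n, seed = 17))
  # HQ > 1 iff conc > adi * bw / consumption
  p_true <- 1 - plnorm(0.025 * 70 / 0.0011, meanlog, sdlog)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(res$prob_exceed_unity - p_true), 3 * se)
  expect_equal(res$per_pesticide$prob_hq_exceed_unity,
               res$prob_exceed_unity)
})

test_that("sensitivity contributions identify the varying inputs", {
  set.seed(53)
  n <- 5000
  # single varying input: all variance attributed to it
  x <- rlnorm(n); const <- rep(2, n)
  inputs <- data.frame(conc = x, consumption = const)
  expect_warning(sa <- sensitivity_analysis(inputs, 3 * x), "zero-variance")
  expect_equal(sa$contribution_pct[sa$input == "conc"], 100)
  expect_equal(sa$contribution_pct[sa$input == "consumption"], 0)
  # two symmetric independent inputs split the variance evenly
  a <- rlnorm(n, 0, 0.5); b <- rlnorm(n, 0, 0.5)
  sa2 <- sensitivity_analysis(data.frame(a = a, b = b), a + b)
  expect_equal(sa2$contribution_pct[sa2$input == "a"], 50, tolerance = 0.1)
  expect_equal(sum(abs(sa2$contribution_pct)), 100, tolerance = 1e-9)
  # an input independent of the output contributes next to nothing
  noise <- rlnorm(n)
  sa3 <- sensitivity_analysis(data.frame(a = a, noise = noise), a)
  expect_lt(abs(sa3$contribution_pct[sa3$input == "noise"]), 1)
  # a negatively coupled input carries a negative sign
  sa4 <- sensitivity_analysis(data.frame(a = a, bw = b), a / b)
  expect_lt(sa4$contribution_pct[sa4$input == "bw"], 0)
})

test_that("the regression-coefficient alternative agrees on symmetric inputs", {
  set.seed(54)
  n <- 4000
  a <- rlnorm(n, 0, 0.3); b <- rlnorm(n, 0, 0.3)
  sa <- sensitivity_analysis(data.frame(a = a, b = b), a + b,
                             method = "src")
  expect_equal(sa$contribution_pct[sa$input == "a"], 50, tolerance = 0.1)
  expect_equal(sum(abs(sa$contribution_pct)), 100, tolerance = 1e-9)
})
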