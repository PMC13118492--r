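test_that("monitoring table survives a write/read round trip", {
  refs <- make_refs()
  ds <- make_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_monitoring_table(ds, path)
  back <- read_monitoring_table(path, refs = refs)
  expect_setequal(back$samples$sample_id, ds$samples$sample_id)
  expect_equal(nrow(back$detections), nrow(ds$detections))
  ord <- function(d) d$detections[order(d$detections$sample_id,
                                        d$detections$analyte), ]
  expect_equal(ord(back), ord(ds))
  # residue-free sample S4 survives the round trip via its blank row
  expect_true("S4" %in% back$samples$sample_id)
  # canonical file round-trips byte-identically
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_monitoring_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid monitoring input is rejected with a clear error", {
  refs <- make_refs()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,province,analyte,concentration_mg_kg",
               "S1,Manisa,flonicamid,-0.1"), path)
  expect_error(read_monitoring_table(path, refs = refs), "concentration")
  writeLines(c("sample_id,province,concentration_mg_kg", "S1,Manisa,0.1"),
             path)
  expect_error(read_monitoring_table(path, refs = refs), "missing column")
  writeLines(c("sample_id,province,analyte,concentration_mg_kg",
               "S1,Manisa,notapesticide,0.1"), path)
  expect_error(read_monitoring_table(path, refs = refs), "notapesticide")
  writeLines(c("sample_id,province,analyte,concentration_mg_kg",
               "S1,Manisa,flonicamid,0.002"), path)
  expect_error(read_monitoring_table(path, refs = refs), "LOQ")
  writeLines(c("sample_id,province,analyte,concentration_mg_kg",
               "S1,Manisa,flonicamid,0.05",
               "S1,Manisa,flonicamid,0.06"), path)
  expect_error(read_monitoring_table(path, refs = refs), "duplicate")
})

test_that("a sample can carry many residues and keeps them all", {
  refs <- make_refs()
  det <- data.frame(
    sample_id = "S1",
    analyte = c("metalaxyl", "flonicamid", "propamocarb", "acetamiprid",
                "chlorpyrifos", "azoxystrobin"),
    concentration_mg_kg = c(0.02, 0.05, 0.06, 0.04, 0.03, 0.02))
  ds <- monitoring_dataset(
    data.frame(sample_id = "S1", province = "Manisa"), det)
  expect_equal(sum(ds$detections$sample_id == "S1"), 6)
  expect_equal(unname(multi_residue_distribution(ds)$n_samples[7]), 1)
})

test_that("censoring substitution follows the LB/MB/UB convention", {
  refs <- make_refs()
  ds <- make_dataset()
  # azoxystrobin was never detected: pure non-detect column, LOQ 0.01
  expect_equal(unname(substitute_censored(ds, "azoxystrobin", "LB", refs)),
               rep(0, 4))
  expect_equal(unname(substitute_censored(ds, "azoxystrobin", "MB", refs)),
               rep(0.005, 4))
  expect_equal(unname(substitute_censored(ds, "azoxystrobin", "UB", refs)),
               rep(0.01, 4))
  # detected values pass through under every policy
  for (p in c("LB", "MB", "UB")) {
    v <- substitute_censored(ds, "flonicamid", p, refs)
    expect_equal(unname(v["S1"]), 0.048)
  }
  expect_error(substitute_censored(ds, "notapesticide", "LB", refs), "panel")
})

test_that("mean concentration is the mean of the substituted vector", {
  refs <- make_refs()
  ds <- monitoring_dataset(
    data.frame(sample_id = c("A", "B"), province = "X"),
    data.frame(sample_id = "A", analyte = "flonicamid",
               concentration_mg_kg = 0.02),
    panel = refs$analyte)
  expect_equal(mean_concentration(ds, "flonicamid", "LB", refs), 0.010)
  expect_equal(mean_concentration(ds, "flonicamid", "MB", refs), 0.0125)
  expect_equal(mean_concentration(ds, "flonicamid", "UB", refs), 0.015)
  # all non-detect under UB collapses to the LOQ
  expect_equal(mean_concentration(ds, "azoxystrobin", "UB", refs), 0.01)
  # all detected: plain arithmetic mean
  ds2 <- monitoring_dataset(
    data.frame(sample_id = c("A", "B"), province = "X"),
    data.frame(sample_id = c("A", "B"), analyte = "flonicamid",
               concentration_mg_kg = c(0.02, 0.04)))
  expect_equal(mean_concentration(ds2, "flonicamid", "LB", refs), 0.03)
})

test_that("substitution is monotone LB <= MB <= UB and leaves detection counts alone", {
  refs <- make_refs()
  for (seed in 1:5) {
    ds <- random_dataset(seed)
    for (a in ds$panel) {
      lb <- substitute_censored(ds, a, "LB", refs)
      mb <- substitute_censored(ds, a, "MB", refs)
      ub <- substitute_censored(ds, a, "UB", refs)
      expect_true(all(lb <= mb & mb <= ub))
      # detection count (positive LB entries) invariant under policy
      expect_equal(sum(lb > 0),
                   sum(ds$detections$analyte == a))
    }
  }
})

test_that("reference table validation enforces the invariants", {
  df <- data.frame(analyte = "x", class = "fungicide", authorised = TRUE,
                   mrl_mg_kg = 0.1, adi_mg_kg_bw_day = 0.01,
                   arfd_mg_kg_bw = NA, loq_mg_kg = 0.01)
  expect_s3_class(as_pesticide_ref(df), "pesticide_ref")
  expect_error(as_pesticide_ref(transform(df, mrl_mg_kg = 0)), "mrl")
  expect_error(as_pesticide_ref(transform(df, loq_mg_kg = -1)), "loq")
  expect_error(as_pesticide_ref(transform(df, class = "herbicide")),
               "class")
  expect_error(as_pesticide_ref(rbind(df, df)), "duplicate")
  expect_error(as_pesticide_ref(df[, -4]), "missing")
})
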