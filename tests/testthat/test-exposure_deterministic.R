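adult <- exposure_params("adult")
child <- exposure_params("child")

test_that("NEDI is mean concentration times consumption over body weight", {
  expect_equal(nedi(0.048, adult), 0.048 * 0.0011 / 70)
  expect_equal(nedi(0.048, adult), 7.543e-7, tolerance = 1e-4)
  expect_equal(nedi(0, adult), 0)
  # child/adult intake ratio at equal concentration
  expect_equal(nedi(0.1, child) / nedi(0.1, adult),
               (0.0004 / 23) / (0.0011 / 70))
  expect_error(nedi(-1, adult), ">= 0")
})

test_that("chronic hazard quotient divides NEDI by the ADI", {
  expect_equal(hq_chronic(0.025, 0.025), 1)
  expect_equal(hq_chronic(7.543e-7, 0.025), 3.017e-5, tolerance = 1e-3)
  expect_equal(hq_chronic(0, 0.025), 0)
  expect_error(hq_chronic(1, 0), "ADI")
  expect_error(hq_chronic(1, NA), "ADI")
})

test_that("IESTI Case 2a formula, applicability window and algebra", {
  expect_equal(iesti_case2a(0.331, adult),
               (0.0544 * 0.331 * 3 + (0.168 - 0.0544) * 0.331) / 70)
  expect_equal(iesti_case2a(0.331, adult), 1.3089e-3, tolerance = 1e-4)
  expect_equal(iesti_case2a(0, adult), 0)
  # v = 1 collapses to LP * HR / bw
  p1 <- exposure_params("adult", v = 1)
  expect_equal(iesti_case2a(0.2, p1), 0.168 * 0.2 / 70)
  # linear in HR
  set.seed(40)
  for (i in 1:20) {
    hr <- runif(1, 0, 2); a <- runif(1, 0.1, 5)
    expect_equal(iesti_case2a(a * hr, adult), a * iesti_case2a(hr, adult))
  }
  # fixed adult:child ratio implied by the formula's constants
  expect_equal(iesti_case2a(1, child) / iesti_case2a(1, adult),
               (0.0544 * 3 + 0.092 - 0.0544) / 23 /
                 ((0.0544 * 3 + 0.168 - 0.0544) / 70))
  expect_error(exposure_params("adult", ue_kg = 0.02), "0.025")
  expect_error(exposure_params("child", ue_kg = 0.095), "large portion")
})

test_that("acute hazard quotient falls back to the ADI when ARfD is absent", {
  expect_equal(hq_acute(0.025, arfd = 0.025)$hq, 1)
  expect_false(hq_acute(0.025, arfd = 0.025)$arfd_fallback)
  fb <- hq_acute(0.01, arfd = NA, adi = 0.2)
  expect_true(fb$arfd_fallback)
  expect_equal(fb$hq, 0.05)
  expect_equal(hq_acute(0, arfd = 0.1)$hq, 0)
  expect_error(hq_acute(0.01), "neither")
})

test_that("hazard index sums HQs with a strict acceptability threshold", {
  expect_equal(hazard_index(numeric(0))$hi, 0)
  h <- hazard_index(c(0.5, 0.5))
  expect_equal(h$hi, 1)
  expect_false(h$acceptable)   # exactly 1 flags concern
  expect_true(hazard_index(c(0.4, 0.5))$acceptable)
  set.seed(41)
  hq <- runif(10)
  expect_equal(hazard_index(hq)$hi, hazard_index(rev(hq))$hi)
  expect_equal(hazard_index(hq)$hi, sum(hq))
  expect_error(hazard_index(c(0.1, -0.2)), ">= 0")
})

test_that("scenario report assembles the full deterministic chain", {
  refs <- make_refs()
  ds <- monitoring_dataset(
    data.frame(sample_id = c("A", "B"), province = "X"),
    data.frame(sample_id = "A", analyte = "flonicamid",
               concentration_mg_kg = 0.048),
    panel = refs$analyte)
  rep <- scenario_report(ds, refs)
  # one pesticide: HIc equals its HQc in every scenario and population
  for (pop in c("adult", "child")) {
    for (pol in c("LB", "MB", "UB")) {
      hqc <- rep$chronic$hqc[rep$chronic$population == pop &
                               rep$chronic$policy == pol]
      hic <- rep$hi$hi[rep$hi$population == pop & rep$hi$type == "chronic" &
                         rep$hi$policy == pol]
      expect_equal(hic, hqc)
    }
  }
  # HQc is LB <= MB <= UB for every pesticide and population
  ch <- rep$chronic
  for (pop in unique(ch$population)) {
    sub <- ch[ch$population == pop, ]
    lb <- sub$hqc[sub$policy == "LB"]
    mb <- sub$hqc[sub$policy == "MB"]
    ub <- sub$hqc[sub$policy == "UB"]
    expect_true(all(lb <= mb & mb <= ub))
  }
  # acute side uses the maximum observed residue
  expect_equal(unique(rep$acute$hr), 0.048)
  expect_equal(rep$acute$iesti[rep$acute$population == "adult"],
               iesti_case2a(0.048, adult))
  # contribution shares sum to one per stratum
  agg <- tapply(ch$hic_share, paste(ch$population, ch$policy), sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})

test_that("all-blank dataset gives a zero LB hazard index", {
  refs <- make_refs()
  ds <- monitoring_dataset(
    data.frame(sample_id = c("A", "B"), province = "X"),
    data.frame(sample_id = character(0), analyte = character(0),
               concentration_mg_kg = numeric(0)),
    panel = refs$analyte)
  rep <- scenario_report(ds, refs)
  expect_equal(nrow(rep$chronic), 0)
  lb <- rep$hi$hi[rep$hi$type == "chronic" & rep$hi$policy == "LB"]
  expect_true(all(lb == 0))
})

test_that("pesticides without an ADI are excluded with a warning", {
  refs <- make_refs()
  ds <- monitoring_dataset(
    data.frame(sample_id = "A", province = "X"),
    data.frame(sample_id = c("A", "A"),
               analyte = c("chlorpyrifos", "flonicamid"),
               concentration_mg_kg = c(0.05, 0.048)),
    panel = refs$analyte)
  expect_warning(rep <- scenario_report(ds, refs), "chlorpyrifos")
  expect_equal(rep$excluded, "chlorpyrifos")
  expect_false("chlorpyrifos" %in% rep$chronic$analyte)
})
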