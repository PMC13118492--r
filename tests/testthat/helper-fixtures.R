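# Shared fixtures: a small reference table and hand-built monitoring
# datasets. Everything is constructed in code so tests carry no binary or
# external data.

make_refs <- function() {
  as_pesticide_ref(data.frame(
    analyte = c("metalaxyl", "flonicamid", "propamocarb", "acetamiprid",
                "chlorpyrifos", "azoxystrobin"),
    class = c("fungicide", "insecticide", "fungicide", "insecticide",
              "insecticide", "fungicide"),
    authorised = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    mrl_mg_kg = c(0.01, 0.7, 5, 0.5, 0.01, 1),
    adi_mg_kg_bw_day = c(0.08, 0.025, 0.29, 0.025, NA, 0.2),
    arfd_mg_kg_bw = c(0.5, 0.025, 1, 0.025, NA, NA),
    loq_mg_kg = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE))
}

# 4 samples over 2 provinces: S1 two residues, S2 one gross exceedance,
# S3 one residue, S4 residue-free.
make_dataset <- function() {
  monitoring_dataset(
    samples = data.frame(
      sample_id = c("S1", "S2", "S3", "S4"),
      province = c("Manisa", "Manisa", "Izmir", "Izmir"),
      stringsAsFactors = FALSE),
    detections = data.frame(
      sample_id = c("S1", "S1", "S2", "S3"),
      analyte = c("flonicamid", "propamocarb", "metalaxyl", "acetamiprid"),
      concentration_mg_kg = c(0.048, 0.056, 0.343, 0.04),
      stringsAsFactors = FALSE),
    panel = make_refs()$analyte)
}

# A seeded random small survey for property-style loops.
random_dataset <- function(seed, n = 30, p = c(0.4, 0.25, 0.15)) {
  specs <- list(
    build_spec_from_summary("flonicamid", p[1], 0.013, 0.048, 0.382),
    build_spec_from_summary("propamocarb", p[2], 0.015, 0.056, 1.030),
    build_spec_from_summary("acetamiprid", p[3], 0.015, 0.040, 0.331))
  generate_dataset(specs, c(A = ceiling(n / 2), B = floor(n / 2)),
                   cooccurrence_model(0.5), seed = seed)
}
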