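# residuerisk

Statistical analysis of multi-residue pesticide monitoring surveys and the
dietary risk they imply. The package is aimed at food-safety laboratories and
risk assessors who hold a long table of quantified residue detections (sample,
region, analyte, concentration in mg/kg) together with a per-analyte reference
table (MRL, ADI, ARfD, LOQ) and need the standard chain of survey statistics:

- **Occurrence**: prevalence per region and overall, multi-residue
  co-occurrence histograms, MRL exceedance counts, and Pearson chi-square
  homogeneity tests of detection and exceedance rates across regions.
- **Quality**: the Index of Quality for Residues per sample,
  `IqR = Σᵢ PRCᵢ / MRLᵢ` over the quantified residues, classified as
  excellent (IqR = 0), good (0 < IqR ≤ 0.6), acceptable (0.6 < IqR ≤ 1) or
  unacceptable (IqR > 1).
- **Ranking**: the Veterinary-Residues-Committee-style composite score
  `S = (A + B) × (C + D + E) × F`, where A–E are matrix bands for acute
  toxicity, potency, dietary contribution, application frequency
  (`FOD = 100·N/P`) and vulnerable groups, and
  `F = (F₀·1 + F₁·2 + F₂·3 + F₃·4)/n` scores the residue levels against the
  MRL.
- **Deterministic exposure**: chronic intake `NEDI = c̄ · consumption / bw`
  and `HQc = NEDI / ADI` under lower/middle/upper-bound substitution of
  non-detects (0, LOQ/2, LOQ); acute intake by IESTI Case 2a,
  `IESTI = (Ue·HR·v + (LP − Ue)·HR)/bw`, and `HQa = IESTI / ARfD` with a
  conservative ADI fallback; hazard indices `HI = Σ HQ` with the < 1
  acceptability threshold.
- **Probabilistic exposure**: Monte Carlo simulation of the chronic hazard
  index with log-normal residue and consumption laws and truncated-normal
  body weight, percentile reporting, ADI-exceedance probabilities, and
  contribution-to-variance sensitivity analysis (signed squared Spearman
  rank correlations normalised to 100%).
- **Method validation**: SANTE-style recovery, RSDr / within-lab RSD, LOQ
  from blank replicates, expanded uncertainty `U = k·√(bias² + RSD_WR²)`,
  calibration linearity, and retention-time / ion-ratio identification
  tolerances.
- **Synthetic surveys**: a seedable generator that reproduces the occurrence
  structure monitoring papers print — per-analyte detection frequencies,
  right-skewed truncated log-normal concentrations matched to printed
  min/mean/max, and multi-residue co-occurrence via a latent per-sample
  contamination propensity — so every downstream stage is testable without
  access to raw survey data.

## Worked example

Generate a 905-sample synthetic survey across five provinces from the four
most frequently detected compounds of a gherkin monitoring campaign, then run
the analysis chain:

```r
library(residuerisk)

refs  <- read_reference_table(system.file("extdata",
           "gherkin_reference_synthetic.csv", package = "residuerisk"))
specs <- read_spec_table(system.file("extdata",
           "occurrence_top4.csv", package = "residuerisk"), loq = 0.01)

survey <- generate_dataset(specs,
  c(Afyonkarahisar = 280, Balikesir = 104, Izmir = 152,
    Manisa = 214, Mardin = 155),
  cooc = cooccurrence_model(0.6), seed = 2026)
survey
#> <monitoring_dataset> 905 samples, 817 detections, panel of 4 analytes
#> provinces: Afyonkarahisar (280), Balikesir (104), Izmir (152), Manisa (214), Mardin (155)

prev <- prevalence_summary(survey, refs)
prev[, c("province", "n_samples", "n_contaminated", "detection_rate")]
#>         province n_samples n_contaminated detection_rate
#> 1 Afyonkarahisar       280            180      0.6428571
#> 2      Balikesir       104             63      0.6057692
#> 3          Izmir       152             92      0.6052632
#> 4         Manisa       214            130      0.6074766
#> 5         Mardin       155             82      0.5290323
#> 6        Overall       905            547      0.6044199

by_prov <- prev[prev$province != "Overall", ]
chi2_homogeneity(by_prov$n_contaminated, by_prov$n_samples)
#> Pearson chi-square homogeneity: X2 = 5.4241, df = 4, p = 0.2465

rep <- scenario_report(survey, refs)   # NEDI/HQc under LB/MB/UB, IESTI/HQa
rep$hi
#>   population    type policy           hi acceptable
#> 1      adult chronic     LB 1.654297e-05       TRUE
#> 2      adult chronic     MB 2.172901e-05       TRUE
#> 3      adult chronic     UB 2.691505e-05       TRUE
#> 4      adult   acute   <NA> 9.721211e-02       TRUE
#> 5      child chronic     LB 1.830842e-05       TRUE
#> 6      child chronic     MB 2.404792e-05       TRUE
#> 7      child chronic     UB 2.978741e-05       TRUE
#> 8      child   acute   <NA> 2.146289e-01       TRUE

mc <- run_mcs(fit_distributions(survey, refs, policy = "MB"),
              mcs_config(10000, seed = 2026, population = "adult"))
mc
#> <mcs_result> 10000 iterations (adult)
#>   HIc mean 2.251e-05, median 1.494e-05, p5 3.996e-06, p95 6.436e-05
#>   P(HIc > 1) = 0

sensitivity_analysis(mc$inputs, mc$hi_samples)
#>          input contribution_pct rank
#> 1   flonicamid       62.8699773    1
#> 2  acetamiprid       24.7536259    2
#> 3  consumption        6.5871658    3
#> 4           bw       -3.7734983    4
#> 5  propamocarb        1.4063730    5
#> 6 azoxystrobin        0.6093596    6
```

Reading the output: roughly 60% of the simulated samples carry at least one
quantified residue and the chi-square test finds no significant regional
heterogeneity in this draw. Every chronic hazard index is orders of magnitude
below 1 — gherkin consumption contributes a negligible chronic risk — while
acute indices are larger but still acceptable. The sensitivity analysis
attributes most of the simulated HIc variance to the two compounds with the
lowest ADI relative to their residue levels; body weight enters negatively
(heavier consumers, lower intake per kg). The deterministic and probabilistic
chronic estimates agree in order of magnitude, as they should when input
spreads are moderate.

`run_pipeline()` drives all stages at once from a YAML or programmatic config
and writes CSV tables, JSON summaries and a reproducibility manifest; see
`?run_pipeline` and the methods vignette
(`vignettes/residue-risk-assessment.Rmd`).

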