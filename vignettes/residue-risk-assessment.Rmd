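---
title: "Residue monitoring statistics and dietary risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue monitoring statistics and dietary risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residuerisk)
```

This vignette is the package's account of the science it implements: the
data model for residue monitoring surveys, the quality index, the risk
ranking matrix, the deterministic and probabilistic exposure models, the
method-validation statistics, and the synthetic-data generator — together
with the numerical choices, default parameters and known limitations a
maintainer or reviewer should know about.

## The data model and left-censoring

A monitoring survey is a sample roster (sample id, region) plus a sparse
long table of *quantified* detections. Multi-residue panels routinely cover
hundreds of analytes, so non-detects are implicit: any (sample, analyte)
pair on the panel without a detection row is a non-detect. Concentrations
below the analyte's LOQ are rejected on input rather than coerced —
monitoring reports publish quantified residues only, and silently keeping
sub-LOQ values would make detection frequencies irreproducible.

Non-detects are left-censored observations: the true concentration lies
somewhere in `[0, LOQ)`. Following the standard substitution approach for
censored food-contaminant data, each analysis that needs a full
concentration vector runs under three bounding scenarios:

| policy | substitution | reading |
|--------|--------------|---------|
| LB     | 0            | optimistic lower bound |
| MB     | LOQ/2        | midpoint compromise |
| UB     | LOQ          | conservative upper bound |

Every quantity derived from substituted vectors is monotone LB ≤ MB ≤ UB,
which the test suite verifies property-style; the spread between LB and UB
results is an honest display of the censoring uncertainty, not an error bar.

## Index of Quality for Residues

Per sample, `IqR = Σᵢ PRCᵢ/MRLᵢ` over its quantified residues. The index is
deliberately an *unweighted* sum of regulatory-pressure ratios: it flags
samples whose residues are individually legal but jointly numerous, which a
per-compound MRL check cannot. Categories are excellent (IqR = 0; exactly
the residue-free samples), good (0 < IqR ≤ 0.6), acceptable
(0.6 < IqR ≤ 1.0) and unacceptable (> 1.0), with boundary values assigned
to the lower category. Some sources call the third band "adequate";
`normalise_iqr_category()` accepts the alias. The summation is over the
detected residues only — non-detects contribute zero under any reasonable
censoring policy, so IqR is censoring-invariant.

## Risk ranking matrix

The composite score is `S = (A + B) × (C + D + E) × F`. The grouping
deserves a note: the scheme is often printed without parentheses and is
typographically ambiguous. We adopt the multiplicative grouping of the
original Veterinary Residues Committee matrix — toxicity block times
exposure block times residue-level factor — which is also the reading under
which published per-compound scores are reproducible with plausible integer
bands (for example, band values A=1, B=1, C=1, D=2, E=3 with F = 1233/905
give S = 16.35 for a compound detected in 36.2% of 905 samples, matching a
printed 16.3). A literal left-to-right reading remains available via
`composite_score(..., grouping = "literal")` for comparison.

Component bands A–E are survey-specific judgments (LD50 bands, ADI bands,
consumption share, dosing frequency `FOD = 100·N/P`, vulnerable groups with
default E = 3 when no specific evidence exists); they enter as a
user-supplied table, not as hard-coded cut-points, because the underlying
band definitions are published in appendices that vary between schemes. The
residue-level factor `F = (F₀ + 2F₁ + 3F₂ + 4F₃)/n` is computed from the
data; band F2 is `MRL ≤ c ≤ 10·MRL` inclusive and F3 strictly above
`10·MRL`. Compounds without an established ADI cannot be potency-scored and
are excluded with a warning.

Categories use half-open intervals — high `[20, ∞)`, medium `[15, 20)`,
low `[0, 15)` — because common phrasings place 15 and 20 in two classes at
once; half-open bands resolve the overlap deterministically.

## Deterministic exposure

Chronic: `NEDI = c̄ × consumption / bw` (mg/kg bw/day) with the mean
concentration under each censoring policy, and `HQc = NEDI/ADI`. Acute:
IESTI Case 2a,

```
IESTI = (Ue·HR·v + (LP − Ue)·HR) / bw
```

where the first edible unit carries the unit-to-unit variability factor `v`
and the rest of the large portion carries the composite-sample level. Case
2a applies when `0.025 kg ≤ Ue < LP`; inputs outside that window raise an
error naming the violated condition rather than silently switching to
another IESTI case, because only Case 2a is implemented. `HR` is the
highest observed concentration per compound; no processing-factor
corrections are applied. `HQa = IESTI/ARfD`, with the ADI substituted
conservatively (and flagged) for compounds lacking an ARfD.

Hazard indices sum HQ values over *detected* compounds — the cumulative
reading of a monitoring survey — not over the full panel; acceptability is
strict (`HI < 1`), so an index of exactly 1 flags concern.

Default population parameters (per-capita gherkin consumption 0.0011 /
0.0004 kg/day, body weight 70 / 23 kg for adults / children, Ue = 0.0544 kg,
v = 3, LP = 0.168 / 0.092 kg) are the survey's values and are all
overridable in `exposure_params()`.

## Probabilistic exposure and sensitivity

The Monte Carlo model draws, per iteration: one concentration per compound
from a log-normal fitted by the method of moments to the substituted
concentration vector; one consumption value from a log-normal; one body
weight from a normal truncated to positive values (resampled, never
clipped); and forms `HIc = Σ_p conc_p · consumption / bw / ADI_p`. All
inputs are sampled independently — the underlying surveys specify no
correlation structure between concentration, consumption and body weight,
and imposing one would be an invention.

Numerical choices:

- **LB floor.** A log-normal cannot carry zeros, so LB-substituted zeros are
  floored at half the smallest positive LOQ on the panel (configurable)
  before fitting; an all-zero vector is an error directing the user to
  MB/UB.
- **Spread defaults.** Monitoring reports rarely publish consumption or
  body-weight variances. The defaults — CV 20% for consumption, CV 15% for
  body weight — are ordinary magnitudes for adult dietary-survey data and
  are stated here as the package's own choice; both are arguments of
  `fit_distributions()`.
- **Iterations and seed.** Default 10,000 iterations; the seed is part of
  `mcs_config()` and is recorded in the pipeline manifest, making every
  simulation bit-reproducible.
- **Degenerate collapse.** With all variances zero the simulation reproduces
  the deterministic HIc to ~1e-9, which the tests assert — a useful
  end-to-end consistency check between the two frameworks.

Sensitivity analysis reports contribution to variance: the signed squared
Spearman rank correlation of each input with HIc, normalised so absolute
contributions sum to 100%. This is the convention of the spreadsheet risk
tools used in the field; because the published descriptions say only
"regression-based", a standardized-regression-coefficient alternative is
available (`method = "src"`). Zero-variance inputs contribute 0 with a
warning. Rank correlations are robust to the monotone nonlinearity of the
`1/bw` term, which is why Spearman is the default.

## Occurrence statistics

Prevalence, diversity, unauthorised-compound and exceedance counts are
computed per region and pooled. MRL exceedance is strict (`c > MRL`): a
residue at the MRL is compliant by definition. Homogeneity across k regions
is tested with the Pearson chi-square on the 2×k success/failure table,
no continuity correction (k > 2), df = k−1 — computed via
`stats::chisq.test` and cross-checked in the tests against a brute-force
`Σ(O−E)²/E` oracle to 1e-9 on a thousand random tables. Two published
checks pin the conventions: detection counts reconstructed from printed
regional percentages against regional totals reproduce a printed statistic
of 10.61, and exceedance counts against *contaminated-sample* denominators
(not totals, which would give 12.07) reproduce 11.12. One documented quirk
is preserved rather than corrected: the printed overall contaminated count
(612) differs by 2 from the sum implied by the printed regional percentages
(614); the package computes whatever the supplied data imply.

## Method validation metrics

Recovery (`100·measured/spike`), repeatability RSDr and within-laboratory
reproducibility RSD_WR, LOQ as 10× the blank-replicate standard deviation
(n = 10 by convention, configurable), expanded uncertainty
`U = k·√(bias² + RSD_WR²)` with k = 2 (~95% coverage), OLS calibration R²,
and the ±0.1 min retention-time and ±30% ion-ratio identification
tolerances. Conventions worth naming: all acceptance windows are inclusive
(a recovery of exactly 70 or 120% passes, RSD of exactly 20% passes);
standard deviations are sample (n−1) throughout, replicate sets being
samples; RSD_WR is computed on the pooled value set across days/analysts
(total RSD) rather than by ANOVA variance components — simpler, monotone in
between-group shifts, and swappable if a components decomposition is ever
needed; bias enters the uncertainty budget as mean absolute bias. The
root-sum-of-squares combination is the standard top-down choice where the
guideline texts say only that trueness and reproducibility are "combined".

## The synthetic-data generator

Raw monitoring datasets are rarely deposited; published papers print
per-compound detection frequencies and concentration min/mean/max. The
generator turns exactly those printed summaries into surveys with the right
occurrence structure, so the full pipeline is testable end to end.

*Concentration law.* Residue concentrations are right-skewed and bounded by
what a survey actually reports, so detected concentrations follow a
log-normal truncated to `[cmin, cmax]`. Given a printed (min, mean, max),
`sdlog` is fixed at `log(cmax/cmin)/4` — ±2 sd of the untruncated law spans
the printed range — and `meanlog` is solved by `uniroot` on the closed-form
truncated mean, which is strictly monotone in `meanlog` with limits `cmin`
and `cmax`, so a root always exists for any mean strictly inside the range.
The closed form underflows for extreme `meanlog`; the implementation
returns the appropriate truncation limit in that regime so the root-finder
always sees a finite monotone function. Sampling is by inverse CDF
restricted to the truncation interval: deterministic per seed, with none of
the iteration-count nondeterminism of rejection sampling. `cmin = cmax`
degenerates to a point mass.

*Co-occurrence.* Surveys show far more multi-residue samples than
independent detections would give. The generator models this with a latent
per-sample contamination propensity `λ ~ Gamma(1/d, 1/d)` (mean 1, variance
`d`) multiplying every analyte's detection odds: a common-cause mechanism —
intensively treated fields carry more of everything. Because
`E[oλ/(1+oλ)] ≠ p` for `d > 0`, the baseline odds are calibrated by
root-finding over a fixed 2001-point gamma quantile grid so that the
*marginal* detection frequency stays exactly at the requested `p_detect`;
the grid makes calibration deterministic. `d = 0` recovers independence;
increasing `d` increases the variance of the per-sample residue count at
fixed marginals, which is the tested definition of "more co-occurrence".
The gamma-propensity form is an assumption: the real correlation structure
of pesticide applications (tank mixes, spray calendars) is not published,
and the generator makes no claim to reproduce any specific
province-by-analyte detection matrix.

*What passing tests show.* The generator reproduces detection frequencies,
concentration summaries and a heavy multi-residue tail. It does not emulate
seasonal trends, analyte-specific regional practices beyond optional odds
multipliers, measurement error near the LOQ, or correlated residues from
shared application events. Green tests therefore demonstrate that the
statistical machinery is correct on data with the right marginal structure
— not that any particular real-world survey would yield the same risk
figures.

*Problem sizes.* The test suite runs surveys of 14–905 samples and Monte
Carlo runs of 300–10,000 iterations: full survey scale where a published
interval is asserted (binomial recovery at n = 905, 10,000-iteration tail
and sensitivity checks), small scale where only an algebraic property is
at stake.

## Pipeline and reproducibility

`run_pipeline()` chains all stages from a programmatic or YAML config,
writing CSV tables and JSON summaries plus `manifest.json` (package
version, seed, scenario list, iteration counts, input paths, record
counts). The manifest plus inputs determine every numeric output exactly;
the tests assert byte-identical reruns and that disabling the simulation
stage leaves deterministic outputs untouched. Optional stages (validation
summary, risk ranking, the simulation itself) fail soft with a warning;
input errors fail fast naming the offending path or analyte.

## Known limitations

- Only IESTI Case 2a is implemented; commodities outside its applicability
  window error out instead of switching case.
- No processing factors (washing, peeling, pickling) in exposure; acute and
  chronic results refer to the raw commodity.
- The chronic simulation treats pesticides independently; no
  cumulative-assessment-group weighting for shared mechanisms of toxicity.
- One-dimensional Monte Carlo: variability and parameter uncertainty are
  not separated into nested loops.
- Published acute hazard quotients from some surveys are not reproducible
  from the IESTI formula and printed constants; this package follows the
  formula as defined and reports what it implies.
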