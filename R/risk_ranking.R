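# Matrix-based risk ranking in the style of the UK Veterinary Residues
# Committee: a composite score built from acute toxicity (A), toxic potency
# (B), dietary contribution (C), application frequency (D), vulnerable-group
# exposure (E, default 3) and a residue-level score (F) derived from the
# distribution of measured concentrations relative to the MRL.

#' Frequency of dosing
#'
#' Pesticide applications per crop growth period, as a percentage:
#' `FOD = 100 * N / P`.
#'
#' @param n_applications number of applications (>= 0).
#' @param growth_period_days crop growth period in days (> 0).
#' @export
frequency_of_dosing <- function(n_applications, growth_period_days) {
  if (any(growth_period_days <= 0)) {
    stop("growth period must be > 0 days", call. = FALSE)
  }
  if (any(n_applications < 0)) {
    stop("number of applications must be >= 0", call. = FALSE)
  }
  100 * n_applications / growth_period_days
}

#' Residue-level score F from MRL-band counts
#'
#' Weighted mean of MRL bands over all analysed samples:
#' `F = (F0*1 + F1*2 + F2*3 + F3*4) / n`, where F0 counts non-detects, F1
#' residues below the MRL, F2 residues from 1x up to and including 10x the
#' MRL, and F3 residues above 10x the MRL. Always in `[1, 4]`.
#'
#' @param f0,f1,f2,f3 band counts (>= 0).
#' @param n total samples; defaults to the band sum and must equal it.
#' @export
residue_level_score <- function(f0, f1, f2, f3, n = f0 + f1 + f2 + f3) {
  counts <- c(f0, f1, f2, f3)
  if (any(counts < 0)) stop("band counts must be >= 0", call. = FALSE)
  if (n <= 0) stop("total sample count must be > 0", call. = FALSE)
  if (sum(counts) != n) {
    stop("band counts (", sum(counts), ") do not sum to n (", n, ")",
         call. = FALSE)
  }
  (f0 * 1 + f1 * 2 + f2 * 3 + f3 * 4) / n
}

#' MRL-band counts for one analyte in a dataset
#'
#' Counts the samples in each residue-level band: F0 non-detect, F1 below
#' the MRL, F2 at 1x to 10x the MRL inclusive, F3 above 10x the MRL.
#'
#' @param dataset a `monitoring_dataset`.
#' @param analyte analyte name.
#' @param refs a `pesticide_ref`.
#' @return list with `f0`, `f1`, `f2`, `f3`, `n`.
#' @export
residue_level_counts <- function(dataset, analyte, refs) {
  mrl <- ref_lookup(refs, analyte, "mrl_mg_kg")
  x <- dataset$detections$concentration_mg_kg[
    dataset$detections$analyte == analyte]
  n <- nrow(dataset$samples)
  f1 <- sum(x < mrl)
  f2 <- sum(x >= mrl & x <= 10 * mrl)
  f3 <- sum(x > 10 * mrl)
  list(f0 = n - length(x), f1 = f1, f2 = f2, f3 = f3, n = n)
}

#' Composite risk score
#'
#' `S = (A + B) * (C + D + E) * F` with integer component scores A-E and the
#' residue-level score F in `[1, 4]`. The multiplicative grouping follows
#' the Veterinary Residues Committee matrix; a fully literal reading of the
#' formula as printed in some sources (`A + B*C + D + E*F`) is available via
#' `grouping = "literal"` for comparison.
#'
#' @param A acute-toxicity score (from LD50 bands).
#' @param B toxic-potency score (from ADI bands).
#' @param C dietary-contribution score (from consumption share).
#' @param D application-frequency score (from FOD bands).
#' @param E vulnerable-group score (default 3: no specific evidence).
#' @param f_score residue-level score F from [residue_level_score()].
#' @param grouping `"vrc"` (default) or `"literal"`.
#' @param band_max upper bound for the component bands (default 5).
#' @return list with `S` and `category` (see [risk_category()]).
#' @export
composite_score <- function(A, B, C, D, E = 3, f_score,
                            grouping = c("vrc", "literal"), band_max = 5) {
  grouping <- match.arg(grouping)
  comp <- c(A = A, B = B, C = C, D = D, E = E)
  if (any(comp != round(comp)) || any(comp < 1) || any(comp > band_max)) {
    stop("component scores A-E must be integers in [1, ", band_max, "]",
         call. = FALSE)
  }
  if (f_score < 1 || f_score > 4) {
    stop("residue-level score F must lie in [1, 4]", call. = FALSE)
  }
  S <- if (grouping == "vrc") (A + B) * (C + D + E) * f_score
       else A + B * C + D + E * f_score
  list(S = S, category = risk_category(S))
}

#' Risk category for a composite score
#'
#' high for `S >= 20`, medium for `15 <= S < 20`, low for `S < 15`
#' (half-open intervals resolve the boundary values appearing in two classes
#' in common phrasings of the scheme).
#'
#' @param S composite score(s), `>= 0`; vectorised.
#' @export
risk_category <- function(S) {
  if (any(is.na(S) | S < 0)) stop("scores must be >= 0", call. = FALSE)
  out <- character(length(S))
  out[S >= 20] <- "high"
  out[S >= 15 & S < 20] <- "medium"
  out[S < 15] <- "low"
  out
}

#' Rank pesticides by composite risk score
#'
#' Computes F from the dataset for every analyte in the component table,
#' evaluates the composite score and sorts descending. Analytes without an
#' established ADI in the reference table are excluded with a warning (their
#' potency component cannot be scored).
#'
#' @param components data frame with columns `analyte`, `A`, `B`, `C`, `D`
#'   and optionally `E` (default 3).
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref`.
#' @param ... passed to [composite_score()].
#' @return tibble sorted by decreasing `S` with the components, `f_score`,
#'   `S` and `category`.
#' @export
rank_pesticides <- function(components, dataset, refs, ...) {
  components <- tibble::as_tibble(components)
  if (!"E" %in% names(components)) components$E <- 3
  adi <- ref_lookup(refs, components$analyte, "adi_mg_kg_bw_day")
  if (any(is.na(adi))) {
    warning("excluded from risk scoring (no established ADI): ",
            paste(components$analyte[is.na(adi)], collapse = ", "),
            call. = FALSE)
    components <- components[!is.na(adi), ]
  }
  rows <- lapply(seq_len(nrow(components)), function(i) {
    cc <- components[i, ]
    bands <- residue_level_counts(dataset, cc$analyte, refs)
    f <- residue_level_score(bands$f0, bands$f1, bands$f2, bands$f3)
    sc <- composite_score(cc$A, cc$B, cc$C, cc$D, cc$E, f_score = f, ...)
    tibble::tibble(analyte = cc$analyte, A = cc$A, B = cc$B, C = cc$C,
                   D = cc$D, E = cc$E, f_score = f, S = sc$S,
                   category = sc$category)
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$S, out$analyte), ]
}
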