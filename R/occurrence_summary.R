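# Prevalence, multi-residue and MRL-exceedance statistics for a monitoring
# survey, with Pearson chi-square homogeneity tests across regions.

per_sample_counts <- function(dataset) {
  cnt <- table(dataset$detections$sample_id)
  out <- stats::setNames(integer(nrow(dataset$samples)),
                         dataset$samples$sample_id)
  out[names(cnt)] <- as.integer(cnt)
  out
}

#' Prevalence summary per province and overall
#'
#' For each province and for the pooled survey: sample count, number and
#' rate of contaminated samples (those with at least one quantified
#' residue), number of distinct residues detected, number of distinct
#' unauthorised compounds detected, and number of samples with at least one
#' MRL exceedance.
#'
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref` (supplies `authorised` and MRLs).
#' @return tibble with one row per province plus an `"Overall"` row.
#' @export
prevalence_summary <- function(dataset, refs) {
  if (nrow(dataset$samples) == 0) stop("empty dataset", call. = FALSE)
  det <- dataset$detections
  det$province <- dataset$samples$province[
    match(det$sample_id, dataset$samples$sample_id)]
  det$authorised <- ref_lookup(refs, det$analyte, "authorised")
  det$mrl <- ref_lookup(refs, det$analyte, "mrl_mg_kg")
  det$exceeds <- det$concentration_mg_kg > det$mrl
  strata <- c(sort(unique(dataset$samples$province)), "Overall")
  rows <- lapply(strata, function(pr) {
    if (pr == "Overall") {
      smp <- dataset$samples; d <- det
    } else {
      smp <- dataset$samples[dataset$samples$province == pr, ]
      d <- det[det$province == pr, ]
    }
    contaminated <- unique(d$sample_id)
    tibble::tibble(
      province = pr,
      n_samples = nrow(smp),
      n_contaminated = length(contaminated),
      detection_rate = length(contaminated) / nrow(smp),
      n_distinct_residues = length(unique(d$analyte)),
      n_unauthorised = length(unique(d$analyte[!d$authorised])),
      n_exceeding_mrl = length(unique(d$sample_id[d$exceeds])))
  })
  dplyr::bind_rows(rows)
}

#' Residue-count histogram across samples
#'
#' How many samples carry 0, 1, 2, ... quantified residues. Bin 0 counts the
#' residue-free samples; the histogram always sums to the number of samples.
#'
#' @param dataset a `monitoring_dataset`.
#' @return tibble with columns `n_residues`, `n_samples`.
#' @export
multi_residue_distribution <- function(dataset) {
  counts <- per_sample_counts(dataset)
  if (length(counts) == 0) {
    return(tibble::tibble(n_residues = integer(0), n_samples = integer(0)))
  }
  tab <- table(factor(counts, levels = 0:max(counts)))
  tibble::tibble(n_residues = as.integer(names(tab)),
                 n_samples = as.integer(tab))
}

#' MRL exceedance flags and per-province exceedance counts
#'
#' A detection is an exceedance iff its concentration is strictly above the
#' analyte's MRL (a residue exactly at the MRL is compliant); a sample
#' exceeds iff any of its residues does.
#'
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref`; every detected analyte must carry an MRL.
#' @return list with `detections` (per-detection tibble incl. `exceeds`) and
#'   `by_province` (tibble of sample-level exceedance counts).
#' @export
exceedance_table <- function(dataset, refs) {
  det <- dataset$detections
  det$mrl_mg_kg <- ref_lookup(refs, det$analyte, "mrl_mg_kg")
  det$exceeds <- det$concentration_mg_kg > det$mrl_mg_kg
  det$province <- dataset$samples$province[
    match(det$sample_id, dataset$samples$sample_id)]
  provs <- sort(unique(dataset$samples$province))
  by_prov <- tibble::tibble(
    province = provs,
    n_samples = vapply(provs, function(p)
      sum(dataset$samples$province == p), 0L, USE.NAMES = FALSE),
    n_exceeding = vapply(provs, function(p)
      length(unique(det$sample_id[det$province == p & det$exceeds])), 0L,
      USE.NAMES = FALSE))
  list(detections = tibble::as_tibble(det), by_province = by_prov)
}

#' Pearson chi-square homogeneity test across groups
#'
#' Tests whether a success proportion (e.g. contaminated samples, or MRL
#' exceedances among contaminated samples) is homogeneous across k groups,
#' via the Pearson statistic on the 2 x k success/failure table without
#' continuity correction, df = k - 1.
#'
#' @param successes,totals equal-length count vectors,
#'   `0 <= successes <= totals`, `totals > 0`.
#' @return list of class `chi2_result` with `statistic`, `df`, `p_value`.
#' @export
chi2_homogeneity <- function(successes, totals) {
  if (length(successes) != length(totals)) {
    stop("successes and totals must have equal length", call. = FALSE)
  }
  if (any(totals <= 0)) stop("totals must be positive", call. = FALSE)
  if (any(successes < 0 | successes > totals)) {
    stop("need 0 <= successes <= totals", call. = FALSE)
  }
  tab <- rbind(successes, totals - successes)
  # chisq.test's small-expected-count advisory is irrelevant here: the
  # statistic itself is exact; p-value interpretation is the caller's call
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value)),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square homogeneity: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
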