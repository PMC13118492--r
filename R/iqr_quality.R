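# Index of Quality for Residues (IqR): per-sample sum of the ratios of each
# quantified residue concentration to its MRL, with a four-category quality
# classification. The index is an unweighted sum by design: it accumulates
# regulatory pressure from multiple residues even when each one individually
# complies with its MRL.

#' IqR of a single sample
#'
#' `IqR = sum_i PRC_i / MRL_i` over the residues quantified in the sample;
#' non-detects contribute nothing, so a residue-free sample scores 0.
#'
#' @param detections named numeric vector of quantified concentrations
#'   (mg/kg), names are analytes; or a data frame with columns `analyte`,
#'   `concentration_mg_kg`. May be empty.
#' @param refs a `pesticide_ref`; every detected analyte must carry an MRL.
#' @return list with `iqr`, per-analyte `contributions`, and `category`.
#' @export
iqr_value <- function(detections, refs) {
  if (is.data.frame(detections)) {
    detections <- stats::setNames(detections$concentration_mg_kg,
                                  detections$analyte)
  }
  if (length(detections) == 0) {
    return(list(iqr = 0, contributions = stats::setNames(numeric(0),
                                                         character(0)),
                category = "excellent"))
  }
  mrl <- ref_lookup(refs, names(detections), "mrl_mg_kg")
  contributions <- detections / mrl
  iqr <- sum(contributions)
  list(iqr = iqr, contributions = contributions,
       category = iqr_category(iqr))
}

#' Quality category for an IqR value
#'
#' excellent (IqR = 0), good (0 < IqR <= 0.6), acceptable
#' (0.6 < IqR <= 1.0), unacceptable (IqR > 1.0). Boundaries inclusive to the
#' lower category. "adequate" is accepted as an alias of "acceptable" in
#' [normalise_iqr_category()].
#'
#' @param iqr nonnegative IqR value(s); vectorised.
#' @return character vector of categories.
#' @export
iqr_category <- function(iqr) {
  if (any(is.na(iqr) | iqr < 0)) {
    stop("IqR values must be >= 0", call. = FALSE)
  }
  out <- character(length(iqr))
  out[iqr == 0] <- "excellent"
  out[iqr > 0 & iqr <= 0.6] <- "good"
  out[iqr > 0.6 & iqr <= 1.0] <- "acceptable"
  out[iqr > 1.0] <- "unacceptable"
  out
}

#' Canonicalise an IqR category label
#'
#' @param category character vector; "adequate" maps to "acceptable".
#' @export
normalise_iqr_category <- function(category) {
  category[category == "adequate"] <- "acceptable"
  bad <- setdiff(unique(category),
                 c("excellent", "good", "acceptable", "unacceptable"))
  if (length(bad) > 0) {
    stop("unknown IqR category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  category
}

#' Per-sample IqR table for a monitoring dataset
#'
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref`.
#' @return tibble with `sample_id`, `province`, `n_residues`, `iqr`,
#'   `category`.
#' @export
sample_iqr <- function(dataset, refs) {
  det <- dataset$detections
  mrl <- if (nrow(det) > 0) ref_lookup(refs, det$analyte, "mrl_mg_kg")
         else numeric(0)
  ratio <- if (nrow(det) > 0) det$concentration_mg_kg / mrl else numeric(0)
  iqr <- stats::setNames(numeric(nrow(dataset$samples)),
                         dataset$samples$sample_id)
  if (nrow(det) > 0) {
    agg <- tapply(ratio, det$sample_id, sum)
    iqr[names(agg)] <- agg
  }
  nres <- per_sample_counts(dataset)
  tibble::tibble(sample_id = dataset$samples$sample_id,
                 province = dataset$samples$province,
                 n_residues = as.integer(nres),
                 iqr = unname(iqr),
                 category = iqr_category(unname(iqr)))
}

#' Quality-category proportions overall and per province
#'
#' Proportions of excellent/good/acceptable/unacceptable samples in each
#' province and pooled; proportions sum to 1 within each stratum, and the
#' excellent share equals the residue-free share by construction.
#'
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref`.
#' @return tibble with columns `province`, `category`, `n`, `proportion`.
#' @export
quality_profile <- function(dataset, refs) {
  if (nrow(dataset$samples) == 0) stop("empty dataset", call. = FALSE)
  per <- sample_iqr(dataset, refs)
  levels_cat <- c("excellent", "good", "acceptable", "unacceptable")
  strata <- c(sort(unique(per$province)), "Overall")
  rows <- lapply(strata, function(pr) {
    sub <- if (pr == "Overall") per else per[per$province == pr, ]
    tab <- table(factor(sub$category, levels = levels_cat))
    tibble::tibble(province = pr, category = levels_cat,
                   n = as.integer(tab),
                   proportion = as.integer(tab) / nrow(sub))
  })
  dplyr::bind_rows(rows)
}
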