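# Deterministic dietary exposure and risk characterisation: chronic intake
# (NEDI) and hazard quotient against the ADI, acute intake by the IESTI
# Case 2a model and hazard quotient against the ARfD (ADI fallback), and
# hazard indices summed over detected pesticides under LB/MB/UB treatment of
# non-detects.

#' Population exposure parameters
#'
#' Consumption, body weight and IESTI constants for a population group.
#' Defaults are the survey's gherkin values: daily per-capita consumption
#' 0.0011 kg (adult) / 0.0004 kg (child), body weight 70 kg / 23 kg, edible
#' unit weight 0.0544 kg, variability factor 3, large portion 0.168 kg /
#' 0.092 kg. Case 2a of the IESTI model requires
#' `0.025 kg <= ue_kg < lp_kg`, which is validated here.
#'
#' @param population `"adult"` or `"child"`.
#' @param consumption_kg_day mean daily consumption (kg/day).
#' @param bw_kg body weight (kg).
#' @param ue_kg edible-portion unit weight (kg).
#' @param v unit-to-unit variability factor.
#' @param lp_kg large portion size (kg).
#' @return list of class `exposure_params`.
#' @export
exposure_params <- function(population = c("adult", "child"),
                            consumption_kg_day = NULL, bw_kg = NULL,
                            ue_kg = 0.0544, v = 3, lp_kg = NULL) {
  population <- match.arg(population)
  defaults <- list(
    adult = list(consumption = 0.0011, bw = 70, lp = 0.168),
    child = list(consumption = 0.0004, bw = 23, lp = 0.092))[[population]]
  if (is.null(consumption_kg_day)) consumption_kg_day <- defaults$consumption
  if (is.null(bw_kg)) bw_kg <- defaults$bw
  if (is.null(lp_kg)) lp_kg <- defaults$lp
  vals <- c(consumption_kg_day, bw_kg, ue_kg, v, lp_kg)
  if (any(is.na(vals) | vals <= 0)) {
    stop("all exposure parameters must be positive", call. = FALSE)
  }
  if (ue_kg < 0.025) {
    stop("IESTI Case 2a requires an edible-unit weight of at least 0.025 kg ",
         "(got ", ue_kg, ")", call. = FALSE)
  }
  if (ue_kg >= lp_kg) {
    stop("IESTI Case 2a requires the unit weight to be smaller than the ",
         "large portion (Ue = ", ue_kg, ", LP = ", lp_kg, ")", call. = FALSE)
  }
  structure(list(population = population,
                 consumption_kg_day = consumption_kg_day, bw_kg = bw_kg,
                 ue_kg = ue_kg, v = v, lp_kg = lp_kg),
            class = "exposure_params")
}

#' National estimated daily intake (chronic)
#'
#' `NEDI = mean residue concentration x consumption / body weight`, in
#' mg/kg bw/day.
#'
#' @param mean_conc mean residue concentration (mg/kg), >= 0.
#' @param params an [exposure_params()].
#' @export
nedi <- function(mean_conc, params) {
  if (any(mean_conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  mean_conc * params$consumption_kg_day / params$bw_kg
}

#' Chronic hazard quotient
#'
#' `HQc = NEDI / ADI` (dimensionless).
#'
#' @param nedi chronic intake (mg/kg bw/day).
#' @param adi acceptable daily intake (mg/kg bw/day), > 0.
#' @export
hq_chronic <- function(nedi, adi) {
  if (any(is.na(adi) | adi <= 0)) stop("ADI must be > 0", call. = FALSE)
  nedi / adi
}

#' IESTI Case 2a acute intake
#'
#' `IESTI = (Ue * HR * v + (LP - Ue) * HR) / bw` in mg/kg bw: the first
#' consumed unit carries the variability factor `v`, the remainder of the
#' large portion carries the composite-level residue. Applicable only when
#' `0.025 <= Ue < LP`, which [exposure_params()] guarantees.
#'
#' @param hr highest residue observed for the pesticide (mg/kg), >= 0.
#' @param params an [exposure_params()].
#' @export
iesti_case2a <- function(hr, params) {
  if (any(hr < 0)) stop("highest residue must be >= 0", call. = FALSE)
  (params$ue_kg * hr * params$v + (params$lp_kg - params$ue_kg) * hr) /
    params$bw_kg
}

#' Acute hazard quotient with ADI fallback
#'
#' `HQa = IESTI / ARfD`; for compounds without an established ARfD the ADI
#' is applied conservatively instead and the fallback is flagged.
#'
#' @param iesti acute intake (mg/kg bw).
#' @param arfd acute reference dose (mg/kg bw) or `NA`.
#' @param adi acceptable daily intake (mg/kg bw/day) or `NA`.
#' @return list with `hq` and `arfd_fallback`.
#' @export
hq_acute <- function(iesti, arfd = NA_real_, adi = NA_real_) {
  if (!is.na(arfd) && arfd > 0) {
    return(list(hq = iesti / arfd, arfd_fallback = FALSE))
  }
  if (!is.na(adi) && adi > 0) {
    return(list(hq = iesti / adi, arfd_fallback = TRUE))
  }
  stop("neither ARfD nor ADI available for the acute hazard quotient",
       call. = FALSE)
}

#' Hazard index
#'
#' Sum of hazard quotients over pesticides; risk is considered acceptable
#' while the index stays strictly below 1.
#'
#' @param hqs finite, nonnegative hazard quotients (may be empty).
#' @return list with `hi` and `acceptable`.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) return(list(hi = 0, acceptable = TRUE))
  if (any(!is.finite(hqs)) || any(hqs < 0)) {
    stop("hazard quotients must be finite and >= 0", call. = FALSE)
  }
  hi <- sum(hqs)
  list(hi = hi, acceptable = hi < 1)
}

#' Deterministic exposure and risk report
#'
#' Runs the full deterministic chain for every detected pesticide: mean
#' concentration and NEDI/HQc per censoring scenario and population, highest
#' residue and IESTI/HQa per population, hazard indices, and each
#' pesticide's contribution share to the chronic hazard index. Pesticides
#' without an established ADI are excluded with a warning.
#'
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref`.
#' @param params named list of [exposure_params()], one per population
#'   (default adult + child).
#' @param policies censoring scenarios to run (default LB, MB, UB).
#' @return list of class `hazard_result` with tibbles `chronic`, `acute`,
#'   `hi`, and character vector `excluded`.
#' @export
scenario_report <- function(dataset, refs,
                            params = list(adult = exposure_params("adult"),
                                          child = exposure_params("child")),
                            policies = c("LB", "MB", "UB")) {
  detected <- sort(unique(dataset$detections$analyte))
  adi <- ref_lookup(refs, detected, "adi_mg_kg_bw_day")
  excluded <- detected[is.na(adi)]
  if (length(excluded) > 0) {
    warning("excluded from exposure assessment (no established ADI): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  detected <- detected[!is.na(adi)]
  chronic <- list(); acute <- list()
  for (a in detected) {
    adi_a <- ref_lookup(refs, a, "adi_mg_kg_bw_day")
    arfd_a <- ref_lookup(refs, a, "arfd_mg_kg_bw")
    hr <- max(dataset$detections$concentration_mg_kg[
      dataset$detections$analyte == a])
    means <- vapply(policies, function(p)
      mean_concentration(dataset, a, p, refs), 0)
    for (pop in names(params)) {
      pp <- params[[pop]]
      ned <- nedi(means, pp)
      chronic[[length(chronic) + 1]] <- tibble::tibble(
        analyte = a, population = pop, policy = policies,
        mean_conc = unname(means), nedi = unname(ned),
        hqc = unname(hq_chronic(ned, adi_a)))
      ie <- iesti_case2a(hr, pp)
      ha <- hq_acute(ie, arfd_a, adi_a)
      acute[[length(acute) + 1]] <- tibble::tibble(
        analyte = a, population = pop, hr = hr, iesti = ie, hqa = ha$hq,
        arfd_fallback = ha$arfd_fallback)
    }
  }
  chronic <- if (length(chronic) > 0) dplyr::bind_rows(chronic) else
    tibble::tibble(analyte = character(0), population = character(0),
                   policy = character(0), mean_conc = numeric(0),
                   nedi = numeric(0), hqc = numeric(0))
  acute <- if (length(acute) > 0) dplyr::bind_rows(acute) else
    tibble::tibble(analyte = character(0), population = character(0),
                   hr = numeric(0), iesti = numeric(0), hqa = numeric(0),
                   arfd_fallback = logical(0))
  hi_rows <- list()
  for (pop in names(params)) {
    for (p in policies) {
      sub <- chronic[chronic$population == pop & chronic$policy == p, ]
      h <- hazard_index(sub$hqc)
      hi_rows[[length(hi_rows) + 1]] <- tibble::tibble(
        population = pop, type = "chronic", policy = p, hi = h$hi,
        acceptable = h$acceptable)
    }
    suba <- acute[acute$population == pop, ]
    h <- hazard_index(suba$hqa)
    hi_rows[[length(hi_rows) + 1]] <- tibble::tibble(
      population = pop, type = "acute", policy = NA_character_, hi = h$hi,
      acceptable = h$acceptable)
  }
  hi <- dplyr::bind_rows(hi_rows)
  # contribution share of each pesticide to the chronic hazard index
  if (nrow(chronic) > 0) {
    chronic <- dplyr::mutate(
      dplyr::group_by(chronic, .data$population, .data$policy),
      hic_share = if (sum(.data$hqc) > 0) .data$hqc / sum(.data$hqc) else
        0 * .data$hqc)
    chronic <- dplyr::ungroup(chronic)
  } else {
    chronic$hic_share <- numeric(0)
  }
  structure(list(chronic = chronic, acute = acute, hi = hi,
                 excluded = excluded),
            class = "hazard_result")
}
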