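# SANTE-style method-validation statistics for fortified-replicate data:
# recovery, repeatability and within-lab reproducibility RSD, LOQ from blank
# replicates, top-down expanded uncertainty, calibration linearity and the
# retention-time / ion-ratio identification tolerances.

#' Recovery percentage from a fortification experiment
#'
#' @param measured_mean mean measured concentration (mg/kg).
#' @param spike_level fortification level (mg/kg), positive.
#' @return recovery in percent, `100 * measured_mean / spike_level`.
#' @export
recovery_percent <- function(measured_mean, spike_level) {
  if (any(spike_level <= 0)) stop("spike_level must be > 0", call. = FALSE)
  100 * measured_mean / spike_level
}

#' Relative standard deviation of a replicate set
#'
#' Sample (n-1) standard deviation as a percentage of the mean.
#'
#' @param values at least two replicate measurements with nonzero mean.
#' @export
rsd_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicates", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Within-laboratory reproducibility RSD
#'
#' RSD of the pooled value set across all day/analyst groups (total RSD, not
#' an ANOVA variance-components split): between-group shifts inflate the
#' pooled spread and therefore the result, which is the intended behaviour
#' for a reproducibility figure.
#'
#' @param groups list of replicate vectors, one per day/analyst combination.
#' @export
within_lab_rsd <- function(groups) {
  if (!is.list(groups)) groups <- list(groups)
  if (length(groups) == 0 || all(lengths(groups) == 0)) {
    stop("no replicate groups supplied", call. = FALSE)
  }
  rsd_percent(unlist(groups, use.names = FALSE))
}

#' LOQ estimate from blank replicate analyses
#'
#' Ten times the sample standard deviation of replicate analyses of blank
#' (low-fortified) samples.
#'
#' @param blank_replicates replicate measurements (mg/kg).
#' @param n_expected required replicate count (default 10); `NULL` disables
#'   the count check.
#' @return LOQ in mg/kg; an all-equal replicate set gives 0, which callers
#'   should treat as below any practical reporting floor.
#' @export
loq_estimate <- function(blank_replicates, n_expected = 10) {
  if (length(blank_replicates) < 2) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  if (!is.null(n_expected) && length(blank_replicates) != n_expected) {
    stop("expected ", n_expected, " replicates, got ",
         length(blank_replicates), call. = FALSE)
  }
  10 * stats::sd(blank_replicates)
}

#' Expanded measurement uncertainty (top-down)
#'
#' Combines trueness (bias) and within-laboratory reproducibility by
#' root-sum-of-squares and applies a coverage factor:
#' `U = k * sqrt(bias^2 + rsdwr^2)`, both inputs in percent.
#'
#' @param bias_pct mean absolute bias, percent.
#' @param rsdwr_pct within-lab reproducibility RSD, percent.
#' @param k coverage factor (default 2, ~95% coverage).
#' @export
expanded_uncertainty <- function(bias_pct, rsdwr_pct, k = 2) {
  if (k <= 0) stop("coverage factor k must be > 0", call. = FALSE)
  k * sqrt(bias_pct^2 + rsdwr_pct^2)
}

#' Calibration linearity (R-squared)
#'
#' Ordinary least-squares coefficient of determination of instrument
#' response on concentration level.
#'
#' @param levels calibration concentrations (>= 3 points).
#' @param responses instrument responses.
#' @return R-squared; a constant response returns 0.
#' @export
linearity <- function(levels, responses) {
  if (length(levels) < 3 || length(levels) != length(responses)) {
    stop("need >= 3 matching calibration points", call. = FALSE)
  }
  if (stats::sd(responses) == 0) return(0)
  fit <- stats::lm(responses ~ levels)
  1 - sum(stats::resid(fit)^2) / sum((responses - mean(responses))^2)
}

#' Analyte identification check
#'
#' SANTE identification tolerances: retention time within +/- `rt_tol`
#' minutes of the reference, relative ion-ratio deviation within
#' `ratio_tol`. Both bounds inclusive.
#'
#' @param rt_sample,rt_reference retention times (min).
#' @param ion_ratio_sample,ion_ratio_reference ion ratios (fractions),
#'   reference must be positive.
#' @param rt_tol retention-time tolerance (min, default 0.1).
#' @param ratio_tol relative ion-ratio tolerance (default 0.30).
#' @return list with `rt_pass`, `ion_ratio_pass`, `pass`.
#' @export
identification_check <- function(rt_sample, rt_reference, ion_ratio_sample,
                                 ion_ratio_reference, rt_tol = 0.1,
                                 ratio_tol = 0.30) {
  if (ion_ratio_reference <= 0) {
    stop("reference ion ratio must be > 0", call. = FALSE)
  }
  rt_pass <- abs(rt_sample - rt_reference) <= rt_tol
  dev <- abs(ion_ratio_sample - ion_ratio_reference) / ion_ratio_reference
  ion_pass <- dev <= ratio_tol
  list(rt_pass = rt_pass, ion_ratio_pass = ion_pass,
       pass = rt_pass && ion_pass)
}

#' Assemble a method-validation report
#'
#' @param recovery_pct,rsdr_pct,rsdwr_pct percentages.
#' @param loq LOQ (mg/kg).
#' @param expanded_uncertainty_pct expanded uncertainty U, percent.
#' @param r_squared calibration R-squared.
#' @param k coverage factor used for U (default 2).
#' @return list of class `validation_report`.
#' @export
validation_report <- function(recovery_pct, rsdr_pct, rsdwr_pct, loq,
                              expanded_uncertainty_pct, r_squared, k = 2) {
  pct <- c(recovery_pct, rsdr_pct, rsdwr_pct, expanded_uncertainty_pct)
  if (any(pct < 0, na.rm = TRUE)) {
    stop("percentages must be >= 0", call. = FALSE)
  }
  structure(list(recovery_pct = recovery_pct, rsdr_pct = rsdr_pct,
                 rsdwr_pct = rsdwr_pct, loq = loq,
                 expanded_uncertainty_pct = expanded_uncertainty_pct,
                 r_squared = r_squared, k = k),
            class = "validation_report")
}

#' SANTE compliance flags for a validation report
#'
#' All windows inclusive: recovery within `recovery_range`, RSDr and
#' RSD_WR at or below `rsd_max`, expanded uncertainty at or below
#' `uncertainty_max`.
#'
#' @param report a [validation_report()].
#' @param recovery_range acceptable recovery window, percent (default
#'   `c(70, 120)`).
#' @param rsd_max maximum acceptable RSD, percent (default 20).
#' @param uncertainty_max default expanded-uncertainty ceiling, percent
#'   (default 50).
#' @return list of logical flags plus overall `compliant`.
#' @export
sante_compliance <- function(report, recovery_range = c(70, 120),
                             rsd_max = 20, uncertainty_max = 50) {
  flags <- list(
    recovery_ok = !is.na(report$recovery_pct) &&
      report$recovery_pct >= recovery_range[1] &&
      report$recovery_pct <= recovery_range[2],
    rsdr_ok = !is.na(report$rsdr_pct) && report$rsdr_pct <= rsd_max,
    rsdwr_ok = !is.na(report$rsdwr_pct) && report$rsdwr_pct <= rsd_max,
    uncertainty_ok = is.na(report$expanded_uncertainty_pct) ||
      report$expanded_uncertainty_pct <= uncertainty_max)
  flags$compliant <- all(unlist(flags))
  flags
}

#' Summarise a fortified-replicate validation table
#'
#' Per analyte and spike level: recovery from the grand mean, repeatability
#' RSDr within the first day/analyst group, within-lab RSD across all
#' groups, and the compliance flags.
#'
#' @param df data frame with columns `analyte`, `spike_level`, `value`,
#'   `day`, `analyst`.
#' @param ... passed to [sante_compliance()].
#' @return tibble with one row per (analyte, spike_level).
#' @export
summarise_validation <- function(df, ...) {
  required <- c("analyte", "spike_level", "value", "day", "analyst")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("validation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  keys <- unique(df[c("analyte", "spike_level")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$analyte == keys$analyte[i] &
                df$spike_level == keys$spike_level[i], ]
    groups <- split(sub$value, paste(sub$day, sub$analyst, sep = "/"))
    rec <- recovery_percent(mean(sub$value), keys$spike_level[i])
    rsdr <- if (length(groups[[1]]) >= 2) rsd_percent(groups[[1]]) else NA_real_
    rsdwr <- if (length(sub$value) >= 2) within_lab_rsd(groups) else NA_real_
    bias <- abs(rec - 100)
    rep <- validation_report(rec, rsdr, rsdwr, loq = NA_real_,
                             expanded_uncertainty_pct =
                               if (is.na(rsdwr)) NA_real_ else
                                 expanded_uncertainty(bias, rsdwr),
                             r_squared = NA_real_)
    fl <- sante_compliance(rep, ...)
    tibble::tibble(analyte = keys$analyte[i],
                   spike_level = keys$spike_level[i],
                   n = nrow(sub), recovery_pct = rec, rsdr_pct = rsdr,
                   rsdwr_pct = rsdwr,
                   expanded_uncertainty_pct = rep$expanded_uncertainty_pct,
                   compliant = fl$compliant)
  })
  dplyr::bind_rows(rows)
}
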