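# Probabilistic chronic-risk characterisation by Monte Carlo simulation:
# log-normal residue concentrations and consumption, truncated-normal body
# weight, per-iteration hazard index, percentile reporting and a
# rank-correlation contribution-to-variance sensitivity analysis.

lnorm_from_moments <- function(m, v) {
  if (m <= 0) stop("mean must be positive for a log-normal fit", call. = FALSE)
  if (v <= 0) return(list(meanlog = log(m), sdlog = 0))
  sd2 <- log(1 + v / m^2)
  list(meanlog = log(m) - sd2 / 2, sdlog = sqrt(sd2))
}

#' Fit input distributions for the Monte Carlo simulation
#'
#' Per-pesticide log-normal concentration laws fitted by the method of
#' moments to the censoring-substituted concentration vectors; a log-normal
#' consumption law and a positive-truncated normal body-weight law built
#' from the population parameters with configurable coefficients of
#' variation. Under the LB policy non-detects are zero, which a log scale
#' cannot carry: zeros are floored at `lb_floor` (default half the smallest
#' positive LOQ on the panel) before fitting, and an all-zero vector is an
#' error suggesting MB/UB.
#'
#' @param dataset a `monitoring_dataset`.
#' @param refs a `pesticide_ref`.
#' @param policy censoring policy for the substitution (default `"MB"`).
#' @param params an [exposure_params()] giving the population means.
#' @param consumption_cv coefficient of variation of daily consumption
#'   (default 0.20).
#' @param bw_cv coefficient of variation of body weight (default 0.15).
#' @param lb_floor positive floor for LB zeros before the log transform.
#' @param analytes analytes to fit; defaults to the detected compounds (the
#'   chronic-intake framing sums over detected pesticides). Passing the full
#'   panel includes pure non-detect columns, which carry no information
#'   under LB and raise an error there.
#' @return list of class `distribution_spec` with `residues` (tibble:
#'   `analyte`, `meanlog`, `sdlog`, `adi`), `consumption`, `bw`,
#'   `population`, `policy`.
#' @export
fit_distributions <- function(dataset, refs, policy = "MB",
                              params = exposure_params("adult"),
                              consumption_cv = 0.20, bw_cv = 0.15,
                              lb_floor = NULL, analytes = NULL) {
  detected <- if (is.null(analytes)) {
    sort(unique(dataset$detections$analyte))
  } else {
    as.character(analytes)
  }
  adi <- ref_lookup(refs, detected, "adi_mg_kg_bw_day")
  if (any(is.na(adi))) {
    warning("excluded from simulation (no established ADI): ",
            paste(detected[is.na(adi)], collapse = ", "), call. = FALSE)
    detected <- detected[!is.na(adi)]
    adi <- adi[!is.na(adi)]
  }
  if (length(detected) == 0) stop("no pesticides to simulate", call. = FALSE)
  if (is.null(lb_floor)) {
    loqs <- ref_lookup(refs, detected, "loq_mg_kg")
    lb_floor <- min(loqs[loqs > 0]) / 2
  }
  rows <- lapply(seq_along(detected), function(i) {
    x <- substitute_censored(dataset, detected[i], policy, refs)
    if (length(x) < 2) stop("need at least 2 values per pesticide",
                            call. = FALSE)
    if (all(x == 0)) {
      stop("all-zero concentration vector for ", detected[i], " under LB; ",
           "use the MB or UB policy (or set lb_floor)", call. = FALSE)
    }
    x[x == 0] <- lb_floor
    fit <- lnorm_from_moments(mean(x), stats::var(x))
    tibble::tibble(analyte = detected[i], meanlog = fit$meanlog,
                   sdlog = fit$sdlog, adi = adi[i])
  })
  cons <- lnorm_from_moments(params$consumption_kg_day,
                             (consumption_cv * params$consumption_kg_day)^2)
  structure(list(residues = dplyr::bind_rows(rows),
                 consumption = cons,
                 bw = list(mean = params$bw_kg, sd = bw_cv * params$bw_kg),
                 population = params$population, policy = policy),
            class = "distribution_spec")
}

#' Monte Carlo simulation settings
#'
#' @param iterations iteration count (default 10000).
#' @param seed integer seed.
#' @param population population label carried into the result.
#' @export
mcs_config <- function(iterations = 10000, seed = 1L,
                       population = "adult") {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed), population = population),
            class = "mcs_config")
}

r_trunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean <= 0) stop("degenerate body weight must be positive",
                        call. = FALSE)
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {   # resample, never clip: truncation at 0
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Run the chronic-exposure Monte Carlo simulation
#'
#' Per iteration, draws one concentration per pesticide, one consumption
#' value and one body weight (all independent), forms
#' `HQ_p = conc_p * consumption / bw / ADI_p` and the hazard index
#' `HIc = sum_p HQ_p`. Reproducible given the config seed.
#'
#' @param spec a [fit_distributions()] result (or hand-built
#'   `distribution_spec`).
#' @param config an [mcs_config()].
#' @return list of class `mcs_result` with `summary` (mean, median, p5,
#'   p95), `prob_exceed_unity`, `per_pesticide` (P(HQ > 1) per compound),
#'   `hi_samples`, and `inputs` (per-iteration draws for the sensitivity
#'   analysis).
#' @export
run_mcs <- function(spec, config = mcs_config()) {
  n <- config$iterations
  set.seed(config$seed)
  res <- spec$residues
  conc <- matrix(0, nrow = n, ncol = nrow(res),
                 dimnames = list(NULL, res$analyte))
  for (j in seq_len(nrow(res))) {
    conc[, j] <- if (res$sdlog[j] == 0) rep(exp(res$meanlog[j]), n) else
      stats::rlnorm(n, res$meanlog[j], res$sdlog[j])
  }
  consumption <- if (spec$consumption$sdlog == 0)
    rep(exp(spec$consumption$meanlog), n) else
      stats::rlnorm(n, spec$consumption$meanlog, spec$consumption$sdlog)
  bw <- r_trunc_norm_pos(n, spec$bw$mean, spec$bw$sd)
  hq <- conc * (consumption / bw) / rep(res$adi, each = n)
  hi <- rowSums(hq)
  q <- stats::quantile(hi, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  inputs <- as.data.frame(conc)
  inputs$consumption <- consumption
  inputs$bw <- bw
  structure(list(
    summary = list(mean = mean(hi), median = q[2], p5 = q[1], p95 = q[3]),
    prob_exceed_unity = mean(hi > 1),
    per_pesticide = tibble::tibble(
      analyte = res$analyte,
      prob_hq_exceed_unity = unname(colMeans(hq > 1))),
    hi_samples = hi,
    inputs = inputs,
    config = config, population = spec$population),
    class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf(paste0("<mcs_result> %d iterations (%s)\n",
                     "  HIc mean %.4g, median %.4g, p5 %.4g, p95 %.4g\n",
                     "  P(HIc > 1) = %.4g\n"),
              x$config$iterations, x$population, x$summary$mean,
              x$summary$median, x$summary$p5, x$summary$p95,
              x$prob_exceed_unity))
  invisible(x)
}

#' Contribution-to-variance sensitivity analysis
#'
#' Attributes the variability of the simulated hazard index to the model
#' inputs. The default measure is the signed squared Spearman rank
#' correlation between each input's draws and the HIc draws, normalised so
#' the absolute contributions sum to 100% (the convention of common
#' spreadsheet risk tools); `method = "src"` instead uses standardized
#' regression coefficients from a linear fit on scaled inputs.
#'
#' @param inputs data frame of per-iteration input draws (columns = inputs).
#' @param hi_samples per-iteration hazard-index vector, aligned with
#'   `inputs` rows.
#' @param method `"spearman"` (default) or `"src"`.
#' @return tibble with `input`, `contribution_pct` (signed) and `rank`,
#'   sorted by absolute contribution.
#' @export
sensitivity_analysis <- function(inputs, hi_samples,
                                 method = c("spearman", "src")) {
  method <- match.arg(method)
  if (nrow(inputs) != length(hi_samples)) {
    stop("inputs and hi_samples must be aligned by iteration", call. = FALSE)
  }
  vars <- vapply(inputs, stats::var, 0)
  if (any(vars == 0)) {
    warning("zero-variance input(s) contribute 0: ",
            paste(names(inputs)[vars == 0], collapse = ", "), call. = FALSE)
  }
  if (method == "spearman") {
    coefs <- vapply(seq_along(inputs), function(j) {
      if (vars[j] == 0 || stats::var(hi_samples) == 0) return(0)
      stats::cor(inputs[[j]], hi_samples, method = "spearman")
    }, 0)
  } else {
    keep <- vars > 0
    coefs <- numeric(ncol(inputs))
    if (any(keep) && stats::var(hi_samples) > 0) {
      df <- as.data.frame(scale(inputs[keep]))
      fit <- stats::lm(scale(hi_samples) ~ ., data = df)
      coefs[keep] <- stats::coef(fit)[-1]
    }
  }
  total <- sum(coefs^2)
  contribution <- if (total == 0) coefs * 0 else
    sign(coefs) * 100 * coefs^2 / total
  out <- tibble::tibble(input = names(inputs),
                        contribution_pct = contribution)
  out <- out[order(-abs(out$contribution_pct)), ]
  out$rank <- seq_len(nrow(out))
  out
}
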