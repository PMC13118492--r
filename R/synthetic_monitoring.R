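# Truncated log-normal machinery. The closed form for the mean of a
# log-normal restricted to [a, b] underflows for extreme mu; the helper
# falls back to the appropriate truncation boundary in that regime so the
# root-finder always sees a monotone, finite function.
trunc_lnorm_mean <- function(meanlog, sdlog, a, b) {
  if (sdlog == 0) return(min(max(exp(meanlog), a), b))
  la <- log(a); lb <- log(b)
  den <- stats::pnorm((lb - meanlog) / sdlog) -
    stats::pnorm((la - meanlog) / sdlog)
  if (!is.finite(den) || den < 1e-300) {
    return(if (meanlog < (la + lb) / 2) a else b)
  }
  num <- exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm((lb - meanlog - sdlog^2) / sdlog) -
       stats::pnorm((la - meanlog - sdlog^2) / sdlog))
  min(max(num / den, a), b)
}

# Inverse-CDF sampler for a log-normal truncated to [a, b]; deterministic
# given the stream of uniforms, which keeps datasets reproducible per seed.
r_trunc_lnorm <- function(n, meanlog, sdlog, a, b) {
  if (n == 0) return(numeric(0))
  if (sdlog == 0) return(rep(min(max(exp(meanlog), a), b), n))
  pa <- stats::plnorm(a, meanlog, sdlog)
  pb <- stats::plnorm(b, meanlog, sdlog)
  u <- stats::runif(n, pa, pb)
  pmin(pmax(stats::qlnorm(u, meanlog, sdlog), a), b)
}

#' Occurrence specification for one analyte
#'
#' Describes how an analyte occurs in a synthetic monitoring survey: a
#' per-sample detection probability and a log-normal concentration law
#' truncated to `[cmin, cmax]` for the detected values.
#'
#' @param analyte analyte name.
#' @param p_detect per-sample detection probability in `[0, 1]`.
#' @param meanlog,sdlog log-normal parameters on the log scale; `sdlog = 0`
#'   yields a point mass.
#' @param cmin,cmax truncation bounds (mg/kg), `cmin <= cmax`.
#' @param province_multipliers optional named vector of per-region odds
#'   multipliers applied to the detection odds.
#' @return an object of class `occurrence_spec`.
#' @export
occurrence_spec <- function(analyte, p_detect, meanlog, sdlog, cmin, cmax,
                            province_multipliers = NULL) {
  stopifnot(length(analyte) == 1, length(p_detect) == 1)
  if (is.na(p_detect) || p_detect < 0 || p_detect > 1) {
    stop("p_detect must lie in [0, 1]", call. = FALSE)
  }
  if (sdlog < 0) stop("sdlog must be >= 0", call. = FALSE)
  if (!(cmin > 0 && cmax >= cmin)) {
    stop("need 0 < cmin <= cmax", call. = FALSE)
  }
  if (!is.null(province_multipliers)) {
    if (is.null(names(province_multipliers)) ||
        any(province_multipliers <= 0)) {
      stop("province_multipliers must be a named vector of positive odds ",
           "multipliers", call. = FALSE)
    }
  }
  structure(list(analyte = as.character(analyte), p_detect = p_detect,
                 meanlog = meanlog, sdlog = sdlog, cmin = cmin, cmax = cmax,
                 province_multipliers = province_multipliers),
            class = "occurrence_spec")
}

#' Build an occurrence spec from printed summary statistics
#'
#' Monitoring reports print, per analyte, a detection frequency and the
#' min/mean/max of the quantified concentrations. This solves for a
#' truncated log-normal on `[cmin, cmax]` whose mean matches `cmean`:
#' `sdlog` is fixed at `log(cmax/cmin)/4` (so roughly +/- 2 sd of the
#' untruncated law spans the printed range) and `meanlog` is found by
#' root-finding on the closed-form truncated mean, which is monotone in
#' `meanlog` with limits `cmin` and `cmax`.
#'
#' @param analyte analyte name.
#' @param p_detect printed detection frequency.
#' @param cmin,cmean,cmax printed minimum, mean, maximum concentration
#'   (mg/kg), `loq <= cmin <= cmean <= cmax`.
#' @param loq limit of quantification (mg/kg).
#' @param province_multipliers optional per-region odds multipliers.
#' @return an `occurrence_spec` whose truncated mean is within 0.1% of
#'   `cmean` (exact to solver tolerance; degenerate `cmin == cmax` gives a
#'   point mass).
#' @export
build_spec_from_summary <- function(analyte, p_detect, cmin, cmean, cmax,
                                    loq = 0.01, province_multipliers = NULL) {
  if (!(loq <= cmin && cmin <= cmean && cmean <= cmax)) {
    stop("need loq <= cmin <= cmean <= cmax", call. = FALSE)
  }
  if (cmin == cmax) {
    return(occurrence_spec(analyte, p_detect, meanlog = log(cmin), sdlog = 0,
                           cmin = cmin, cmax = cmax,
                           province_multipliers = province_multipliers))
  }
  sdlog <- log(cmax / cmin) / 4
  f <- function(mu) trunc_lnorm_mean(mu, sdlog, cmin, cmax) - cmean
  lo <- log(cmin) - 5 * sdlog
  hi <- log(cmax) + 5 * sdlog
  meanlog <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  spec <- occurrence_spec(analyte, p_detect, meanlog, sdlog, cmin, cmax,
                          province_multipliers = province_multipliers)
  achieved <- trunc_lnorm_mean(meanlog, sdlog, cmin, cmax)
  if (abs(achieved - cmean) > 0.05 * cmean) {
    stop("could not match the target mean within 5%: achieved ", achieved,
         call. = FALSE)
  }
  spec
}

#' Read occurrence specs from a summary CSV
#'
#' @param path CSV with columns `analyte`, `p_detect`, `cmin`, `cmean`,
#'   `cmax` and optionally `loq` (defaults to `loq`).
#' @param loq default LOQ (mg/kg) for rows without their own.
#' @return list of `occurrence_spec`.
#' @export
read_spec_table <- function(path, loq = 0.01) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("analyte", "p_detect", "cmin", "cmean", "cmax")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("spec table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$loq)) df$loq <- loq
  lapply(seq_len(nrow(df)), function(i) {
    build_spec_from_summary(df$analyte[i], df$p_detect[i], df$cmin[i],
                            df$cmean[i], df$cmax[i], loq = df$loq[i])
  })
}

#' Multi-residue co-occurrence model
#'
#' Residues in monitoring surveys co-occur: a sample from an intensively
#' treated field tends to carry several compounds at once. The model places
#' a latent gamma-distributed contamination propensity on each sample
#' (mean 1, variance `dispersion`) that multiplies the detection odds of
#' every analyte. `dispersion = 0` recovers independent detections.
#'
#' @param dispersion nonnegative variance of the latent propensity.
#' @export
cooccurrence_model <- function(dispersion = 0) {
  if (is.na(dispersion) || dispersion < 0) {
    stop("dispersion must be >= 0", call. = FALSE)
  }
  structure(list(dispersion = dispersion), class = "cooccurrence_model")
}

# Baseline odds such that the marginal detection probability stays at p once
# the gamma propensity multiplier is integrated out. Solved on a fixed
# quantile grid of the gamma law (deterministic quadrature, no extra
# randomness), where E[o*L/(1+o*L)] is monotone increasing in o.
calibrate_odds <- function(p, dispersion, grid = 2001) {
  if (p <= 0) return(0)
  if (p >= 1) return(Inf)
  if (dispersion == 0) return(p / (1 - p))
  shape <- 1 / dispersion
  lam <- stats::qgamma((seq_len(grid) - 0.5) / grid, shape = shape,
                       rate = shape)
  f <- function(lo) mean(exp(lo) * lam / (1 + exp(lo) * lam)) - p
  lo <- stats::uniroot(f, c(log(p / (1 - p)) - 20, log(p / (1 - p)) + 20),
                       tol = 1e-10)$root
  exp(lo)
}

#' Generate a synthetic monitoring dataset
#'
#' Draws one survey: per-province sample rosters, a latent contamination
#' propensity per sample, Bernoulli detections per (sample, analyte) at the
#' calibrated odds, and truncated log-normal concentrations for the
#' detections. Fully reproducible given `seed`.
#'
#' @param specs list of [occurrence_spec()] objects (one per analyte).
#' @param province_sizes named integer vector of samples per province.
#' @param cooc a [cooccurrence_model()].
#' @param seed integer seed for the dataset's generator stream.
#' @return a `monitoring_dataset` whose panel is the spec analytes.
#' @export
generate_dataset <- function(specs, province_sizes,
                             cooc = cooccurrence_model(0), seed) {
  if (length(specs) == 0) stop("empty spec list", call. = FALSE)
  if (inherits(specs, "occurrence_spec")) specs <- list(specs)
  if (any(province_sizes <= 0)) {
    stop("province sizes must be positive", call. = FALSE)
  }
  if (is.null(names(province_sizes))) {
    names(province_sizes) <- paste0("P", seq_along(province_sizes))
  }
  n <- sum(province_sizes)
  set.seed(as.integer(seed))
  samples <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    province = rep(names(province_sizes), times = province_sizes))
  lambda <- if (cooc$dispersion == 0) rep(1, n) else
    stats::rgamma(n, shape = 1 / cooc$dispersion, rate = 1 / cooc$dispersion)
  det_list <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    o0 <- calibrate_odds(sp$p_detect, cooc$dispersion)
    mult <- rep(1, n)
    if (!is.null(sp$province_multipliers)) {
      m <- sp$province_multipliers[samples$province]
      mult <- ifelse(is.na(m), 1, m)
    }
    odds <- o0 * lambda * mult
    p_s <- ifelse(is.infinite(odds), 1, odds / (1 + odds))
    hit <- stats::runif(n) < p_s
    conc <- r_trunc_lnorm(sum(hit), sp$meanlog, sp$sdlog, sp$cmin, sp$cmax)
    det_list[[k]] <- tibble::tibble(
      sample_id = samples$sample_id[hit],
      analyte = sp$analyte,
      concentration_mg_kg = conc)
  }
  detections <- dplyr::bind_rows(det_list)
  monitoring_dataset(samples, detections,
                     panel = vapply(specs, `[[`, "", "analyte"))
}

#' Estimate occurrence parameters from a monitoring dataset
#'
#' Companion to [generate_dataset()] for parameter-recovery checks: the
#' empirical detection frequency and the moments of the detected (quantified)
#' concentrations.
#'
#' @param dataset a `monitoring_dataset`.
#' @param analyte analyte name.
#' @return list with `p_detect`, `n_detect`, `mean_conc`, `meanlog`, `sdlog`.
#' @export
fit_occurrence <- function(dataset, analyte) {
  x <- dataset$detections$concentration_mg_kg[
    dataset$detections$analyte == analyte]
  n <- nrow(dataset$samples)
  list(p_detect = length(x) / n,
       n_detect = length(x),
       mean_conc = if (length(x) > 0) mean(x) else NA_real_,
       meanlog = if (length(x) > 0) mean(log(x)) else NA_real_,
       sdlog = if (length(x) > 1) stats::sd(log(x)) else NA_real_)
}
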