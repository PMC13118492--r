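#' Validate a pesticide reference table
#'
#' A reference table carries the per-analyte regulatory and toxicological
#' constants every downstream stage needs: the maximum residue level (MRL,
#' mg/kg), the acceptable daily intake (ADI, mg/kg bw/day), the optional
#' acute reference dose (ARfD, mg/kg bw), the limit of quantification (LOQ,
#' mg/kg), a pesticide class and an authorisation flag.
#'
#' An ADI may be missing (`NA`) for compounds without an established value;
#' such compounds are excluded from risk ranking and exposure stages with a
#' warning rather than rejected at the door.
#'
#' @param df data frame with columns `analyte`, `class`, `authorised`,
#'   `mrl_mg_kg`, `adi_mg_kg_bw_day`, `arfd_mg_kg_bw`, `loq_mg_kg`.
#' @return a validated tibble of class `pesticide_ref`.
#' @export
as_pesticide_ref <- function(df) {
  required <- c("analyte", "class", "authorised", "mrl_mg_kg",
                "adi_mg_kg_bw_day", "arfd_mg_kg_bw", "loq_mg_kg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[required]
  df$analyte <- as.character(df$analyte)
  df$class <- as.character(df$class)
  df$authorised <- as.logical(df$authorised)
  for (col in c("mrl_mg_kg", "adi_mg_kg_bw_day", "arfd_mg_kg_bw", "loq_mg_kg")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (anyDuplicated(df$analyte)) {
    stop("duplicate analyte name(s) in reference table: ",
         paste(unique(df$analyte[duplicated(df$analyte)]), collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(df$class), c("fungicide", "insecticide", "acaricide"))
  if (length(bad_class) > 0) {
    stop("unknown pesticide class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$mrl_mg_kg) | df$mrl_mg_kg <= 0)) {
    stop("mrl_mg_kg must be positive for every analyte", call. = FALSE)
  }
  if (any(!is.na(df$adi_mg_kg_bw_day) & df$adi_mg_kg_bw_day <= 0)) {
    stop("adi_mg_kg_bw_day must be positive when present", call. = FALSE)
  }
  if (any(!is.na(df$arfd_mg_kg_bw) & df$arfd_mg_kg_bw <= 0)) {
    stop("arfd_mg_kg_bw must be positive when present", call. = FALSE)
  }
  if (any(is.na(df$loq_mg_kg) | df$loq_mg_kg <= 0)) {
    stop("loq_mg_kg must be positive for every analyte", call. = FALSE)
  }
  if (any(is.na(df$authorised))) {
    stop("authorised must be TRUE or FALSE for every analyte", call. = FALSE)
  }
  class(df) <- c("pesticide_ref", class(df))
  df
}

#' Read a pesticide reference table from CSV
#'
#' @param path CSV with the columns listed in [as_pesticide_ref()]; a blank
#'   `arfd_mg_kg_bw` or `adi_mg_kg_bw_day` cell is read as missing.
#' @return a `pesticide_ref` tibble.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  as_pesticide_ref(df)
}

ref_lookup <- function(refs, analyte, field) {
  i <- match(analyte, refs$analyte)
  if (any(is.na(i))) {
    stop("analyte(s) not in reference table: ",
         paste(analyte[is.na(i)], collapse = ", "), call. = FALSE)
  }
  refs[[field]][i]
}

#' Construct a monitoring dataset
#'
#' A monitoring dataset pairs a sample roster (one row per sample, with its
#' region label) with a sparse long table of quantified detections. Any
#' (sample, analyte-in-panel) pair without a detection row is a non-detect:
#' the long format stays sparse even for panels of hundreds of analytes.
#'
#' @param samples data frame with columns `sample_id`, `province`.
#' @param detections data frame with columns `sample_id`, `analyte`,
#'   `concentration_mg_kg`; only quantified residues appear here.
#' @param panel character vector of analytes sought; defaults to the analytes
#'   present in `detections`.
#' @return an object of class `monitoring_dataset`.
#' @export
monitoring_dataset <- function(samples, detections, panel = NULL) {
  samples <- tibble::as_tibble(samples)[c("sample_id", "province")]
  samples$sample_id <- as.character(samples$sample_id)
  samples$province <- as.character(samples$province)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) == 0) stop("dataset has no samples", call. = FALSE)
  detections <- tibble::as_tibble(detections)[c("sample_id", "analyte",
                                               "concentration_mg_kg")]
  detections$sample_id <- as.character(detections$sample_id)
  detections$analyte <- as.character(detections$analyte)
  detections$concentration_mg_kg <- as.numeric(detections$concentration_mg_kg)
  unknown <- setdiff(detections$sample_id, samples$sample_id)
  if (length(unknown) > 0) {
    stop("detections reference unknown sample_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(detections$concentration_mg_kg) |
          detections$concentration_mg_kg <= 0)) {
    stop("detected concentrations must be positive numbers", call. = FALSE)
  }
  key <- paste(detections$sample_id, detections$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, analyte) detection row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (is.null(panel)) panel <- sort(unique(detections$analyte))
  off_panel <- setdiff(detections$analyte, panel)
  if (length(off_panel) > 0) {
    stop("detections for analyte(s) outside the panel: ",
         paste(off_panel, collapse = ", "), call. = FALSE)
  }
  structure(
    list(samples = samples, detections = detections,
         panel = as.character(panel)),
    class = "monitoring_dataset")
}

#' @export
print.monitoring_dataset <- function(x, ...) {
  prov <- table(x$samples$province)
  cat("<monitoring_dataset> ", nrow(x$samples), " samples, ",
      nrow(x$detections), " detections, panel of ", length(x$panel),
      " analytes\n", sep = "")
  cat("provinces: ",
      paste0(names(prov), " (", as.integer(prov), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of samples in a monitoring dataset
#' @param dataset a `monitoring_dataset`.
#' @export
n_samples <- function(dataset) nrow(dataset$samples)

#' Read a long-format monitoring table from CSV
#'
#' Expected columns: `sample_id`, `province`, `analyte`,
#' `concentration_mg_kg`. A row with an empty `analyte` declares a
#' residue-free sample (so that samples without any detection still enter the
#' roster); its concentration cell must be empty.
#'
#' When a reference table is supplied, analytes are checked against it and
#' concentrations below the analyte's LOQ are rejected: a monitoring table
#' reports quantified residues only.
#'
#' @param path CSV file path.
#' @param refs optional `pesticide_ref`; enables analyte and LOQ validation.
#' @param panel optional analyte panel; defaults to `refs$analyte` when refs
#'   are given, otherwise to the analytes observed.
#' @return a `monitoring_dataset`.
#' @export
read_monitoring_table <- function(path, refs = NULL, panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "NA", fileEncoding = "UTF-8",
                        colClasses = c(sample_id = "character"))
  required <- c("sample_id", "province", "analyte", "concentration_mg_kg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("monitoring table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$analyte <- as.character(df$analyte)
  df$analyte[is.na(df$analyte)] <- ""
  blank <- df$analyte == ""
  conc <- suppressWarnings(as.numeric(df$concentration_mg_kg))
  if (any(!blank & (is.na(conc) | conc <= 0))) {
    bad <- df$sample_id[!blank & (is.na(conc) | conc <= 0)]
    stop("non-positive or non-numeric concentration for sample(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  samples <- unique(tibble::tibble(sample_id = as.character(df$sample_id),
                                   province = as.character(df$province)))
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id(s) listed with conflicting provinces: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  detections <- tibble::tibble(
    sample_id = as.character(df$sample_id[!blank]),
    analyte = df$analyte[!blank],
    concentration_mg_kg = conc[!blank])
  if (!is.null(refs)) {
    if (is.null(panel)) panel <- refs$analyte
    unknown <- setdiff(detections$analyte, refs$analyte)
    if (length(unknown) > 0) {
      stop("analyte(s) not in reference table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    loq <- ref_lookup(refs, detections$analyte, "loq_mg_kg")
    below <- detections$concentration_mg_kg < loq
    if (any(below)) {
      stop("concentration(s) below the analyte LOQ (quantified residues ",
           "only): ", paste(unique(detections$analyte[below]), collapse = ", "),
           call. = FALSE)
    }
  }
  monitoring_dataset(samples, detections, panel = panel)
}

#' Write a monitoring dataset to canonical long CSV
#'
#' One row per detection plus one blank-analyte row for each residue-free
#' sample, sorted by sample id then analyte, so that write/read round-trips
#' are byte-identical on canonicalised files.
#'
#' @param dataset a `monitoring_dataset`.
#' @param path output CSV path.
#' @export
write_monitoring_table <- function(dataset, path) {
  det <- dataset$detections
  prov <- stats::setNames(dataset$samples$province, dataset$samples$sample_id)
  free <- setdiff(dataset$samples$sample_id, det$sample_id)
  out <- rbind(
    data.frame(sample_id = det$sample_id,
               province = unname(prov[det$sample_id]),
               analyte = det$analyte,
               concentration_mg_kg = det$concentration_mg_kg,
               stringsAsFactors = FALSE),
    data.frame(sample_id = free, province = unname(prov[free]),
               analyte = "", concentration_mg_kg = NA_real_,
               stringsAsFactors = FALSE))
  out <- out[order(out$sample_id, out$analyte), ]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Substitution value for a left-censored (non-detect) result
#'
#' Non-detects are replaced following the lower/middle/upper-bound convention
#' for left-censored concentration data: 0 (LB), LOQ/2 (MB) or LOQ (UB).
#'
#' @param policy one of `"LB"`, `"MB"`, `"UB"`.
#' @param loq analyte limit of quantification (mg/kg).
#' @return the substitution concentration (mg/kg).
#' @export
censoring_value <- function(policy, loq) {
  policy <- match.arg(policy, c("LB", "MB", "UB"))
  switch(policy, LB = 0 * loq, MB = loq / 2, UB = loq)
}

#' Per-sample concentration vector under a censoring policy
#'
#' Detected values pass through unchanged; non-detects take the policy's
#' substitution value for the analyte's LOQ. The vector is ordered and named
#' by the dataset's sample roster.
#'
#' @param dataset a `monitoring_dataset`.
#' @param analyte analyte name (must be on the panel and in `refs`).
#' @param policy censoring policy, `"LB"`, `"MB"` or `"UB"`.
#' @param refs a `pesticide_ref` supplying the LOQ.
#' @return named numeric vector, length `n_samples(dataset)`.
#' @export
substitute_censored <- function(dataset, analyte, policy, refs) {
  if (!analyte %in% dataset$panel) {
    stop("analyte not on the panel: ", analyte, call. = FALSE)
  }
  loq <- ref_lookup(refs, analyte, "loq_mg_kg")
  sub <- censoring_value(policy, loq)
  out <- stats::setNames(rep(sub, nrow(dataset$samples)),
                         dataset$samples$sample_id)
  det <- dataset$detections[dataset$detections$analyte == analyte, ]
  out[det$sample_id] <- det$concentration_mg_kg
  out
}

#' Mean residue concentration under a censoring policy
#'
#' Arithmetic mean of the substituted concentration vector; this is the
#' "residue concentration" input of the chronic intake calculation.
#'
#' @inheritParams substitute_censored
#' @return mean concentration (mg/kg).
#' @export
mean_concentration <- function(dataset, analyte, policy, refs) {
  if (nrow(dataset$samples) < 1) stop("empty dataset", call. = FALSE)
  mean(substitute_censored(dataset, analyte, policy, refs))
}
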