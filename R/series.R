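#' Time point record
#'
#' One follow-up of one patient: days from first resection (the clock origin
#' of all time-to-progression computations), a reference to its segmentation
#' mask, the aggregate burden measurements and optional expert annotations.
#'
#' @param days_from_surgery Integer days since first resection (>= 0).
#' @param mask_ref Path to the mask file, or an in-memory [seg_mask].
#' @param measurements Named numeric vector of non-negative aggregate burden
#'   values, conventionally `spd2d`, `spd25d` (mm^2) and `volume` (mm^3).
#' @param lesion_count_measurable,lesion_count_nonmeasurable Lesion counts.
#' @param expert_spd Optional expert SPD in mm^2.
#' @param expert_is_nadir Optional flag: expert designated this time point as
#'   the nadir/baseline reference.
#' @param expert_rating Optional categorical rating: "PD", "SD", "PR" or "CR".
#' @return An object of class `timepoint_record`.
#' @export
timepoint_record <- function(days_from_surgery, mask_ref = NULL,
                             measurements = numeric(0),
                             lesion_count_measurable = NA_integer_,
                             lesion_count_nonmeasurable = NA_integer_,
                             expert_spd = NA_real_, expert_is_nadir = NA,
                             expert_rating = NA_character_) {
  days_from_surgery <- as.integer(days_from_surgery)
  if (is.na(days_from_surgery) || days_from_surgery < 0L)
    stop("days_from_surgery must be a non-negative integer")
  measurements <- unlist(measurements)
  if (length(measurements) && (is.null(names(measurements)) ||
      any(!nzchar(names(measurements)))))
    stop("measurements must be named")
  if (any(measurements < 0, na.rm = TRUE))
    stop("measurements must be non-negative")
  if (!is.na(expert_rating) &&
      !expert_rating %in% c("PD", "SD", "PR", "CR"))
    stop("expert_rating must be one of PD, SD, PR, CR")
  structure(list(days_from_surgery = days_from_surgery, mask_ref = mask_ref,
                 measurements = measurements,
                 lesion_count_measurable = as.integer(lesion_count_measurable),
                 lesion_count_nonmeasurable = as.integer(lesion_count_nonmeasurable),
                 expert_spd = as.numeric(expert_spd),
                 expert_is_nadir = expert_is_nadir,
                 expert_rating = expert_rating),
            class = "timepoint_record")
}

#' Longitudinal patient series
#'
#' The unit of time-to-progression computation: an ordered list of time
#' points plus overall survival, both in days from first resection.
#'
#' @param patient_id Patient identifier.
#' @param timepoints List of [timepoint_record]s; sorted by day on creation.
#' @param os_days Overall survival in days (> 0, and at least the last
#'   time point's day).
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, timepoints, os_days) {
  stopifnot(length(timepoints) >= 1L)
  days <- vapply(timepoints, function(tp) tp$days_from_surgery, integer(1))
  if (anyDuplicated(days))
    stop("duplicate days_from_surgery in series for patient ", patient_id)
  timepoints <- timepoints[order(days)]
  days <- sort(days)
  os_days <- as.integer(os_days)
  if (is.na(os_days) || os_days <= 0L)
    stop("os_days must be a positive integer")
  if (os_days < days[length(days)])
    stop("os_days earlier than the last time point for patient ", patient_id)
  structure(list(patient_id = as.character(patient_id),
                 timepoints = timepoints, os_days = os_days),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  days <- vapply(x$timepoints, function(tp) tp$days_from_surgery, integer(1))
  cat(sprintf("<patient_series> %s: %d time points (days %s), OS %d days\n",
              x$patient_id, length(days), paste(days, collapse = ", "),
              x$os_days))
  invisible(x)
}

#' @export
length.patient_series <- function(x) length(x$timepoints)

# metric trace of a series as a numeric vector (NA where absent)
series_metric <- function(series, metric) {
  vapply(series$timepoints,
         function(tp) unname(tp$measurements[metric])[1] %||% NA_real_,
         numeric(1))
}

series_days <- function(series)
  vapply(series$timepoints, function(tp) tp$days_from_surgery, integer(1))

#' Load a longitudinal cohort from a CSV manifest
#'
#' The manifest requires columns `patient_id`, `days_from_surgery`,
#' `mask_file` and `os_days`; columns `expert_spd`, `expert_is_nadir` and
#' `expert_rating` are optional.  Row-level validation problems (duplicate
#' patient/day, inconsistent OS within a patient, missing mask file) are
#' aggregated and reported together.
#'
#' @param manifest Path to the CSV manifest (header row required), or a
#'   data.frame with the same columns.
#' @param mask_dir Directory that `mask_file` entries are relative to
#'   (default: the manifest's directory).
#' @param check_masks Verify that mask files exist (default `TRUE`).
#' @return A named list of [patient_series], ordered by patient id.
#' @export
load_series <- function(manifest, mask_dir = NULL, check_masks = TRUE) {
  if (is.character(manifest)) {
    if (is.null(mask_dir)) mask_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  mask_dir <- mask_dir %||% "."
  need <- c("patient_id", "days_from_surgery", "mask_file", "os_days")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  errs <- character(0)
  key <- paste(manifest$patient_id, manifest$days_from_surgery)
  dup <- which(duplicated(key))
  for (i in dup)
    errs <- c(errs, sprintf("row %d: duplicate (patient, day) = (%s, %s)",
                            i, manifest$patient_id[i], manifest$days_from_surgery[i]))
  for (pid in unique(manifest$patient_id)) {
    os <- unique(manifest$os_days[manifest$patient_id == pid])
    if (length(os) > 1L)
      errs <- c(errs, sprintf("patient %s: inconsistent os_days (%s)",
                              pid, paste(os, collapse = ", ")))
  }
  paths <- file.path(mask_dir, manifest$mask_file)
  if (isTRUE(check_masks)) {
    bad <- which(!file.exists(paths))
    for (i in bad) errs <- c(errs, sprintf("row %d: mask file not found: %s", i, paths[i]))
  }
  if (length(errs))
    stop("manifest validation failed:\n  ", paste(errs, collapse = "\n  "))
  out <- lapply(sort(unique(manifest$patient_id)), function(pid) {
    rows <- manifest[manifest$patient_id == pid, , drop = FALSE]
    rows <- rows[order(rows$days_from_surgery), , drop = FALSE]
    tps <- lapply(seq_len(nrow(rows)), function(i) {
      timepoint_record(
        days_from_surgery = rows$days_from_surgery[i],
        mask_ref = file.path(mask_dir, rows$mask_file[i]),
        expert_spd = if ("expert_spd" %in% names(rows))
          rows$expert_spd[i] else NA_real_,
        expert_is_nadir = if ("expert_is_nadir" %in% names(rows))
          as.logical(rows$expert_is_nadir[i]) else NA,
        expert_rating = if ("expert_rating" %in% names(rows) &&
                            !is.na(rows$expert_rating[i]) &&
                            nzchar(rows$expert_rating[i]))
          rows$expert_rating[i] else NA_character_)
    })
    patient_series(pid, tps, os_days = rows$os_days[1])
  })
  names(out) <- sort(unique(manifest$patient_id))
  out
}
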