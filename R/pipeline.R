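#' Measure every lesion of a mask
#'
#' Runs the full measurement stack on one segmentation mask: lesion
#' separation, bidimensional axial measurement, 2.5D measurement,
#' volumetry and sphericity, plus the measurability flag.
#'
#' @param mask A binary [seg_mask].
#' @param cfg A [run_config] (geometry and RANO parameters).
#' @return List with `lesions` -- one row per lesion: `lesion_id`,
#'   `n_voxels`, `volume_mm3`, `sphericity`, `d1_2d`, `d2_2d`,
#'   `product_2d`, `slice_index`, `d1_25d`, `d2_25d`, `product_25d`,
#'   direction cosines `dir_x/dir_y/dir_z` of the free diameter, and
#'   `measurable` -- and `summary`, the per-time-point aggregates from
#'   [aggregate_timepoint()].
#' @export
measure_mask <- function(mask, cfg = run_config()) {
  lesions <- extract_lesions(mask)
  rows <- lapply(lesions, function(les) {
    m2 <- measure_lesion_2d(les, step_mm = cfg$step_mm,
                            contain_step = cfg$contain_step,
                            tol_deg = cfg$tol_deg)
    m25 <- measure_lesion_25d(les, plane_step_mm = cfg$plane_step_mm,
                              contain_step = cfg$contain_step)
    data.frame(
      lesion_id = les$lesion_id,
      n_voxels = les$n_voxels,
      volume_mm3 = lesion_volume(les)$volume_mm3,
      sphericity = sphericity(les),
      d1_2d = m2$longest$length_mm,
      d2_2d = if (is.null(m2$perpendicular)) NA_real_
              else m2$perpendicular$length_mm,
      product_2d = m2$product_mm2,
      slice_index = m2$longest$slice_index,
      d1_25d = m25$longest$length_mm,
      d2_25d = if (is.null(m25$perpendicular)) NA_real_
               else m25$perpendicular$length_mm,
      product_25d = m25$product_mm2,
      dir_x = attr(m25$longest, "direction")[1],
      dir_y = attr(m25$longest, "direction")[2],
      dir_z = attr(m25$longest, "direction")[3],
      measurable = is_measurable(m2, cfg$rano))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion_id = integer(0), n_voxels = integer(0),
               volume_mm3 = numeric(0), sphericity = numeric(0),
               d1_2d = numeric(0), d2_2d = numeric(0),
               product_2d = numeric(0), slice_index = integer(0),
               d1_25d = numeric(0), d2_25d = numeric(0),
               product_25d = numeric(0), dir_x = numeric(0),
               dir_y = numeric(0), dir_z = numeric(0),
               measurable = logical(0))
  list(lesions = df, summary = aggregate_timepoint(df, cfg$rano))
}

#' Aggregate per-lesion measurements into a time-point record
#'
#' SPDs and volume are reported both unfiltered (all lesions, the
#' recommended default for automated segmentations) and filtered
#' (measurability rule plus the five-target cap), alongside measurable /
#' non-measurable counts and the non-measurable burden fractions.
#'
#' @param lesions Per-lesion measurement data.frame from [measure_mask()].
#' @param cfg A [rano_config].
#' @return A one-row data.frame of aggregates.
#' @export
aggregate_timepoint <- function(lesions, cfg = rano_config()) {
  filt <- rano_config(measurability_mm = cfg$measurability_mm,
                      max_target_lesions = cfg$max_target_lesions,
                      threshold_2d = cfg$threshold_2d,
                      threshold_volume = cfg$threshold_volume,
                      apply_measurability = TRUE, apply_target_limit = TRUE)
  nm <- count_nonmeasurable(lesions, cfg)
  data.frame(
    spd2d = aggregate_spd(lesions, "product_2d"),
    spd25d = aggregate_spd(lesions, "product_25d"),
    volume = sum(lesions$volume_mm3),
    spd2d_filtered = aggregate_spd(select_targets(lesions, filt, "spd2d"),
                                   "product_2d"),
    spd25d_filtered = aggregate_spd(select_targets(lesions, filt, "spd25d"),
                                    "product_25d"),
    volume_filtered = sum(select_targets(lesions, filt,
                                         "volume")$volume_mm3),
    n_lesions = nrow(lesions),
    n_measurable = nm$n_measurable,
    n_nonmeasurable = nm$n_nonmeasurable,
    frac_spd2d_nonmeasurable = nm$frac_spd2d_nonmeasurable,
    frac_volume_nonmeasurable = nm$frac_volume_nonmeasurable)
}

resolve_mask <- function(ref, cfg) {
  mask <- if (inherits(ref, "seg_mask")) ref
          else load_mask(ref, label_map = cfg$label_map,
                         axial_axis = cfg$axial_axis)
  if (cfg$resample) mask <- resample_iso(mask, cfg$target_mm)
  mask
}

#' Measure a set of masks or a manifest cohort (CSV in, CSV out)
#'
#' Orchestrates the measurement pipeline and writes `lesions.csv` (one row
#' per lesion per mask) and `timepoints.csv` (one aggregate row per mask).
#' The configuration in force is serialised next to the outputs for
#' provenance.
#'
#' @param masks Character vector of mask paths, or a manifest (path or
#'   data.frame, see [load_series()]); in-memory [seg_mask]s also work.
#' @param cfg A [run_config].
#' @param out_dir Output directory (created if absent); `NULL` to skip
#'   writing.
#' @param mask_dir Mask root when `masks` is a manifest path.
#' @return Invisibly, list with `lesions` and `timepoints` data.frames.
#' @export
cmd_measure <- function(masks, cfg = run_config(), out_dir = NULL,
                        mask_dir = NULL) {
  meta <- NULL
  if (is.data.frame(masks) ||
      (is.character(masks) && length(masks) == 1L &&
       grepl("\\.csv$", masks, ignore.case = TRUE))) {
    cohort <- load_series(masks, mask_dir = mask_dir)
    meta <- do.call(rbind, lapply(cohort, function(s)
      data.frame(patient_id = s$patient_id, days = series_days(s),
                 mask = vapply(s$timepoints, function(tp)
                   as.character(tp$mask_ref), character(1)))))
    refs <- as.list(meta$mask)
  } else if (inherits(masks, "seg_mask")) {
    refs <- list(masks)
  } else {
    refs <- as.list(masks)
  }
  les_all <- list()
  tp_all <- list()
  for (i in seq_along(refs)) {
    res <- measure_mask(resolve_mask(refs[[i]], cfg), cfg)
    id <- if (!is.null(meta))
      data.frame(patient_id = meta$patient_id[i], days = meta$days[i])
    else
      data.frame(patient_id = NA_character_, days = NA_integer_)
    id$mask <- if (is.character(refs[[i]])) refs[[i]] else
      sprintf("<in-memory %d>", i)
    les_all[[i]] <- if (nrow(res$lesions)) cbind(id, res$lesions) else
      cbind(id[0, , drop = FALSE], res$lesions)
    tp_all[[i]] <- cbind(id, res$summary)
  }
  out <- list(lesions = do.call(rbind, les_all),
              timepoints = do.call(rbind, tp_all))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$lesions, file.path(out_dir, "lesions.csv"),
              row.names = FALSE)
    write.csv(out$timepoints, file.path(out_dir, "timepoints.csv"),
              row.names = FALSE)
    write_run_config(cfg, file.path(out_dir, "config.yaml"))
  }
  invisible(out)
}

# attach measured metric traces from a timepoints table to manifest series
series_with_measurements <- function(timepoints, manifest,
                                     mask_dir = NULL) {
  cohort <- load_series(manifest, mask_dir = mask_dir, check_masks = FALSE)
  lapply(cohort, function(s) {
    days <- series_days(s)
    rows <- timepoints[timepoints$patient_id == s$patient_id, , drop = FALSE]
    for (i in seq_along(s$timepoints)) {
      r <- rows[rows$days == days[i], , drop = FALSE]
      if (nrow(r) != 1L)
        stop("no measurement row for patient ", s$patient_id, " day ",
             days[i])
      s$timepoints[[i]]$measurements <- c(spd2d = r$spd2d,
                                          spd25d = r$spd25d,
                                          volume = r$volume)
    }
    s
  })
}

#' Assess a measured cohort: TTP, threshold sweep, TTP-OS correlation
#'
#' Joins a per-time-point measurement table with the series manifest and
#' computes, per patient x metric x threshold, the nadir-referenced TTP
#' (and its difference to the expert TTP when expert ratings exist), plus
#' the cohort threshold-sweep table and the TTP-OS rank correlation per
#' metric and threshold.
#'
#' @param timepoints Measurement table (data.frame or `timepoints.csv`
#'   path) from [cmd_measure()].
#' @param manifest Series manifest (path or data.frame).
#' @param cfg A [run_config]; `cfg$metrics` and `cfg$thresholds` define the
#'   grid.
#' @param out_dir Output directory for `ttp.csv`, `sweep.csv` and
#'   `ttp_os.csv`; `NULL` to skip writing.
#' @param mask_dir Mask root for manifest paths.
#' @return Invisibly, list with `ttp`, `sweep` and `ttp_os` data.frames.
#' @export
cmd_assess <- function(timepoints, manifest, cfg = run_config(),
                       out_dir = NULL, mask_dir = NULL) {
  if (is.character(timepoints)) timepoints <- read.csv(timepoints)
  cohort <- series_with_measurements(timepoints, manifest, mask_dir)
  have_expert <- any(vapply(cohort, function(s)
    any(vapply(s$timepoints, function(tp) !is.na(tp$expert_rating),
               logical(1))), logical(1)))
  grid <- expand.grid(metric = cfg$metrics, threshold = cfg$thresholds,
                      stringsAsFactors = FALSE)
  ttp <- do.call(rbind, lapply(cohort, function(s) {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
      r <- compute_ttp(s, grid$metric[g], threshold = grid$threshold[g])
      row <- data.frame(patient_id = s$patient_id, metric = grid$metric[g],
                        threshold = grid$threshold[g],
                        ttp_days = r$ttp_days, progressed = r$progressed,
                        os_days = s$os_days)
      if (have_expert) {
        row$expert_ttp_days <- expert_ttp(s)
        row$diff_days <- row$ttp_days - row$expert_ttp_days
      }
      row
    }))
  }))
  sweep_tab <- if (have_expert)
    do.call(rbind, lapply(cfg$metrics, function(m)
      cbind(metric = m, threshold_sweep(cohort, m,
                                        thresholds = cfg$thresholds))))
  else NULL
  ttp_os <- if (length(cohort) >= 3L)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
      ct <- tryCatch(ttp_os_correlation(cohort, grid$metric[g],
                                        grid$threshold[g]),
                     error = function(e) list(rho = NA_real_,
                                              p_value = NA_real_))
      data.frame(metric = grid$metric[g], threshold = grid$threshold[g],
                 rho = ct$rho, p_value = ct$p_value, n = length(cohort))
    }))
  else NULL
  out <- list(ttp = ttp, sweep = sweep_tab, ttp_os = ttp_os)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ttp, file.path(out_dir, "ttp.csv"), row.names = FALSE)
    if (!is.null(sweep_tab))
      write.csv(sweep_tab, file.path(out_dir, "sweep.csv"),
                row.names = FALSE)
    if (!is.null(ttp_os))
      write.csv(ttp_os, file.path(out_dir, "ttp_os.csv"), row.names = FALSE)
  }
  invisible(out)
}

#' Pairwise trend agreement and rank correlation between methods
#'
#' Builds the method x method trend-agreement and Spearman correlation
#' matrices, pooling transitions over all patients.  Methods are aligned on
#' (patient, day) keys and every method must cover the same time points.
#'
#' @param measurements Named list: method name -> per-time-point table
#'   (data.frame or CSV path) with columns `patient_id`, `days` and the
#'   metric column.
#' @param metric Column compared across methods (default `"volume"`; an
#'   expert SPD table would use its own column name).
#' @param out_dir Output directory for `agreement.csv` / `spearman.csv`;
#'   `NULL` to skip writing.
#' @return Invisibly, list with matrices `agreement` (percent) and `rho`.
#' @export
cmd_agree <- function(measurements, metric = "volume", out_dir = NULL) {
  stopifnot(length(measurements) >= 2L, !is.null(names(measurements)))
  tabs <- lapply(measurements, function(m)
    if (is.character(m)) read.csv(m) else m)
  keyed <- lapply(tabs, function(t) {
    t <- t[order(t$patient_id, t$days), , drop = FALSE]
    key <- paste(t$patient_id, t$days)
    setNames(t[[metric]], key)
  })
  keys <- names(keyed[[1]])
  for (k in keyed)
    if (!identical(names(k), keys))
      stop("methods are not aligned on the same (patient, day) keys")
  pids <- sub(" [^ ]+$", "", keys)
  split_series <- function(v) split(unname(v), pids)
  n <- length(keyed)
  agree <- rho <- matrix(NA_real_, n, n,
                         dimnames = list(names(keyed), names(keyed)))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      agree[i, j] <- trend_agreement(split_series(keyed[[i]]),
                                     split_series(keyed[[j]]))
      rho[i, j] <- spearman_rho(keyed[[i]], keyed[[j]])
    }
  out <- list(agreement = agree, rho = rho)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(agree, file.path(out_dir, "agreement.csv"))
    write.csv(rho, file.path(out_dir, "spearman.csv"))
  }
  invisible(out)
}
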