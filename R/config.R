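#' Run configuration
#'
#' One object holding everything a pipeline run needs: label semantics,
#' resampling, RANO filter settings, the metrics and threshold grid of the
#' assessment step.  Serialisable to YAML/JSON so a run can be reproduced
#' from its dumped configuration.
#'
#' @param label_map Named character vector mapping label values to classes;
#'   labels mapped to `"enhancing"` form the working mask.
#' @param resample Resample masks to isotropic voxels on load (default
#'   `TRUE`, the standard 1 mm preprocessing convention).
#' @param target_mm Isotropic target spacing in mm.
#' @param axial_axis Optional axial-axis override (default: from the image
#'   orientation).
#' @param rano A [rano_config].
#' @param metrics Metrics the assessment step runs on.
#' @param thresholds Progression threshold grid for sweeps.
#' @param step_mm,contain_step,tol_deg,plane_step_mm Geometry parameters,
#'   see [measure_lesion_2d()] and [measure_lesion_25d()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(label_map = c("1" = "enhancing"), resample = TRUE,
                       target_mm = 1, axial_axis = NULL,
                       rano = rano_config(),
                       metrics = c("spd2d", "spd25d", "volume"),
                       thresholds = c(0.25, 0.40), step_mm = 0.1,
                       contain_step = 0.2, tol_deg = 2,
                       plane_step_mm = 0.5) {
  structure(list(label_map = label_map, resample = isTRUE(resample),
                 target_mm = as.numeric(target_mm), axial_axis = axial_axis,
                 rano = rano, metrics = metrics,
                 thresholds = as.numeric(thresholds),
                 step_mm = step_mm, contain_step = contain_step,
                 tol_deg = tol_deg, plane_step_mm = plane_step_mm),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()] and [rano_config()] (the
#' latter nested under `rano`); absent keys keep their defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON: ", path))
  rano_args <- raw$rano %||% list()
  raw$rano <- NULL
  lm <- raw$label_map
  if (!is.null(lm)) raw$label_map <- unlist(lm)
  cfg <- do.call(run_config, c(raw, list(rano = do.call(rano_config,
                                                        rano_args))))
  cfg
}

#' Write a run configuration to YAML or JSON
#'
#' @param cfg A [run_config].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$rano <- unclass(x$rano)
  x$label_map <- as.list(x$label_map)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = NA, null = "null"),
         stop("config must be YAML or JSON: ", path))
  invisible(path)
}
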