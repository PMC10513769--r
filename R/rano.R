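#' RANO configuration
#'
#' Parameters of the RANO-style filtering and progression rules.  The
#' default configuration applies NO measurability or target-lesion filter:
#' the recommended default for automated segmentations is to consider all
#' detected lesions, with the classical filters available as opt-in flags.
#'
#' @param measurability_mm Measurability threshold in mm applied to both
#'   bidimensional diameters (default 10; the boundary is inclusive,
#'   following the RANO convention).
#' @param max_target_lesions Maximum number of target lesions (default 5).
#' @param threshold_2d Relative SPD increase over the nadir that counts as
#'   progression for bidimensional measurements (default 0.25, i.e. >= 25%).
#' @param threshold_volume Relative volume increase over the nadir that
#'   counts as progression for volumetry (default 0.40, i.e. >= 40%).
#' @param apply_measurability Drop non-measurable lesions before
#'   aggregation (default `FALSE`).
#' @param apply_target_limit Cap the number of target lesions (default
#'   `FALSE`).
#' @return An object of class `rano_config`.
#' @export
rano_config <- function(measurability_mm = 10, max_target_lesions = 5L,
                        threshold_2d = 0.25, threshold_volume = 0.40,
                        apply_measurability = FALSE,
                        apply_target_limit = FALSE) {
  stopifnot(measurability_mm > 0, threshold_2d > 0, threshold_volume > 0,
            max_target_lesions >= 1L)
  structure(list(measurability_mm = as.numeric(measurability_mm),
                 max_target_lesions = as.integer(max_target_lesions),
                 threshold_2d = as.numeric(threshold_2d),
                 threshold_volume = as.numeric(threshold_volume),
                 apply_measurability = isTRUE(apply_measurability),
                 apply_target_limit = isTRUE(apply_target_limit)),
            class = "rano_config")
}

#' @export
print.rano_config <- function(x, ...) {
  cat(sprintf(paste0("<rano_config> measurability >= %g mm (both diameters",
                     ", %s), <= %d target lesions (%s),\n",
                     "  progression >= %g%% (2D SPD) / >= %g%% (volume)\n"),
              x$measurability_mm,
              if (x$apply_measurability) "applied" else "off",
              x$max_target_lesions,
              if (x$apply_target_limit) "applied" else "off",
              100 * x$threshold_2d, 100 * x$threshold_volume))
  invisible(x)
}

# vectorised core rule: both diameters must reach the threshold
measurable_rule <- function(d1, d2, cfg) {
  !is.na(d1) & !is.na(d2) &
    d1 >= cfg$measurability_mm & d2 >= cfg$measurability_mm
}

#' Lesion measurability under the RANO rule
#'
#' A lesion is measurable iff its longest diameter and its perpendicular
#' diameter both reach the measurability threshold (inclusive); a lesion
#' without a perpendicular diameter is non-measurable.
#'
#' @param m A `bidim_measurement`, or a numeric longest diameter in mm (then
#'   supply `d2`).
#' @param cfg A [rano_config].
#' @param d2 Perpendicular diameter(s) in mm when `m` is numeric.
#' @return Logical.
#' @export
is_measurable <- function(m, cfg = rano_config(), d2 = NULL) {
  if (inherits(m, "bidim_measurement")) {
    d1 <- m$longest$length_mm
    d2 <- if (is.null(m$perpendicular)) NA_real_ else m$perpendicular$length_mm
    return(unname(measurable_rule(d1, d2, cfg)))
  }
  measurable_rule(as.numeric(m), as.numeric(d2), cfg)
}

#' Select target lesions
#'
#' Applies the configured filters to a per-lesion measurement table: keep
#' measurable lesions (when `apply_measurability`) and cap them at the
#' `max_target_lesions` largest by the per-lesion value of the aggregation
#' metric -- the 2D product for SPD aggregation, the volume for volume
#' totals (when `apply_target_limit`).  Ties are broken by lesion id, so
#' selection is deterministic.
#'
#' @param lesions A data.frame with columns `lesion_id`, `d1_2d`, `d2_2d`
#'   and the metric column (`product_2d`, `product_25d` or `volume_mm3`),
#'   as produced by [measure_mask()].
#' @param cfg A [rano_config].
#' @param metric Aggregation metric: `"spd2d"`, `"spd25d"` or `"volume"`.
#' @return The selected subset of `lesions` (possibly all rows).
#' @export
select_targets <- function(lesions, cfg = rano_config(),
                           metric = c("spd2d", "spd25d", "volume")) {
  metric <- match.arg(metric)
  if (!nrow(lesions)) return(lesions)
  sel <- lesions
  if (cfg$apply_measurability)
    sel <- sel[measurable_rule(sel$d1_2d, sel$d2_2d, cfg), , drop = FALSE]
  if (cfg$apply_target_limit && nrow(sel) > cfg$max_target_lesions) {
    key <- switch(metric, spd2d = sel$product_2d, spd25d = sel$product_25d,
                  volume = sel$volume_mm3)
    ord <- order(-key, sel$lesion_id)
    sel <- sel[ord[seq_len(cfg$max_target_lesions)], , drop = FALSE]
  }
  sel
}

#' Sum of products of perpendicular diameters
#'
#' @param products Numeric vector of per-lesion diameter products in mm^2
#'   (or a per-lesion measurement data.frame plus `metric`).
#' @param metric Column to aggregate when a data.frame is given.
#' @return The SPD (0 for an empty selection).
#' @export
aggregate_spd <- function(products, metric = "product_2d") {
  if (is.data.frame(products))
    products <- products[[metric]]
  if (!length(products)) return(0)
  sum(products, na.rm = TRUE)
}

#' Count non-measurable lesions and their burden share
#'
#' Counts lesions failing the measurability rule and reports which fraction
#' of the total burden (2D product and volume) they hold -- automated
#' segmentations tend to fragment recurrence along resection-cavity walls
#' into many small, individually non-measurable lesions, and this offset is
#' what the fractions expose.
#'
#' @param lesions Per-lesion measurement data.frame (see [measure_mask()]).
#' @param cfg A [rano_config].
#' @return List with `n_nonmeasurable`, `n_measurable`,
#'   `frac_spd2d_nonmeasurable` and `frac_volume_nonmeasurable` (NaN when
#'   the total burden is zero).
#' @export
count_nonmeasurable <- function(lesions, cfg = rano_config()) {
  if (!nrow(lesions))
    return(list(n_nonmeasurable = 0L, n_measurable = 0L,
                frac_spd2d_nonmeasurable = NaN,
                frac_volume_nonmeasurable = NaN))
  meas <- measurable_rule(lesions$d1_2d, lesions$d2_2d, cfg)
  list(n_nonmeasurable = sum(!meas),
       n_measurable = sum(meas),
       frac_spd2d_nonmeasurable =
         sum(lesions$product_2d[!meas]) / sum(lesions$product_2d),
       frac_volume_nonmeasurable =
         sum(lesions$volume_mm3[!meas]) / sum(lesions$volume_mm3))
}
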