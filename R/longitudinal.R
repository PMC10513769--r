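#' Classify the trend between two adjacent time points
#'
#' @param prev,curr Burden at the earlier / later time point (>= 0).
#' @param rel_eps Relative tolerance under which the pair counts as
#'   constant (default 1e-9, effectively exact equality: continuous burden
#'   measures rarely tie).
#' @return `"increasing"`, `"decreasing"` or `"constant"` (vectorised).
#' @export
classify_trend <- function(prev, curr, rel_eps = 1e-9) {
  stopifnot(length(prev) == length(curr))
  tol <- rel_eps * pmax(prev, curr, 1)
  ifelse(abs(curr - prev) <= tol, "constant",
         ifelse(curr > prev, "increasing", "decreasing"))
}

trend_labels <- function(x, rel_eps = 1e-9) {
  n <- length(x)
  if (n < 2L) return(character(0))
  classify_trend(x[-n], x[-1], rel_eps)
}

#' Longitudinal trend agreement between two measurement methods
#'
#' The percentage of adjacent-time-point trends (increasing / decreasing /
#' constant) on which two aligned series agree.  With lists of per-patient
#' series, all transitions are pooled before the percentage is computed, so
#' the result is a single cohort-level figure.
#'
#' @param series_a,series_b Numeric vectors of aligned measurements
#'   (length >= 2), or lists of such vectors (one per patient).
#' @param rel_eps Constant-trend tolerance, see [classify_trend()].
#' @return Agreement percentage in `[0, 100]`.
#' @export
trend_agreement <- function(series_a, series_b, rel_eps = 1e-9) {
  if (!is.list(series_a)) series_a <- list(series_a)
  if (!is.list(series_b)) series_b <- list(series_b)
  stopifnot(length(series_a) == length(series_b))
  match_n <- 0L
  total <- 0L
  for (i in seq_along(series_a)) {
    a <- series_a[[i]]
    b <- series_b[[i]]
    if (length(a) != length(b)) stop("series length mismatch at element ", i)
    if (length(a) < 2L) stop("series must have at least 2 time points")
    ta <- trend_labels(a, rel_eps)
    tb <- trend_labels(b, rel_eps)
    match_n <- match_n + sum(ta == tb)
    total <- total + length(ta)
  }
  100 * match_n / total
}

#' Spearman rank correlation
#'
#' Pearson correlation of fractional (average-tie) ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rank variance is zero; Spearman correlation undefined")
  cor(rx, ry)
}

#' Consistency intraclass correlation, ICC(3,1)
#'
#' Two-way, single-measurement consistency ICC:
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)` from the
#' two-way ANOVA without interaction, `k` the number of raters.  Response
#' assessment only evaluates relative change, so consistency (invariant to
#' a constant rater offset) is the appropriate variant: a tool with a
#' stable segmentation bias is not penalised.
#'
#' @param scores Numeric subjects x raters matrix (complete; >= 2 subjects,
#'   >= 2 raters).
#' @return The ICC.
#' @export
icc_consistency <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L)
    stop("need at least 2 subjects and 2 raters")
  if (anyNA(scores)) stop("scores table must be complete")
  k <- ncol(scores)
  d <- data.frame(score = as.vector(scores),
                  subject = factor(rep(seq_len(nrow(scores)), times = k)),
                  rater = factor(rep(seq_len(k), each = nrow(scores))))
  # a perfect fit (e.g. exactly offset raters) is legitimate here; the
  # F-test reliability warning does not concern the mean squares
  ms <- suppressWarnings(
    anova(lm(score ~ subject + rater, data = d))[, "Mean Sq"])
  msb <- ms[1]
  mse <- ms[3]
  unname((msb - mse) / (msb + (k - 1) * mse))
}

#' Nadir-referenced time-to-progression
#'
#' Scans the series in chronological order with a running reference: in
#' `auto` mode the reference at each time point is the minimum of the
#' metric over all earlier time points (nadir or baseline); in `expert`
#' mode it is the metric at the most recent expert-flagged nadir time
#' point, which guards the reference against under-segmented follow-ups.
#' Progression is called at the first time point whose metric is at least
#' `(1 + threshold)` times the reference; if the series never progresses,
#' the TTP is set to the overall survival time.  A reference of exactly 0
#' (complete disappearance) followed by any positive burden is called
#' progression and flagged, because the relative increase is undefined.
#'
#' @param series A [patient_series] whose time points carry the metric, or
#'   a numeric burden trace (then supply `days` and `os_days`).
#' @param metric `"volume"`, `"spd2d"` or `"spd25d"`.
#' @param threshold Relative progression threshold; defaults to the RANO
#'   value for the metric: 0.40 for volume, 0.25 for the bidimensional
#'   SPDs.
#' @param nadir_mode `"auto"`, `"expert"`, or the default `"auto_or_expert"`
#'   which uses expert nadir flags when the series has any and the running
#'   minimum otherwise.
#' @param days,os_days Used only when `series` is a bare numeric trace.
#' @return A `ttp_result`: `ttp_days`, `progressed`, `progression_index`,
#'   `nadir_trace` (the reference used at each time point), `metric`,
#'   `threshold` and `zero_nadir_call`.
#' @export
compute_ttp <- function(series, metric = c("volume", "spd2d", "spd25d"),
                        threshold = NULL,
                        nadir_mode = c("auto_or_expert", "auto", "expert"),
                        days = NULL, os_days = NULL) {
  metric <- match.arg(metric)
  nadir_mode <- match.arg(nadir_mode)
  if (is.null(threshold))
    threshold <- if (metric == "volume") 0.40 else 0.25
  stopifnot(threshold > 0)
  if (inherits(series, "patient_series")) {
    values <- series_metric(series, metric)
    days <- series_days(series)
    os_days <- series$os_days
    nadir_flags <- vapply(series$timepoints,
                          function(tp) isTRUE(tp$expert_is_nadir), logical(1))
  } else {
    values <- as.numeric(series)
    stopifnot(!is.null(days), !is.null(os_days))
    nadir_flags <- rep(FALSE, length(values))
  }
  n <- length(values)
  if (n < 2L) stop("need at least 2 time points")
  if (anyNA(values)) stop("metric '", metric, "' missing at a time point")
  use_expert <- switch(nadir_mode, expert = TRUE, auto = FALSE,
                       auto_or_expert = any(nadir_flags))
  if (use_expert && !any(nadir_flags))
    stop("nadir_mode = 'expert' but no expert nadir flags in the series")
  ref <- rep(NA_real_, n)
  prog_idx <- NA_integer_
  zero_call <- FALSE
  for (t in 2:n) {
    ref[t] <- if (use_expert) {
      flagged <- which(nadir_flags[seq_len(t - 1)])
      if (length(flagged)) values[max(flagged)] else values[1]
    } else min(values[seq_len(t - 1)])
    if (ref[t] == 0) {
      if (values[t] > 0) {
        prog_idx <- t
        zero_call <- TRUE
        break
      }
    } else if (values[t] >= (1 + threshold) * ref[t]) {
      prog_idx <- t
      break
    }
  }
  progressed <- !is.na(prog_idx)
  structure(list(ttp_days = if (progressed) days[prog_idx] else as.integer(os_days),
                 progressed = progressed,
                 progression_index = prog_idx,
                 nadir_trace = ref, metric = metric, threshold = threshold,
                 zero_nadir_call = zero_call),
            class = "ttp_result")
}

#' @export
print.ttp_result <- function(x, ...) {
  cat(sprintf("<ttp_result %s, threshold %g%%> %s, TTP = %d days\n",
              x$metric, 100 * x$threshold,
              if (x$progressed)
                sprintf("progressed at time point %d", x$progression_index)
              else "no progression (TTP set to OS)",
              x$ttp_days))
  invisible(x)
}

# expert TTP: first time point rated progressive disease, else OS
expert_ttp <- function(series) {
  ratings <- vapply(series$timepoints,
                    function(tp) tp$expert_rating %||% NA_character_,
                    character(1))
  pd <- which(!is.na(ratings) & ratings == "PD")
  if (length(pd)) series_days(series)[pd[1]] else series$os_days
}

#' Progression-threshold sweep
#'
#' Evaluates, for each candidate threshold, the mean difference between the
#' automated TTP and the expert TTP across the cohort -- the curve used to
#' check whether progression thresholds should be adapted to the
#' sensitivity of a measurement method.
#'
#' @param cohort List of [patient_series] with the metric and expert
#'   ratings present.
#' @param metric Burden metric, see [compute_ttp()].
#' @param thresholds Numeric grid of relative thresholds.
#' @param nadir_mode Passed to [compute_ttp()].
#' @return data.frame with columns `threshold`, `mean_diff_days` and `n`.
#' @export
threshold_sweep <- function(cohort, metric = "volume",
                            thresholds = seq(0.05, 0.95, by = 0.05),
                            nadir_mode = "auto_or_expert") {
  ettp <- vapply(cohort, expert_ttp, numeric(1))
  out <- lapply(thresholds, function(th) {
    attp <- vapply(cohort, function(s)
      as.numeric(compute_ttp(s, metric, threshold = th,
                             nadir_mode = nadir_mode)$ttp_days), numeric(1))
    data.frame(threshold = th, mean_diff_days = mean(attp - ettp),
               n = length(cohort))
  })
  do.call(rbind, out)
}

#' Correlation between time-to-progression and overall survival
#'
#' Spearman rank correlation across patients between the automated TTP and
#' OS, with the exact permutation p-value for n <= 9 pairs and the
#' t-approximation otherwise.  A threshold that times progression calls
#' well should produce TTPs that rank patients like their survival does.
#'
#' @param cohort List of [patient_series].
#' @param metric,threshold,nadir_mode Passed to [compute_ttp()].
#' @return List with `rho` and `p_value`.
#' @export
ttp_os_correlation <- function(cohort, metric = "volume", threshold = NULL,
                               nadir_mode = "auto_or_expert") {
  stopifnot(length(cohort) >= 3L)
  ttp <- vapply(cohort, function(s)
    as.numeric(compute_ttp(s, metric, threshold = threshold,
                           nadir_mode = nadir_mode)$ttp_days), numeric(1))
  os <- vapply(cohort, function(s) as.numeric(s$os_days), numeric(1))
  if (stats::sd(rank(ttp)) == 0 || stats::sd(rank(os)) == 0)
    stop("degenerate ranks; TTP-OS correlation undefined")
  ct <- suppressWarnings(cor.test(ttp, os, method = "spearman",
                                  exact = length(ttp) <= 9L))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
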