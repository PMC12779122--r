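#' Extract the raw intensity profile of a sample lane
#'
#' Averages the denoised intensity across the lane's columns for every pixel
#' row and attaches the base-pair size of each row from the calibration map,
#' yielding the lane's intensity-versus-size curve. The per-lane baseline
#' (the minimum of the raw profile, later subtracted before integration) is
#' recorded as an attribute. A warning is raised when any signal falls on
#' extrapolated calibration rows.
#'
#' @param img A `gel_image` at stage `"denoised"`.
#' @param ls A [lane_set()].
#' @param lane Lane number (1-based) to profile; use the ladder lane only
#'   for diagnostics, not for sample QC.
#' @param cal A `calibration_map` covering the image rows.
#' @return A `gel_profile` tibble with columns `row`, `bp`, `raw`;
#'   attributes `baseline`, `lane`, `s` (NA until [profile_smooth()]).
#' @export
sample_profile <- function(img, ls, lane, cal) {
  stopifnot_stage(img, "denoised", "sample_profile")
  if (!inherits(ls, "lane_set")) abort_validation("`ls` must be a lane_set")
  check_scalar_number(lane, "lane", lo = 1, hi = ls$k)
  lane <- as.integer(lane)
  if (!inherits(cal, "calibration_map")) {
    abort_validation("`cal` must be a calibration_map")
  }
  nr <- nrow(img$pixels)
  if (length(cal$rows) != nr) {
    abort_validation(sprintf(
      "calibration covers %d rows but the image has %d", length(cal$rows), nr
    ))
  }
  cols <- ls$left[lane]:ls$right[lane]
  raw <- rowMeans(img$pixels[, cols, drop = FALSE])
  if (length(cal$extrapolated_rows) > 0) {
    mass <- sum(raw - min(raw))
    mass_ex <- sum((raw - min(raw))[cal$extrapolated_rows])
    if (mass > 0 && mass_ex / mass > 0.05) {
      warning(sprintf(
        "lane %d: %.1f%% of signal mass lies on extrapolated calibration rows",
        lane, 100 * mass_ex / mass
      ), call. = FALSE)
    }
  }
  out <- tibble::tibble(row = cal$rows, bp = cal$bp, raw = raw)
  structure_profile(out, baseline = min(raw), lane = lane, s = NA_real_)
}

structure_profile <- function(df, baseline, lane, s) {
  attr(df, "baseline") <- baseline
  attr(df, "lane") <- lane
  attr(df, "s") <- s
  class(df) <- unique(c("gel_profile", class(df)))
  df
}

#' Profile from explicit vectors
#'
#' Builds a `gel_profile` directly from paired base-pair and intensity
#' vectors, for synthetic curves and secondary analysis of exported data.
#'
#' @param bp Strictly monotone base-pair vector (descending with row, as
#'   produced by a calibration map, or ascending; stored as given).
#' @param raw Raw intensity vector, same length.
#' @param baseline Baseline to record; defaults to `min(raw)`.
#' @return A `gel_profile` tibble.
#' @export
as_gel_profile <- function(bp, raw, baseline = min(raw)) {
  bp <- as.numeric(bp); raw <- as.numeric(raw)
  if (length(bp) != length(raw)) abort_validation("`bp` and `raw` lengths differ")
  if (length(bp) < 3L) abort_validation("a profile needs at least 3 points")
  d <- diff(bp)
  if (!(all(d > 0) || all(d < 0))) {
    abort_validation("`bp` must be strictly monotone")
  }
  out <- tibble::tibble(row = seq_along(bp), bp = bp, raw = raw)
  structure_profile(out, baseline = baseline, lane = NA_integer_, s = NA_real_)
}

#' Blend raw and smoothed intensity
#'
#' Computes a Gaussian-weighted moving average of the raw profile and blends
#' it with the raw curve as `final = s * smoothed + (1 - s) * raw`, where
#' `s` in `[0, 1]` is the user's smoothing factor: 0 applies no smoothing,
#' 1 full smoothing.
#'
#' @param profile A `gel_profile`.
#' @param s Smoothing factor in `[0, 1]`.
#' @param window Odd window length in rows; defaults to
#'   `max(5, round(0.05 * profile length))`, forced odd.
#' @return The profile with `smoothed` and `final` columns added.
#' @export
profile_smooth <- function(profile, s = 0.5, window = NULL) {
  if (!inherits(profile, "gel_profile")) {
    abort_validation("`profile` must be a gel_profile")
  }
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    abort_validation(sprintf("smoothing factor `s` must be in [0, 1], got %s", s))
  }
  n <- nrow(profile)
  if (is.null(window)) {
    window <- max(5L, as.integer(round(0.05 * n)))
    if (window %% 2L == 0L) window <- window + 1L
  }
  sm <- gauss_moving_average(profile$raw, window)
  out <- profile
  out$smoothed <- sm
  out$final <- s * sm + (1 - s) * profile$raw
  structure_profile(out, baseline = attr(profile, "baseline"),
                    lane = attr(profile, "lane"), s = s)
}

#' Call peaks on a sample's intensity curve
#'
#' Local maxima of the final (blended) intensity with prominence at least
#' `min_prominence` of the curve's dynamic range above baseline, separated
#' by at least `min_distance_bp` on the base-pair axis. Peaks are reported
#' in descending base-pair order.
#'
#' @param profile A smoothed `gel_profile` (see [profile_smooth()]).
#' @param min_prominence Fraction of `(max(final) - baseline)`.
#' @param min_distance_bp Minimum base-pair separation between peaks.
#' @return A `gel_peaks` tibble with columns `row`, `peak_bp`,
#'   `peak_intensity`, `prominence`. Empty (with a warning) when the curve
#'   has no qualifying peak.
#' @export
call_peaks <- function(profile, min_prominence = 0.05, min_distance_bp = 25) {
  need_final(profile, "call_peaks")
  y <- profile$final
  base <- attr(profile, "baseline")
  rng <- max(y) - base
  empty <- tibble::tibble(row = integer(), peak_bp = numeric(),
                          peak_intensity = numeric(), prominence = numeric())
  class(empty) <- c("gel_peaks", class(empty))
  if (rng <= 0) {
    warning("no peaks detected: flat intensity curve", call. = FALSE)
    return(empty)
  }
  pk <- select_peaks(y, min_prominence = min_prominence * rng,
                     min_distance = min_distance_bp, pos = profile$bp)
  pk <- pk[pk$height > base, , drop = FALSE]
  if (nrow(pk) == 0L) {
    warning("no peaks detected on this intensity curve", call. = FALSE)
    return(empty)
  }
  out <- tibble::tibble(row = profile$row[pk$idx], peak_bp = profile$bp[pk$idx],
                        peak_intensity = pk$height, prominence = pk$prominence)
  out <- out[order(-out$peak_bp), ]
  class(out) <- c("gel_peaks", class(out))
  out
}

need_final <- function(profile, op) {
  if (!inherits(profile, "gel_profile") || is.null(profile$final)) {
    abort_validation(sprintf(
      "`%s` needs a smoothed profile; run profile_smooth() first", op
    ))
  }
  invisible(profile)
}

## ascending-bp view of a profile's baseline-subtracted final curve
ascending_curve <- function(profile) {
  base <- attr(profile, "baseline")
  y <- pmax(profile$final - base, 0)
  o <- order(profile$bp)
  list(bp = profile$bp[o], y = y[o], final = profile$final[o],
       row = profile$row[o])
}

#' Relative area under the curve for each peak
#'
#' Splits the baseline-subtracted intensity curve at the valley (the
#' minimum of the final curve) between each pair of adjacent peaks — the
#' outermost segments extend to the profile ends — and integrates each
#' segment over the (non-uniform) calibrated base-pair axis by trapezoidal
#' quadrature. Each peak's area is reported as a percentage of the total
#' curve area; segments partition the curve, so the percentages sum to 100.
#'
#' @param profile A smoothed `gel_profile`.
#' @param peaks A `gel_peaks` tibble from [call_peaks()] on this profile.
#' @return `peaks` with `left_bound_bp`, `right_bound_bp` (lower and upper
#'   base-pair integration limits) and `relative_area_pct` filled in.
#' @export
peak_areas <- function(profile, peaks) {
  need_final(profile, "peak_areas")
  if (!inherits(peaks, "gel_peaks")) abort_validation("`peaks` must be a gel_peaks table")
  if (nrow(peaks) == 0L) {
    peaks$left_bound_bp <- numeric(0)
    peaks$right_bound_bp <- numeric(0)
    peaks$relative_area_pct <- numeric(0)
    return(peaks)
  }
  ac <- ascending_curve(profile)
  n <- length(ac$bp)
  pidx <- match(peaks$row, ac$row)
  o <- order(pidx)
  pidx_sorted <- pidx[o]
  m <- length(pidx_sorted)
  cuts <- integer(m + 1L)
  cuts[1] <- 1L
  cuts[m + 1L] <- n
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      a <- pidx_sorted[i]; b <- pidx_sorted[i + 1L]
      seg <- ac$final[a:b]
      cuts[i + 1L] <- a + which.min(seg) - 1L
    }
  }
  total <- pracma::trapz(ac$bp, ac$y)
  areas <- numeric(m)
  for (i in seq_len(m)) {
    rangei <- cuts[i]:cuts[i + 1L]
    areas[i] <- pracma::trapz(ac$bp[rangei], ac$y[rangei])
  }
  if (total <= 0) {
    warning("total curve area is zero; relative areas set to 0", call. = FALSE)
    rel <- rep(0, m)
  } else {
    rel <- 100 * areas / total
  }
  out <- peaks
  out$left_bound_bp <- NA_real_
  out$right_bound_bp <- NA_real_
  out$relative_area_pct <- NA_real_
  out$left_bound_bp[o] <- ac$bp[cuts[seq_len(m)]]
  out$right_bound_bp[o] <- ac$bp[cuts[seq_len(m) + 1L]]
  out$relative_area_pct[o] <- rel
  out
}

#' Percentage of signal mass within a target size range
#'
#' Trapezoidal integral of the baseline-subtracted final intensity over the
#' base-pair interval `[lo_bp, hi_bp]` (partial intervals handled by linear
#' interpolation of the curve at the exact range endpoints), as a percentage
#' of the total baseline-subtracted curve area. This is the headline
#' fragmentation QC metric: the share of fragments inside the target size
#' window.
#'
#' @param profile A smoothed `gel_profile`.
#' @param lo_bp,hi_bp Target base-pair range, `lo_bp < hi_bp`.
#' @return A percentage in `[0, 100]`. Returns 0 with a warning when the
#'   range lies entirely outside the calibrated span.
#' @export
pct_in_range <- function(profile, lo_bp, hi_bp) {
  need_final(profile, "pct_in_range")
  check_scalar_number(lo_bp, "lo_bp")
  check_scalar_number(hi_bp, "hi_bp")
  if (lo_bp >= hi_bp) abort_validation("`lo_bp` must be less than `hi_bp`")
  ac <- ascending_curve(profile)
  span <- range(ac$bp)
  if (hi_bp <= span[1] || lo_bp >= span[2]) {
    warning(sprintf(
      "target range [%g, %g] bp lies outside the calibrated span [%g, %g]",
      lo_bp, hi_bp, span[1], span[2]
    ), call. = FALSE)
    return(0)
  }
  total <- pracma::trapz(ac$bp, ac$y)
  if (total <= 0) {
    warning("total curve area is zero; pct_in_range set to 0", call. = FALSE)
    return(0)
  }
  lo <- max(lo_bp, span[1]); hi <- min(hi_bp, span[2])
  inside <- ac$bp > lo & ac$bp < hi
  xs <- c(lo, ac$bp[inside], hi)
  ys <- c(stats::approx(ac$bp, ac$y, xout = lo)$y,
          ac$y[inside],
          stats::approx(ac$bp, ac$y, xout = hi)$y)
  part <- pracma::trapz(xs, ys)
  min(max(100 * part / total, 0), 100)
}

#' Percent error of a measured peak size against a reference
#'
#' `100 * |measured - reference| / reference`, the band-wise accuracy
#' measure used when benchmarking against ladders of known size.
#'
#' @param peak_measured Measured peak size(s), bp.
#' @param peak_reference Reference size(s), bp; must be positive.
#' @return Percent error(s), `>= 0`.
#' @export
percent_error <- function(peak_measured, peak_reference) {
  if (!is.numeric(peak_measured) || !is.numeric(peak_reference)) {
    abort_validation("inputs must be numeric")
  }
  if (any(peak_reference <= 0)) {
    abort_validation("`peak_reference` must be positive")
  }
  100 * abs(peak_measured - peak_reference) / peak_reference
}

#' Drop low-area peaks attributed to noise
#'
#' Optional post-filter: peaks whose relative area percentage falls below a
#' threshold are treated as noise and removed. The default threshold 0
#' disables the filter.
#'
#' @param peaks A `gel_peaks` tibble with `relative_area_pct` filled.
#' @param min_area_pct Threshold in percentage points.
#' @return The filtered `gel_peaks` tibble.
#' @export
filter_peaks <- function(peaks, min_area_pct = 0) {
  if (!inherits(peaks, "gel_peaks")) abort_validation("`peaks` must be a gel_peaks table")
  check_scalar_number(min_area_pct, "min_area_pct", lo = 0, hi = 100)
  if (min_area_pct == 0 || nrow(peaks) == 0L) return(peaks)
  peaks[peaks$relative_area_pct >= min_area_pct, , drop = FALSE]
}
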