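#' Ladder specification
#'
#' The known marker sizes of the reference DNA ladder, in base pairs,
#' strictly descending (largest fragment first: it migrates least and sits
#' nearest the well, i.e. the lowest row index).
#'
#' @param bp_values Numeric vector of at least 3 strictly descending
#'   positive marker sizes.
#' @return A `ladder_spec` object.
#' @export
ladder_spec <- function(bp_values) {
  bp_values <- as.numeric(bp_values)
  if (length(bp_values) < 3L) {
    abort_validation("a ladder needs at least 3 marker sizes")
  }
  if (anyNA(bp_values) || any(bp_values <= 0)) {
    abort_validation("ladder marker sizes must be positive")
  }
  if (any(diff(bp_values) >= 0)) {
    abort_validation("ladder marker sizes must be strictly descending (largest first)")
  }
  structure(list(bp_values = bp_values), class = "ladder_spec")
}

#' A 14-marker 75 bp – 10 kb ladder
#'
#' Marker sizes of a broad-range 1 kb-plus style ladder, used as the default
#' ladder of the gel simulator.
#'
#' @return A [ladder_spec()].
#' @export
ladder_1kb_plus <- function() {
  ladder_spec(c(10000, 7000, 5000, 4000, 3000, 2000, 1500,
                1000, 700, 500, 400, 300, 200, 75))
}

#' Row-wise intensity profile of the ladder lane
#'
#' Averages the denoised intensity across the ladder lane's columns for each
#' pixel row, then min–max normalises the result to `[0, 1]`.
#'
#' @param img A `gel_image` at stage `"denoised"`.
#' @param ls A [lane_set()]; the lane at `ls$ladder_index` is profiled.
#' @return A tibble with columns `row` and `intensity` (normalised).
#' @export
ladder_profile <- function(img, ls) {
  stopifnot_stage(img, "denoised", "ladder_profile")
  if (!inherits(ls, "lane_set")) abort_validation("`ls` must be a lane_set")
  li <- ls$ladder_index
  cols <- ls$left[li]:ls$right[li]
  v <- rowMeans(img$pixels[, cols, drop = FALSE])
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("ladder lane profile has zero variance; no markers can be located",
            call. = FALSE)
    v <- rep(0, length(v))
  } else {
    v <- (v - rng[1]) / diff(rng)
  }
  tibble::tibble(row = seq_along(v), intensity = v)
}

#' Locate ladder markers on a lane profile
#'
#' Finds local maxima of the normalised ladder profile — each corresponds to
#' one ladder marker band — subject to a minimum peak prominence and a
#' minimum inter-peak distance. If more peaks than ladder markers are found,
#' the most prominent ones are kept (prominence ties break toward the lower
#' row). Peaks are then matched to marker sizes by row order: the topmost
#' peak is the largest fragment.
#'
#' @param profile Tibble from [ladder_profile()] (columns `row`,
#'   `intensity`), or a bare numeric intensity vector.
#' @param spec A [ladder_spec()].
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   normalised intensity range.
#' @param min_distance Minimum row separation between accepted peaks;
#'   defaults to `floor(profile_length / (3 * n_markers))`.
#' @return A `gel_markers` tibble with columns `row`, `bp`, `prominence`.
#' @export
detect_markers <- function(profile, spec, min_prominence = 0.05,
                           min_distance = NULL) {
  if (!inherits(spec, "ladder_spec")) abort_validation("`spec` must be a ladder_spec")
  y <- if (is.data.frame(profile)) profile$intensity else as.numeric(profile)
  n_markers <- length(spec$bp_values)
  if (is.null(min_distance)) {
    min_distance <- max(1L, length(y) %/% (3L * n_markers))
  }
  pk <- select_peaks(y, min_prominence = min_prominence,
                     min_distance = min_distance)
  if (nrow(pk) < n_markers) {
    abort_calibration(sprintf(
      paste0("found %d candidate marker peaks but the ladder has %d markers; ",
             "lower `min_prominence`/`min_distance` or supply rows via ",
             "override_markers()"),
      nrow(pk), n_markers
    ))
  }
  if (nrow(pk) > n_markers) {
    ord <- order(-pk$prominence, pk$idx)
    pk <- pk[sort(ord[seq_len(n_markers)]), , drop = FALSE]
  }
  new_gel_markers(pk$idx, spec$bp_values, pk$prominence)
}

#' Construct a marker table from known rows
#'
#' Builds the marker localisation directly from user-supplied pixel rows —
#' the fully manual calibration path, for when automatic detection is not
#' wanted or not possible.
#'
#' @param rows Strictly ascending pixel rows, one per marker.
#' @param bp_values Matching marker sizes (descending; largest bp pairs
#'   with the topmost row), or a [ladder_spec()].
#' @return A `gel_markers` tibble.
#' @export
gel_markers <- function(rows, bp_values) {
  if (inherits(bp_values, "ladder_spec")) bp_values <- bp_values$bp_values
  new_gel_markers(rows, bp_values)
}

new_gel_markers <- function(rows, bp_values, prominences = NA_real_) {
  rows <- as.integer(rows)
  if (length(rows) != length(bp_values)) {
    abort_validation(sprintf(
      "%d marker rows do not match %d ladder sizes",
      length(rows), length(bp_values)
    ))
  }
  if (any(diff(rows) <= 0)) {
    abort_validation("marker rows must be strictly ascending")
  }
  out <- tibble::tibble(row = rows, bp = as.numeric(bp_values),
                        prominence = as.numeric(prominences))
  class(out) <- c("gel_markers", class(out))
  out
}

#' Replace detected marker rows
#'
#' Programmatic equivalent of manually adjusting marker locations: supply
#' the pixel row of every marker yourself (topmost row pairs with the
#' largest fragment).
#'
#' @param ml A `gel_markers` tibble from [detect_markers()].
#' @param new_rows Strictly ascending integer rows, one per marker.
#' @return A new `gel_markers` tibble.
#' @export
override_markers <- function(ml, new_rows) {
  if (!inherits(ml, "gel_markers")) abort_validation("`ml` must be a gel_markers table")
  new_gel_markers(new_rows, ml$bp, rep(NA_real_, length(new_rows)))
}

#' Build the pixel-row to base-pair calibration map
#'
#' Linearly interpolates base-pair size against pixel row between
#' consecutive marker knots; rows above the first and below the last knot
#' are linearly extrapolated from the nearest two knots and flagged. The
#' resulting map is strictly decreasing in row (smaller fragments migrate
#' farther) and passes exactly through every knot.
#'
#' @param ml A `gel_markers` tibble (needs at least 2 markers).
#' @param n_rows Number of rows of the analysed region.
#' @return A `calibration_map` object.
#' @export
build_calibration <- function(ml, n_rows) {
  if (!inherits(ml, "gel_markers")) abort_validation("`ml` must be a gel_markers table")
  if (nrow(ml) < 2L) abort_validation("calibration needs at least 2 markers")
  if (anyDuplicated(ml$row)) {
    abort_validation("two markers share the same pixel row; calibration is degenerate")
  }
  check_scalar_number(n_rows, "n_rows", lo = 2)
  rows <- seq_len(as.integer(n_rows))
  bp <- bp_interp(rows, ml$row, ml$bp)
  if (any(diff(bp) >= 0)) {
    abort_calibration("calibration map is not strictly decreasing in row")
  }
  structure(
    list(rows = rows, bp = bp,
         knots = tibble::tibble(row = ml$row, bp = ml$bp),
         extrapolated_rows = rows[rows < min(ml$row) | rows > max(ml$row)]),
    class = "calibration_map"
  )
}

## piecewise-linear interpolation with linear extrapolation from the two
## nearest knots on each end
bp_interp <- function(x, kx, ky) {
  n <- length(kx)
  out <- stats::approx(kx, ky, xout = x, method = "linear", rule = 1)$y
  sl_lo <- (ky[2] - ky[1]) / (kx[2] - kx[1])
  sl_hi <- (ky[n] - ky[n - 1]) / (kx[n] - kx[n - 1])
  lo <- x < kx[1]; hi <- x > kx[n]
  out[lo] <- ky[1] + sl_lo * (x[lo] - kx[1])
  out[hi] <- ky[n] + sl_hi * (x[hi] - kx[n])
  out
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf(
    "<calibration_map> %d rows, %d knots (%g-%g bp), %d extrapolated rows\n",
    length(x$rows), nrow(x$knots), min(x$knots$bp), max(x$knots$bp),
    length(x$extrapolated_rows)
  ))
  invisible(x)
}

#' Base-pair size at given pixel rows
#'
#' @param cal A `calibration_map`.
#' @param rows Pixel rows (may be fractional).
#' @return Numeric base-pair sizes.
#' @export
bp_at_row <- function(cal, rows) {
  if (!inherits(cal, "calibration_map")) {
    abort_validation("`cal` must be a calibration_map")
  }
  bp_interp(rows, cal$knots$row, cal$knots$bp)
}

#' @rdname build_calibration
#' @param x A `calibration_map`.
#' @param ... Unused.
#' @export
tidy.calibration_map <- function(x, ...) {
  tibble::tibble(row = x$rows, bp = x$bp,
                 extrapolated = x$rows %in% x$extrapolated_rows)
}
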