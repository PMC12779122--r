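#' Lane boundary set
#'
#' Ordered left/right column boundaries of the `k` vertical lanes of a gel,
#' plus which lane holds the reference ladder. Boundaries are 1-based column
#' indices, strictly ascending; consecutive boundaries pair into lanes
#' (1st–2nd, 3rd–4th, ...).
#'
#' @param boundaries Integer vector of `2 * k` strictly ascending column
#'   indices.
#' @param k Number of lanes.
#' @param ladder_index Which lane (1-based) is the ladder.
#' @param image_width Optional image width used for bounds checking.
#' @return A `lane_set` object.
#' @export
lane_set <- function(boundaries, k, ladder_index, image_width = NULL) {
  check_scalar_number(k, "k", lo = 1)
  k <- as.integer(k)
  check_scalar_number(ladder_index, "ladder_index", lo = 1, hi = k)
  ladder_index <- as.integer(ladder_index)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 2L * k) {
    abort_validation(sprintf(
      "expected %d boundaries for k = %d lanes, got %d",
      2L * k, k, length(boundaries)
    ))
  }
  if (anyNA(boundaries) || any(diff(boundaries) <= 0)) {
    abort_validation("boundaries must be strictly ascending")
  }
  if (any(boundaries < 1)) abort_validation("boundaries must be >= 1")
  if (!is.null(image_width) && any(boundaries > image_width)) {
    abort_validation(sprintf(
      "boundary %d exceeds image width %d",
      max(boundaries), image_width
    ))
  }
  left <- boundaries[seq(1L, 2L * k, by = 2L)]
  right <- boundaries[seq(2L, 2L * k, by = 2L)]
  if (any(right - left + 1 < 3)) {
    abort_validation("every lane must be at least 3 columns wide")
  }
  structure(
    list(boundaries = as.integer(round(boundaries)), k = k,
         ladder_index = ladder_index,
         left = as.integer(round(left)), right = as.integer(round(right)),
         image_width = if (is.null(image_width)) NA_integer_ else as.integer(image_width)),
    class = "lane_set"
  )
}

#' @export
print.lane_set <- function(x, ...) {
  cat(sprintf("<lane_set> k=%d lanes, ladder=lane %d\n", x$k, x$ladder_index))
  print(tidy_lane_set(x))
  invisible(x)
}

tidy_lane_set <- function(x) {
  tibble::tibble(
    lane = seq_len(x$k),
    left = x$left,
    right = x$right,
    width = x$right - x$left + 1L,
    is_ladder = seq_len(x$k) == x$ladder_index
  )
}

#' @rdname lane_set
#' @param x A `lane_set`.
#' @param ... Unused.
#' @export
tidy.lane_set <- function(x, ...) tidy_lane_set(x)

#' Canny edge map of a denoised gel image
#'
#' Edges are located at local maxima of the image gradient (Sobel
#' derivatives after Gaussian smoothing, with non-maximum suppression along
#' the gradient direction) and kept by hysteresis between a high and a low
#' threshold. By default the high threshold is set from the cumulative
#' histogram of the gradient magnitude — the smallest 64-bin edge below
#' which 70% of all pixels fall, the classic automatic-Canny heuristic —
#' and the low threshold to `low_frac` times the high one. Gel images
#' carry three gradient populations (background noise, faint full-height
#' lane-track borders, strong band sides); a two-class split such as Otsu's
#' lands between the last two and discards the faint lane borders, so the
#' percentile rule is the default.
#'
#' @param img A `gel_image` at stage `"denoised"`.
#' @param sigma Gaussian pre-smoothing standard deviation in pixels.
#' @param high,low Optional explicit hysteresis thresholds on the gradient
#'   magnitude.
#' @param low_frac Low threshold as a fraction of the high threshold.
#' @return A logical matrix of edge pixels, same shape as the image.
#' @export
gel_edge_map <- function(img, sigma = 1, high = NULL, low = NULL, low_frac = 0.4) {
  stopifnot_stage(img, "denoised", "gel_edge_map")
  x <- gauss_blur(img$pixels, sigma)
  nr <- nrow(x); nc <- ncol(x)
  xp <- pad_replicate(x, 1L)
  sv <- function(di, dj) shift_view(xp, di, dj, nr, nc, 1L)
  gx <- (sv(-1, 1) + 2 * sv(0, 1) + sv(1, 1)) -
        (sv(-1, -1) + 2 * sv(0, -1) + sv(1, -1))
  gy <- (sv(1, -1) + 2 * sv(1, 0) + sv(1, 1)) -
        (sv(-1, -1) + 2 * sv(-1, 0) + sv(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nr, nc))

  ## non-maximum suppression along the quantised gradient direction
  theta <- atan2(gy, gx)
  theta[theta < 0] <- theta[theta < 0] + pi
  sector <- (floor(theta / (pi / 4) + 0.5)) %% 4
  mp <- pad_replicate(mag, 1L)
  msv <- function(di, dj) shift_view(mp, di, dj, nr, nc, 1L)
  n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    o <- offs[[as.character(s)]]
    n1[sel] <- msv(o[1], o[2])[sel]
    n2[sel] <- msv(-o[1], -o[2])[sel]
  }
  nms <- ifelse(mag >= n1 & mag >= n2, mag, 0)

  mx <- max(mag)
  if (is.null(high)) {
    ## 64-bin cumulative-histogram rule: 70% of pixels are not edges
    cnt <- tabulate(pmin(64L, floor(mag / mx * 64) + 1L), nbins = 64L)
    bin <- which(cumsum(cnt) >= 0.7 * length(mag))[1]
    high <- mx * bin / 64
  }
  if (is.null(low)) low <- low_frac * high
  if (high <= 0) return(matrix(FALSE, nr, nc))
  strong <- nms >= high
  weak <- nms >= low
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  labels <- EBImage::bwlabel(t(weak))
  keep <- unique(labels[t(strong)])
  keep <- keep[keep > 0]
  t(matrix(labels %in% keep, nrow(labels), ncol(labels)))
}

#' Per-column vertical-edge strength
#'
#' Applies a vertical-edge-selective Sobel operator to a binary edge map and
#' sums the absolute response down each column. Columns traversed by long
#' vertical edge runs — lane boundaries, assuming lanes are oriented
#' vertically — score highest.
#'
#' @param edges Logical (or 0/1 numeric) matrix from [gel_edge_map()].
#' @return Numeric vector of one score per column.
#' @export
lane_edge_strength <- function(edges) {
  e <- matrix(as.numeric(edges), nrow(edges), ncol(edges))
  nr <- nrow(e); nc <- ncol(e)
  ep <- pad_replicate(e, 1L)
  sv <- function(di, dj) shift_view(ep, di, dj, nr, nc, 1L)
  gx <- (sv(-1, 1) + 2 * sv(0, 1) + sv(1, 1)) -
        (sv(-1, -1) + 2 * sv(0, -1) + sv(1, -1))
  colSums(abs(gx))
}

#' Detect lane boundaries
#'
#' Runs [gel_edge_map()] and [lane_edge_strength()], then selects the
#' `2 * k` highest-scoring columns under non-maximum suppression (no two
#' selected columns closer than `min_lane_width`; equal scores break ties
#' toward the lower column index), sorts them ascending and pairs
#' consecutive boundaries into lanes.
#'
#' @inheritParams gel_edge_map
#' @param k Number of lanes in the image (user input).
#' @param ladder_index Which lane (1-based, left to right) is the ladder.
#' @param min_lane_width Minimum separation between selected boundary
#'   columns; defaults to `floor(image_width / (4 * k))`.
#' @param ... Passed to [gel_edge_map()].
#' @return A [lane_set()].
#' @export
gel_detect_lanes <- function(img, k, ladder_index = 1L, min_lane_width = NULL, ...) {
  stopifnot_stage(img, "denoised", "gel_detect_lanes")
  check_scalar_number(k, "k", lo = 1)
  k <- as.integer(k)
  check_scalar_number(ladder_index, "ladder_index", lo = 1, hi = k)
  nc <- ncol(img$pixels)
  if (is.null(min_lane_width)) min_lane_width <- max(3L, nc %/% (4L * k))
  if (nc < 2L * k * 3L) {
    abort_validation(sprintf(
      "image of width %d cannot hold %d lanes of >= 3 columns", nc, k
    ))
  }
  edges <- gel_edge_map(img, ...)
  score <- lane_edge_strength(edges)
  ## a 1-px edge line excites the vertical Sobel on its two flanking
  ## columns; pick maxima on a lightly smoothed score, then centre each
  ## boundary at the local score centroid so the twin responses merge
  smoothed <- c(score[1], score[-length(score)]) / 4 + score / 2 +
    c(score[-1], score[length(score)]) / 4
  sel <- integer(0)
  sc <- smoothed
  suppressed <- rep(FALSE, nc)
  while (length(sel) < 2L * k && any(sc > 0)) {
    i <- which.max(sc)  # ties: which.max takes the first (lowest column)
    w <- max(1L, i - 2L):min(nc, i + 2L)
    ctr <- as.integer(floor(sum(w * score[w]) / sum(score[w]) + 0.5))
    if (suppressed[ctr]) {  # residual tail of an already-claimed ridge
      sc[i] <- 0
      next
    }
    sel <- c(sel, ctr)
    lo <- max(1L, ctr - (min_lane_width - 1L))
    hi <- min(nc, ctr + (min_lane_width - 1L))
    sc[lo:hi] <- 0
    suppressed[lo:hi] <- TRUE
  }
  if (length(sel) < 2L * k) {
    abort_detection(sprintf(
      paste0("lane detection found only %d boundary candidates but %d are ",
             "required for k = %d lanes; supply boundaries manually via ",
             "override_lanes() or the `boundaries` option"),
      length(sel), 2L * k, k
    ))
  }
  sel <- sort(sel)
  ## lanes are roughly constant width; grossly uneven detected widths mean
  ## the requested k does not match the image
  widths <- sel[seq(2L, 2L * k, 2L)] - sel[seq(1L, 2L * k, 2L)] + 1L
  med_w <- stats::median(widths)
  if (k > 1L && diff(range(widths)) > 0.5 * med_w) {
    abort_detection(paste0(
      "detected lane widths are grossly uneven (", paste(widths, collapse = ", "),
      "); the lane count k may not match the image - supply boundaries ",
      "manually via override_lanes() or the `boundaries` option"
    ))
  }
  lane_set(sel, k = k, ladder_index = ladder_index, image_width = nc)
}

#' Replace detected lane boundaries
#'
#' Programmatic equivalent of manually adjusting inaccurate lane
#' detections: supply all `2 * k` boundary columns yourself. All lane-set
#' invariants are re-validated.
#'
#' @param ls A `lane_set`.
#' @param new_boundaries Strictly ascending vector of `2 * k` column indices.
#' @return A new `lane_set`.
#' @export
override_lanes <- function(ls, new_boundaries) {
  if (!inherits(ls, "lane_set")) abort_validation("`ls` must be a lane_set")
  lane_set(new_boundaries, k = ls$k, ladder_index = ls$ladder_index,
           image_width = if (is.na(ls$image_width)) NULL else ls$image_width)
}
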