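## Internal numerical helpers shared across modules.

abort_validation <- function(msg) {
  rlang::abort(msg, class = c("gelqc_error_validation", "gelqc_error"))
}

abort_input <- function(msg) {
  rlang::abort(msg, class = c("gelqc_error_input", "gelqc_error"))
}

abort_detection <- function(msg) {
  rlang::abort(msg, class = c("gelqc_error_detection", "gelqc_error"))
}

abort_calibration <- function(msg) {
  rlang::abort(msg, class = c("gelqc_error_calibration", "gelqc_error"))
}

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation(sprintf("`%s` must be a single number", name))
  }
  if (x < lo || x > hi) {
    abort_validation(sprintf("`%s` must be in [%s, %s], got %s", name, lo, hi, x))
  }
  invisible(x)
}

check_odd_size <- function(x, name, min = 3L) {
  check_scalar_number(x, name, lo = min)
  if (x %% 2 == 0) {
    abort_validation(sprintf("`%s` must be odd, got %d", name, as.integer(x)))
  }
  as.integer(x)
}

## Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(x, p) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rep(1L, p), seq_len(nr), rep(nr, p))
  ci <- c(rep(1L, p), seq_len(nc), rep(nc, p))
  x[ri, ci, drop = FALSE]
}

## View of a padded matrix shifted by (di, dj); used to build small
## convolutions without loops. `p` is the pad width of `xp`.
shift_view <- function(xp, di, dj, nr, nc, p) {
  xp[(1 + p + di):(nr + p + di), (1 + p + dj):(nc + p + dj), drop = FALSE]
}

## Separable box mean with replicate boundary handling; preserves constants
## exactly. w must be odd.
box_mean <- function(x, w) {
  r <- (w - 1L) / 2L
  xp <- pad_replicate(x, r)
  acc <- matrix(0, nrow(x), ncol(x))
  for (di in -r:r) acc <- acc + shift_view(xp, di, 0L, nrow(x), ncol(x), r)
  acc <- acc / w
  xp <- pad_replicate(acc, r)
  acc2 <- matrix(0, nrow(x), ncol(x))
  for (dj in -r:r) acc2 <- acc2 + shift_view(xp, 0L, dj, nrow(x), ncol(x), r)
  acc2 / w
}

## Separable Gaussian blur with replicate boundaries.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  xp <- pad_replicate(x, r)
  acc <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) {
    acc <- acc + k[i] * shift_view(xp, (-r:r)[i], 0L, nrow(x), ncol(x), r)
  }
  xp <- pad_replicate(acc, r)
  acc2 <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) {
    acc2 <- acc2 + k[i] * shift_view(xp, 0L, (-r:r)[i], nrow(x), ncol(x), r)
  }
  acc2
}

## Gaussian-weighted moving average of a vector, window w (odd); weights are
## renormalised near the ends so constants are preserved exactly. The kernel
## standard deviation follows the w/5 convention of Gaussian-window smoothers.
gauss_moving_average <- function(y, w) {
  w <- check_odd_size(w, "window", min = 3L)
  n <- length(y)
  r <- (w - 1L) / 2L
  sd <- (w - 1) / 5
  k <- stats::dnorm(-r:r, sd = sd)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
    out[i] <- sum(kk * y[lo:hi]) / sum(kk)
  }
  out
}

## Local maxima of a vector with prominences (lowest-contour-line definition).
## Plateaus report their centre (rounded down). Returns a data.frame with
## columns idx, height, prominence, ordered by idx.
local_peaks <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(idx = integer(), height = numeric(), prominence = numeric()))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) {
        idx <- c(idx, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(idx) == 0L) {
    return(data.frame(idx = integer(), height = numeric(), prominence = numeric()))
  }
  prom <- vapply(idx, function(p) {
    h <- y[p]
    lmin <- h
    for (q in seq(p - 1L, 1L)) {
      if (y[q] > h) break
      if (y[q] < lmin) lmin <- y[q]
    }
    left_base <- lmin
    rmin <- h
    if (p < n) {
      for (q in seq(p + 1L, n)) {
        if (y[q] > h) break
        if (y[q] < rmin) rmin <- y[q]
      }
    }
    right_base <- rmin
    h - max(left_base, right_base)
  }, numeric(1))
  data.frame(idx = idx, height = y[idx], prominence = prom)
}

## Prominence- and distance-filtered peak selection. Peaks are admitted in
## decreasing prominence (ties broken by lower index); a candidate closer
## than min_distance (on the `pos` axis, default the index) to an already
## admitted peak is suppressed.
select_peaks <- function(y, min_prominence = 0, min_distance = 0, pos = NULL) {
  pk <- local_peaks(y)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) == 0L) return(pk)
  if (is.null(pos)) pos <- seq_along(y)
  ord <- order(-pk$prominence, pk$idx)
  pk <- pk[ord, , drop = FALSE]
  keep <- logical(nrow(pk))
  kept_pos <- numeric(0)
  for (i in seq_len(nrow(pk))) {
    p <- pos[pk$idx[i]]
    if (length(kept_pos) == 0L || all(abs(kept_pos - p) >= min_distance)) {
      keep[i] <- TRUE
      kept_pos <- c(kept_pos, p)
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk[order(pk$idx), , drop = FALSE]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
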