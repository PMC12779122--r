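#' Fill hole artifacts by grayscale morphological reconstruction
#'
#' Holes — regional intensity minima not connected to the image border, such
#' as dust or bubbles inside bright bands — are raised to the level of their
#' surroundings by reconstructing the complement image from its border
#' (reconstruction by dilation, 8-connected). On a bands-bright image this
#' never decreases any pixel value.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @return Matrix of the same shape with holes filled.
#' @export
fill_holes <- function(pixels) {
  comp <- 1 - pixels
  marker <- matrix(0, nrow(comp), ncol(comp))
  marker[1, ] <- comp[1, ]
  marker[nrow(comp), ] <- comp[nrow(comp), ]
  marker[, 1] <- comp[, 1]
  marker[, ncol(comp)] <- comp[, ncol(comp)]
  rec <- .reconstruct_dilation(marker, comp)
  1 - rec
}

## Vectorised 3x3 median with replicate borders: sort each 3-pixel row of
## the window, then median-of-3 of (max of mins, median of medians, min of
## maxes) — the classic 9-element median network.
median_filter_3 <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  xp <- pad_replicate(px, 1L)
  g <- function(di, dj) shift_view(xp, di, dj, nr, nc, 1L)
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  lo <- med <- hi <- vector("list", 3L)
  for (j in -1:1) {
    a <- g(-1, j); b <- g(0, j); c <- g(1, j)
    lo[[j + 2]] <- pmin(a, b, c)
    hi[[j + 2]] <- pmax(a, b, c)
    med[[j + 2]] <- med3(a, b, c)
  }
  med3(pmax(lo[[1]], lo[[2]], lo[[3]]),
       med3(med[[1]], med[[2]], med[[3]]),
       pmin(hi[[1]], hi[[2]], hi[[3]]))
}

## Pixel-wise adaptive (local Wiener) filter: local mean and variance are
## estimated over a w x w window; smoothing is inversely proportional to the
## estimated local variance, with the noise power taken as the mean local
## variance. Flat regions collapse to their local mean; high-variance
## (edge) regions pass through.
wiener_adaptive <- function(pixels, w) {
  mu <- box_mean(pixels, w)
  sig2 <- pmax(box_mean(pixels^2, w) - mu^2, 0)
  noise <- mean(sig2)
  denom <- pmax(sig2, noise)
  gain <- ifelse(denom > 0, pmax(sig2 - noise, 0) / denom, 0)
  mu + gain * (pixels - mu)
}

#' Denoise a gel image
#'
#' Applies, in order: polarity normalisation (the image is inverted if bands
#' are dark so that all downstream analysis sees bright bands on a dark
#' background), hole filling by grayscale morphological reconstruction
#' ([fill_holes()]), a median filter, and a pixel-wise adaptive local-Wiener
#' filter whose smoothing strength is inversely proportional to the local
#' variance. Quantification is performed on this denoised image; the
#' contrast-enhanced image from [gel_enhance()] is for display only.
#'
#' @param img A `gel_image` at stage `"raw"`.
#' @param median_size Odd window size (pixels) of the median filter.
#' @param wiener_size Odd window size (pixels) of the adaptive filter.
#' @return A `gel_image` at stage `"denoised"`, polarity `bands_bright`.
#' @export
gel_denoise <- function(img, median_size = 3L, wiener_size = 5L) {
  stopifnot_stage(img, "raw", "gel_denoise")
  median_size <- check_odd_size(median_size, "median_size")
  wiener_size <- check_odd_size(wiener_size, "wiener_size")
  if (nrow(img$pixels) < 16L || ncol(img$pixels) < 16L) {
    abort_validation("denoising requires an image of at least 16 x 16 pixels")
  }
  px <- img$pixels
  if (img$polarity == "bands_dark") px <- 1 - px
  px <- fill_holes(px)
  if (stats::sd(px) > 0) {
    px <- if (median_size == 3L) {
      median_filter_3(px)
    } else {
      t(EBImage::medianFilter(t(px), size = (median_size - 1L) / 2L))
    }
  }
  px <- wiener_adaptive(px, wiener_size)
  gel_image(clip01(px), polarity = "bands_bright", stage = "denoised",
            source = img$source)
}

#' Contrast-enhance a denoised image for display
#'
#' Contrast-limited adaptive histogram equalisation (CLAHE) applied to the
#' denoised image. The result is for visualisation and QC overlays only:
#' quantification always runs on the denoised image, and results are
#' identical whether or not this function is called.
#'
#' @param img A `gel_image` at stage `"denoised"`.
#' @param tiles Number of contextual tiles per axis.
#' @param clip_limit Normalised clip limit in `(0, 1]`; higher values allow
#'   stronger local contrast amplification.
#' @return A `gel_image` at stage `"display"`.
#' @export
gel_enhance <- function(img, tiles = 8L, clip_limit = 0.01) {
  stopifnot_stage(img, "denoised", "gel_enhance")
  check_scalar_number(tiles, "tiles", lo = 1)
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L ||
      clip_limit <= 0 || clip_limit > 1) {
    abort_validation(sprintf("`clip_limit` must be in (0, 1], got %s", clip_limit))
  }
  px <- img$pixels
  rng <- range(px)
  if (diff(rng) == 0) {
    return(gel_image(px, polarity = img$polarity, stage = "display",
                     source = img$source))
  }
  nx <- max(1L, min(as.integer(tiles), ncol(px) %/% 8L))
  ny <- max(1L, min(as.integer(tiles), nrow(px) %/% 8L))
  limit <- max(1, clip_limit * 256)
  ## the CLAHE kernel needs dimensions divisible by the tile counts:
  ## replicate-pad to the next multiple, enhance, crop back
  nr <- nrow(px); nc <- ncol(px)
  nr2 <- ceiling(nr / ny) * ny
  nc2 <- ceiling(nc / nx) * nx
  pxp <- px[c(seq_len(nr), rep(nr, nr2 - nr)), c(seq_len(nc), rep(nc, nc2 - nc)),
            drop = FALSE]
  outp <- t(EBImage::clahe(EBImage::Image(t(pxp)), nx = nx, ny = ny,
                           bins = 256L, limit = limit, keep.range = FALSE))
  out <- outp[seq_len(nr), seq_len(nc), drop = FALSE]
  gel_image(clip01(out), polarity = img$polarity, stage = "display",
            source = img$source)
}
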