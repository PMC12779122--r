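#' Gel image container
#'
#' A `gel_image` wraps a numeric matrix of intensities in `[0, 1]`, rows
#' running top to bottom (row 1 is the well end; electrophoretic migration
#' increases with the row index) and columns left to right, together with
#' band polarity and processing-stage metadata.
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param polarity `"bands_bright"` (bands brighter than background, the
#'   convention of UV transilluminator photographs) or `"bands_dark"`
#'   (stained-gel scans). Auto-detected by [gel_read()]; all processing after
#'   [gel_denoise()] assumes `bands_bright`.
#' @param stage Processing stage: `"raw"`, `"denoised"` or `"display"`.
#' @param source Free-text provenance string.
#'
#' @return A `gel_image` object.
#' @seealso [gel_read()], [gel_crop()], [gel_denoise()], [gel_enhance()]
#' @export
gel_image <- function(pixels,
                      polarity = c("bands_bright", "bands_dark"),
                      stage = c("raw", "denoised", "display"),
                      source = "matrix") {
  polarity <- match.arg(polarity)
  stage <- match.arg(stage)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_validation("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    abort_validation("image must have at least 2 rows and 2 columns")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    abort_validation("intensities must lie in [0, 1] with no missing values")
  }
  structure(
    list(pixels = pixels, polarity = polarity, stage = stage, source = source),
    class = "gel_image"
  )
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf(
    "<gel_image> %d x %d px, polarity=%s, stage=%s, source=%s\n",
    nrow(x$pixels), ncol(x$pixels), x$polarity, x$stage, x$source
  ))
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gel_image <- function(x, ...) x$pixels

stopifnot_stage <- function(img, stage, op) {
  if (!inherits(img, "gel_image")) {
    abort_validation(sprintf("`%s` expects a gel_image", op))
  }
  if (!identical(img$stage, stage)) {
    abort_validation(sprintf(
      "`%s` expects a %s-stage image, got stage '%s'", op, stage, img$stage
    ))
  }
  invisible(img)
}

#' Read a gel image from file
#'
#' Reads an 8- or 16-bit PNG, TIFF or JPEG image, collapses colour to
#' luminance (Rec. 601 weights, as `rgb2gray` does), rescales intensities to
#' `[0, 1]` and auto-detects band polarity: if the median pixel is darker
#' than the mean the image is mostly dark background with bright bands
#' (`bands_bright`), otherwise `bands_dark`. The polarity is recorded but not
#' applied; [gel_denoise()] normalises it.
#'
#' @param path Path to the image file.
#' @param polarity Optional override of the auto-detected polarity.
#' @return A `gel_image` at stage `"raw"`.
#' @export
gel_read <- function(path, polarity = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_input(sprintf("cannot read image: file '%s' does not exist", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      {
        im <- EBImage::readImage(path)
        aperm_ebimage(im)
      }
    ),
    error = function(e) {
      abort_input(sprintf("cannot decode image file '%s': %s", path, conditionMessage(e)))
    }
  )
  px <- collapse_luminance(arr)
  if (length(px) == 0L || nrow(px) < 2L || ncol(px) < 2L) {
    abort_validation(sprintf("image '%s' is too small to analyse", path))
  }
  px <- clip01(px)
  if (is.null(polarity)) {
    polarity <- if (stats::median(px) < mean(px)) "bands_bright" else "bands_dark"
  }
  gel_image(px, polarity = polarity, stage = "raw", source = path)
}

## EBImage stores x (width) as the first dimension; transpose back to
## row-major matrix convention.
aperm_ebimage <- function(im) {
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

collapse_luminance <- function(arr) {
  if (is.matrix(arr)) return(arr)
  d <- dim(arr)
  if (length(d) == 3L) {
    if (d[3] >= 3L) {
      0.2989 * arr[, , 1] + 0.5870 * arr[, , 2] + 0.1140 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  } else {
    abort_validation("unsupported image array layout")
  }
}

#' Write a gel image as an 8-bit grayscale PNG
#'
#' @param img A `gel_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
gel_write_png <- function(img, path) {
  if (!inherits(img, "gel_image")) abort_validation("`img` must be a gel_image")
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

#' Region of interest
#'
#' Pixel bounds of a rectangular region, 1-based and inclusive.
#'
#' @param row_start,row_stop First and last row of the region.
#' @param col_start,col_stop First and last column of the region.
#' @return A `gel_roi` object.
#' @export
gel_roi <- function(row_start, row_stop, col_start, col_stop) {
  for (v in list(row_start, row_stop, col_start, col_stop)) {
    check_scalar_number(v, "roi bound", lo = 1)
  }
  if (row_stop <= row_start) {
    abort_validation(sprintf("roi row_stop (%d) must exceed row_start (%d)",
                             row_stop, row_start))
  }
  if (col_stop <= col_start) {
    abort_validation(sprintf("roi col_stop (%d) must exceed col_start (%d)",
                             col_stop, col_start))
  }
  structure(
    list(row_start = as.integer(row_start), row_stop = as.integer(row_stop),
         col_start = as.integer(col_start), col_stop = as.integer(col_stop)),
    class = "gel_roi"
  )
}

#' Crop a gel image to a region of interest
#'
#' Returns an exact sub-block copy of the pixel matrix; stage and polarity
#' are carried over.
#'
#' @param img A `gel_image`.
#' @param roi A [gel_roi()] (or a length-4 numeric
#'   `c(row_start, row_stop, col_start, col_stop)`, 1-based inclusive).
#' @return A cropped `gel_image`.
#' @export
gel_crop <- function(img, roi) {
  if (!inherits(img, "gel_image")) abort_validation("`img` must be a gel_image")
  if (is.numeric(roi) && length(roi) == 4L) {
    roi <- gel_roi(roi[1], roi[2], roi[3], roi[4])
  }
  if (!inherits(roi, "gel_roi")) abort_validation("`roi` must be a gel_roi")
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (roi$row_stop > nr) {
    abort_validation(sprintf("roi row_stop (%d) exceeds image rows (%d)", roi$row_stop, nr))
  }
  if (roi$col_stop > nc) {
    abort_validation(sprintf("roi col_stop (%d) exceeds image columns (%d)", roi$col_stop, nc))
  }
  px <- img$pixels[roi$row_start:roi$row_stop, roi$col_start:roi$col_stop, drop = FALSE]
  gel_image(px, polarity = img$polarity, stage = img$stage,
            source = sprintf("%s [crop %d:%d, %d:%d]", img$source,
                             roi$row_start, roi$row_stop, roi$col_start, roi$col_stop))
}
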