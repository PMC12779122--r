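#' Plot a lane's size distribution
#'
#' Intensity versus base-pair size for one lane, on a log10 size axis, with
#' detected peaks marked if supplied.
#'
#' @param object A `gel_profile` (smoothed or raw).
#' @param peaks Optional `gel_peaks` tibble to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gel_profile <- function(object, peaks = NULL, ...) {
  y <- if (!is.null(object$final)) object$final else object$raw
  df <- tibble::tibble(bp = object$bp, intensity = y)
  df <- df[df$bp > 0, , drop = FALSE]  # extrapolated rows can map below 0 bp
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bp, y = .data$intensity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fragment size (bp)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(bp = peaks$peak_bp, intensity = peaks$peak_intensity),
      colour = "firebrick", shape = 17, size = 2.5
    )
  }
  p
}

#' Plot pipeline results
#'
#' `type = "pct_in_range"` draws the per-sample bar chart of the percent of
#' signal inside the target size range; `type = "profiles"` overlays all
#' sample size distributions.
#'
#' @param object A `gel_qc_run`.
#' @param type One of `"pct_in_range"`, `"profiles"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gel_qc_run <- function(object, type = c("pct_in_range", "profiles"), ...) {
  type <- match.arg(type)
  if (type == "pct_in_range") {
    tr <- object$config$target_range
    ggplot2::ggplot(object$samples,
                    ggplot2::aes(x = factor(.data$lane), y = .data$pct_in_range)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_cartesian(ylim = c(0, 100)) +
      ggplot2::labs(x = "lane",
                    y = sprintf("%% of signal in [%g, %g] bp", tr[1], tr[2])) +
      ggplot2::theme_minimal()
  } else {
    df <- purrr::map_dfr(names(object$profiles), function(nm) {
      prof <- object$profiles[[nm]]
      tibble::tibble(lane = nm, bp = prof$bp, intensity = prof$final)
    })
    df <- df[df$bp > 0, , drop = FALSE]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bp, y = .data$intensity,
                                     colour = .data$lane)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "fragment size (bp)", y = "intensity (a.u.)") +
      ggplot2::theme_minimal()
  }
}

#' Plot a gel image
#'
#' Raster view of the pixel matrix with the well end at the top.
#'
#' @param object A `gel_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gel_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(col = seq_len(ncol(px)), row = seq_len(nrow(px)))
  df$intensity <- as.vector(px)  # column-major: row varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}
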