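#' Run the full gel QC pipeline on one image
#'
#' Non-interactive batch equivalent of the guided workflow: load and crop
#' the image, denoise, detect (or override) lane boundaries, locate (or
#' override) ladder markers, build the row-to-bp calibration, then quantify
#' every non-ladder lane: smoothed intensity curve, peak calls with relative
#' areas, and percent of signal in the target size range. If `out_dir` is
#' set, per-sample profile CSVs, a QC summary table, the marker table, an
#' annotated overlay PNG, per-sample distribution plots, a percent-in-range
#' bar plot and a JSON summary are written — only after every stage has
#' succeeded, so a failed run leaves no partial output.
#'
#' @param config A named list or path to a YAML file. Recognised keys:
#'   `image` (path, or a `gel_image` when calling from R), `roi`
#'   (`c(row_start, row_stop, col_start, col_stop)`, 1-based inclusive),
#'   `k`, `ladder_index`, `ladder_bp` (descending sizes), `smoothing_factor`
#'   (`s` in `[0, 1]`, default 0.5), `smoothing_window`, `target_range`
#'   (default `c(150, 600)`), `min_peak_prominence` (default 0.05),
#'   `min_peak_distance_bp` (default 25), `min_peak_area_pct` (default 0),
#'   `marker_min_prominence`, `marker_min_distance`, `min_lane_width`,
#'   `median_size`, `wiener_size`, `polarity`, `boundaries`, `markers`,
#'   `out_dir`.
#' @param boundaries Optional manual lane boundaries (overrides config).
#' @param markers Optional manual marker rows (overrides config).
#' @return A `gel_qc_run` object; see [tidy.gel_qc_run()] and
#'   [glance.gel_qc_run()].
#' @export
gel_run <- function(config, boundaries = NULL, markers = NULL) {
  cfg <- normalise_run_config(config)
  if (!is.null(boundaries)) cfg$boundaries <- boundaries
  if (!is.null(markers)) cfg$markers <- markers

  img <- run_stage("preprocess", {
    im <- if (inherits(cfg$image, "gel_image")) cfg$image else gel_read(cfg$image, polarity = cfg$polarity)
    if (!is.null(cfg$roi)) im <- gel_crop(im, cfg$roi)
    gel_denoise(im, median_size = cfg$median_size, wiener_size = cfg$wiener_size)
  }, "check the image path and roi bounds")

  display <- run_stage("preprocess", gel_enhance(img),
                       "contrast enhancement failed")

  ls <- run_stage("lanes", {
    if (!is.null(cfg$boundaries)) {
      lane_set(cfg$boundaries, k = cfg$k, ladder_index = cfg$ladder_index,
               image_width = ncol(img$pixels))
    } else {
      gel_detect_lanes(img, k = cfg$k, ladder_index = cfg$ladder_index,
                       min_lane_width = cfg$min_lane_width)
    }
  }, "supply `boundaries` to override automatic lane detection")

  spec <- ladder_spec(cfg$ladder_bp)
  ml <- run_stage("calibrate", {
    if (!is.null(cfg$markers)) {
      new_gel_markers(cfg$markers, spec$bp_values)
    } else {
      prof <- ladder_profile(img, ls)
      detect_markers(prof, spec,
                     min_prominence = cfg$marker_min_prominence,
                     min_distance = cfg$marker_min_distance)
    }
  }, "supply `markers` to override automatic marker detection")

  cal <- run_stage("calibrate", build_calibration(ml, nrow(img$pixels)),
                   "marker rows may be degenerate")

  sample_lanes <- setdiff(seq_len(cfg$k), cfg$ladder_index)
  quant <- run_stage("quantify", {
    lapply(sample_lanes, function(lane) {
      prof <- sample_profile(img, ls, lane, cal)
      prof <- profile_smooth(prof, s = cfg$smoothing_factor,
                             window = cfg$smoothing_window)
      pks <- withCallingHandlers(
        call_peaks(prof, min_prominence = cfg$min_peak_prominence,
                   min_distance_bp = cfg$min_peak_distance_bp),
        warning = function(w) invokeRestart("muffleWarning")
      )
      pks <- peak_areas(prof, pks)
      pks <- filter_peaks(pks, cfg$min_peak_area_pct)
      pir <- pct_in_range(prof, cfg$target_range[1], cfg$target_range[2])
      list(lane = lane, profile = prof, peaks = pks, pct_in_range = pir)
    })
  }, "inspect the profiles; peak parameters may need adjustment")

  peaks_tbl <- purrr::map_dfr(quant, function(q) {
    if (nrow(q$peaks) == 0L) return(tibble::tibble())
    dplyr::mutate(tibble::as_tibble(q$peaks), lane = q$lane, .before = 1)
  })
  samples_tbl <- purrr::map_dfr(quant, function(q) {
    tibble::tibble(
      lane = q$lane,
      n_peaks = nrow(q$peaks),
      top_peak_bp = if (nrow(q$peaks)) q$peaks$peak_bp[which.max(q$peaks$relative_area_pct)] else NA_real_,
      pct_in_range = q$pct_in_range,
      flag = if (nrow(q$peaks) == 0L) "no_peaks" else ""
    )
  })

  res <- structure(
    list(samples = samples_tbl, peaks = peaks_tbl,
         markers = ml, lanes = ls, calibration = cal,
         profiles = stats::setNames(lapply(quant, `[[`, "profile"),
                                    paste0("lane", sample_lanes)),
         image = img, display = display, config = cfg),
    class = "gel_qc_run"
  )

  if (!is.null(cfg$out_dir)) export_run(res, cfg$out_dir)
  res
}

normalise_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_input(sprintf("config file '%s' does not exist", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_validation("`config` must be a list or YAML path")
  defaults <- list(
    roi = NULL, smoothing_factor = 0.5, smoothing_window = NULL,
    target_range = c(150, 600), min_peak_prominence = 0.05,
    min_peak_distance_bp = 25, min_peak_area_pct = 0,
    marker_min_prominence = 0.05, marker_min_distance = NULL,
    min_lane_width = NULL, median_size = 3L, wiener_size = 5L,
    polarity = NULL, boundaries = NULL, markers = NULL, out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  for (key in c("image", "k", "ladder_index", "ladder_bp")) {
    if (is.null(cfg[[key]])) {
      abort_validation(sprintf("config key `%s` is required", key))
    }
  }
  if (is.character(cfg$image) && !inherits(cfg$image, "gel_image") &&
      !file.exists(cfg$image)) {
    abort_input(sprintf("image file '%s' does not exist", cfg$image))
  }
  check_scalar_number(cfg$smoothing_factor, "smoothing_factor", lo = 0, hi = 1)
  if (length(cfg$target_range) != 2L || cfg$target_range[1] >= cfg$target_range[2]) {
    abort_validation("`target_range` must be c(lo, hi) with lo < hi")
  }
  if (!is.null(cfg$roi) && is.numeric(cfg$roi)) {
    cfg$roi <- gel_roi(cfg$roi[1], cfg$roi[2], cfg$roi[3], cfg$roi[4])
  }
  cfg
}

run_stage <- function(stage, expr, hint) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      if (inherits(e, "gelqc_stage_error")) rlang::cnd_signal(e)
      rlang::abort(
        sprintf("[%s] %s (%s)", stage, conditionMessage(e), hint),
        class = c("gelqc_stage_error", class(e))
      )
    }),
    message = function(m) m
  )
}

export_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$samples, file.path(out_dir, "qc_table.csv"))
  if (nrow(res$peaks)) {
    readr::write_csv(res$peaks, file.path(out_dir, "peaks.csv"))
  }
  readr::write_csv(tibble::as_tibble(res$markers), file.path(out_dir, "markers.csv"))
  readr::write_csv(tidy(res$lanes), file.path(out_dir, "lanes.csv"))
  for (nm in names(res$profiles)) {
    prof <- res$profiles[[nm]]
    readr::write_csv(
      tibble::tibble(bp = prof$bp, raw_intensity = prof$raw,
                     smoothed_intensity = prof$smoothed,
                     final_intensity = prof$final),
      file.path(out_dir, sprintf("profile_%s.csv", nm))
    )
  }
  jsonlite::write_json(
    list(samples = res$samples,
         n_lanes = res$lanes$k,
         ladder_index = res$lanes$ladder_index,
         target_range = res$config$target_range,
         smoothing_factor = res$config$smoothing_factor),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  png::writePNG(overlay_rgb(res), file.path(out_dir, "overlay.png"))
  for (nm in names(res$profiles)) {
    lane <- as.integer(sub("lane", "", nm))
    pks <- res$peaks[res$peaks$lane == lane, , drop = FALSE]
    p <- autoplot(res$profiles[[nm]], peaks = pks) +
      ggplot2::ggtitle(sprintf("Lane %d size distribution", lane))
    ggplot2::ggsave(file.path(out_dir, sprintf("plot_%s.png", nm)), p,
                    width = 6, height = 4, dpi = 120)
  }
  p <- autoplot(res, type = "pct_in_range")
  ggplot2::ggsave(file.path(out_dir, "plot_pct_in_range.png"), p,
                  width = 6, height = 4, dpi = 120)
  invisible(out_dir)
}

## annotated detection overlay: display image in gray, lane boundaries in
## red, marker rows in green across the ladder lane
overlay_rgb <- function(res) {
  px <- res$display$pixels
  arr <- array(px, dim = c(nrow(px), ncol(px), 3))
  for (b in res$lanes$boundaries) {
    arr[, b, 1] <- 1; arr[, b, 2] <- 0; arr[, b, 3] <- 0
  }
  li <- res$lanes$ladder_index
  cols <- res$lanes$left[li]:res$lanes$right[li]
  for (r in res$markers$row) {
    arr[r, cols, 1] <- 0; arr[r, cols, 2] <- 1; arr[r, cols, 3] <- 0
  }
  arr
}

#' @export
print.gel_qc_run <- function(x, ...) {
  cat(sprintf("<gel_qc_run> %d sample lanes (+ ladder), target range [%g, %g] bp\n",
              nrow(x$samples), x$config$target_range[1], x$config$target_range[2]))
  print(x$samples)
  invisible(x)
}

#' Tidy and summarise a pipeline run
#'
#' `tidy()` returns the per-peak table (one row per detected peak across all
#' sample lanes); `glance()` a one-row run summary.
#'
#' @param x A `gel_qc_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gel_qc_run <- function(x, ...) x$peaks

#' @rdname tidy.gel_qc_run
#' @export
glance.gel_qc_run <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_peaks = nrow(x$peaks),
    mean_top_peak_bp = mean(x$samples$top_peak_bp, na.rm = TRUE),
    mean_pct_in_range = mean(x$samples$pct_in_range),
    smoothing_factor = x$config$smoothing_factor
  )
}

#' Batch-process several gel images
#'
#' Runs [gel_run()] for every entry of a manifest (a YAML file whose
#' top-level is a list of run configs, or an R list of configs), logging one
#' line per image, and returns the combined per-run summaries.
#'
#' @param manifest Path to a YAML manifest or a list of configs.
#' @return A tibble with one row per run (`glance()` of each), with an `id`
#'   column.
#' @export
gel_batch <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest)) {
      abort_input(sprintf("manifest '%s' does not exist", manifest))
    }
    manifest <- yaml::read_yaml(manifest)
  }
  if (!is.list(manifest) || length(manifest) == 0L) {
    abort_validation("manifest must be a non-empty list of run configs")
  }
  purrr::map_dfr(seq_along(manifest), function(i) {
    cfg <- manifest[[i]]
    id <- if (is.character(cfg)) cfg
          else if (!is.null(cfg$image) && is.character(cfg$image)) cfg$image
          else sprintf("run%d", i)
    message(sprintf("[gelqc] run %d/%d: %s", i, length(manifest), id))
    res <- gel_run(cfg)
    dplyr::mutate(glance(res), id = id, .before = 1)
  })
}
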