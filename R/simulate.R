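#' Sample-lane content specifications for the gel simulator
#'
#' `sim_smear()` describes randomly fragmented DNA as a log-normal fragment
#' size distribution (median in bp, log standard deviation in natural-log
#' units). `sim_bands()` describes discrete fragments of known size, as in a
#' purified ladder.
#'
#' @param median_bp Median fragment size in bp.
#' @param sigma_log Standard deviation of `log(size)` (natural log).
#' @param amplitude Peak intensity of the rendered signal, in `[0, 1]`.
#' @return A lane-content spec for [gel_sim_config()].
#' @export
sim_smear <- function(median_bp = 300, sigma_log = 0.35, amplitude = 0.5) {
  check_scalar_number(median_bp, "median_bp", lo = 1)
  check_scalar_number(sigma_log, "sigma_log", lo = 1e-3)
  check_scalar_number(amplitude, "amplitude", lo = 0, hi = 1)
  list(type = "smear", median_bp = median_bp, sigma_log = sigma_log,
       amplitude = amplitude)
}

#' @rdname sim_smear
#' @param bp Vector of discrete fragment sizes in bp.
#' @export
sim_bands <- function(bp, amplitude = 0.6) {
  if (!is.numeric(bp) || length(bp) < 1L || any(bp <= 0)) {
    abort_validation("`bp` must be positive fragment sizes")
  }
  check_scalar_number(amplitude, "amplitude", lo = 0, hi = 1)
  list(type = "bands", bp = sort(as.numeric(bp), decreasing = TRUE),
       amplitude = amplitude)
}

#' Synthetic gel configuration
#'
#' Describes a vertically laned gel: geometry, the reference ladder, the
#' log-size migration law `row = migration_a + migration_b *
#' (log10(bp_max) - log10(bp))` (larger fragments migrate less and sit at
#' lower row indices), per-lane sample contents, and the corruption model
#' (additive Gaussian noise, a vertical background gradient, and dark
#' circular hole artifacts inside bright bands).
#'
#' @param image_height,image_width Image size in pixels; width defaults to
#'   what the lane layout requires plus an 8-px margin per side.
#' @param k Number of lanes (ladder included).
#' @param ladder_index Which lane (1-based) carries the ladder.
#' @param ladder_bp Descending marker sizes, a [ladder_spec()] or numeric.
#' @param migration_a Row of the largest ladder fragment.
#' @param migration_b Rows per decade of fragment size (separation
#'   coefficient); must be positive.
#' @param band_sigma Band point-spread (Gaussian sigma) in rows.
#' @param lane_width,lane_gap Lane and inter-lane widths in pixels.
#' @param lane_base Intensity step of a lane track over the background.
#' @param band_inset Lateral inset (pixels) of band/smear signal from the
#'   lane walls: wells are cast narrower than the lane pitch and diffusion
#'   does not reach the track edges, so DNA signal never touches the lane
#'   boundary columns.
#' @param samples List of per-lane content specs ([sim_smear()] /
#'   [sim_bands()] / `NULL`), length `k` (ladder entry ignored), or `NULL`
#'   for the default: every non-ladder lane a 300-bp median smear.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param background_gradient Maximum additive vertical background tilt.
#' @param hole_rate Expected number of hole artifacts per band.
#' @param seed Mandatory RNG seed; rendering is fully determined by it.
#' @return A `gel_sim_config` object.
#' @export
gel_sim_config <- function(image_height = 360L, image_width = NULL,
                           k = 9L, ladder_index = 1L,
                           ladder_bp = ladder_1kb_plus(),
                           migration_a = 20, migration_b = 140,
                           band_sigma = 2,
                           lane_width = 30L, lane_gap = 12L,
                           lane_base = 0.12, band_inset = 5L,
                           samples = NULL,
                           noise_sigma = 0.02,
                           background_gradient = 0.05,
                           hole_rate = 0,
                           seed) {
  if (missing(seed)) abort_validation("`seed` is mandatory for the simulator")
  check_scalar_number(seed, "seed")
  check_scalar_number(image_height, "image_height", lo = 32)
  check_scalar_number(k, "k", lo = 1)
  k <- as.integer(k)
  check_scalar_number(ladder_index, "ladder_index", lo = 1, hi = k)
  if (inherits(ladder_bp, "ladder_spec")) ladder_bp <- ladder_bp$bp_values
  ladder_bp <- ladder_spec(ladder_bp)$bp_values
  check_scalar_number(migration_a, "migration_a", lo = 0)
  check_scalar_number(migration_b, "migration_b", lo = 1e-9)
  check_scalar_number(band_sigma, "band_sigma", lo = 0.1)
  check_scalar_number(lane_width, "lane_width", lo = 3)
  check_scalar_number(lane_gap, "lane_gap", lo = 1)
  check_scalar_number(lane_base, "lane_base", lo = 0, hi = 0.5)
  check_scalar_number(band_inset, "band_inset", lo = 0)
  if (2 * band_inset > lane_width - 3) {
    abort_validation("`band_inset` leaves fewer than 3 signal columns per lane")
  }
  check_scalar_number(noise_sigma, "noise_sigma", lo = 0, hi = 0.5)
  check_scalar_number(background_gradient, "background_gradient", lo = 0, hi = 0.5)
  check_scalar_number(hole_rate, "hole_rate", lo = 0)
  margin <- 8L
  lane_width <- as.integer(lane_width); lane_gap <- as.integer(lane_gap)
  need <- k * lane_width + (k + 1L) * lane_gap + 2L * margin
  if (is.null(image_width)) image_width <- need
  check_scalar_number(image_width, "image_width", lo = 16)
  if (image_width < need) {
    abort_validation(sprintf(
      "image_width %d cannot hold %d lanes (need >= %d)", image_width, k, need
    ))
  }
  if (is.null(samples)) {
    samples <- lapply(seq_len(k), function(i) {
      if (i == as.integer(ladder_index)) NULL else sim_smear()
    })
  }
  if (length(samples) != k) {
    abort_validation(sprintf("`samples` must have one entry per lane (%d)", k))
  }
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         k = k, ladder_index = as.integer(ladder_index),
         ladder_bp = ladder_bp,
         migration_a = migration_a, migration_b = migration_b,
         band_sigma = band_sigma,
         lane_width = lane_width, lane_gap = lane_gap, margin = margin,
         lane_base = lane_base, band_inset = as.integer(band_inset),
         samples = samples,
         noise_sigma = noise_sigma,
         background_gradient = background_gradient,
         hole_rate = hole_rate, seed = as.integer(seed)),
    class = "gel_sim_config"
  )
}

#' Migration law of the simulator
#'
#' Fractional pixel row at which a fragment of the given size sits:
#' `row = migration_a + migration_b * (log10(bp_max) - log10(bp))`, the
#' standard log-size migration relation. Strictly increasing as `bp`
#' decreases.
#'
#' @param bp Fragment size(s), bp, positive.
#' @param cfg A `gel_sim_config`.
#' @return Fractional row(s).
#' @export
migration_row <- function(bp, cfg) {
  if (!inherits(cfg, "gel_sim_config")) {
    abort_validation("`cfg` must be a gel_sim_config")
  }
  if (!is.numeric(bp) || any(is.na(bp)) || any(bp <= 0)) {
    abort_validation("`bp` must be positive")
  }
  cfg$migration_a + cfg$migration_b * (log10(max(cfg$ladder_bp)) - log10(bp))
}

## normalise a per-lane sample entry to a list of content components:
## NULL -> empty; a single sim_smear()/sim_bands() -> length-1 list;
## a list of such specs -> itself
lane_components <- function(sp) {
  if (is.null(sp)) return(list())
  if (!is.null(sp$type)) return(list(sp))
  sp
}

## lane column layout: left edges of each lane
lane_columns <- function(cfg) {
  left <- cfg$margin + cfg$lane_gap +
    (seq_len(cfg$k) - 1L) * (cfg$lane_width + cfg$lane_gap) + 1L
  list(left = as.integer(left), right = as.integer(left + cfg$lane_width - 1L))
}

## evaluate RNG-dependent code under a local seed, restoring global state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic gel with exact ground truth
#'
#' Places `k` vertical lane tracks, draws ladder marker bands and sample
#' contents as Gaussian bands in row space at their migration rows (a
#' log-normal smear maps to a Gaussian row profile, because the migration
#' law is affine in log size), then adds a vertical background gradient,
#' dark disc hole artifacts inside bands, and Gaussian noise. Rendering is
#' fully determined by `cfg$seed`.
#'
#' @param cfg A [gel_sim_config()].
#' @return A list with `image` (a raw-stage `gel_image`, `bands_bright`)
#'   and `truth` (a `gel_truth` object: true boundaries, fractional and
#'   rounded marker rows, per-lane sample table with the analytic true peak
#'   bp, the noise-free clean render, and `mass_in(lane, lo, hi)` giving
#'   the analytic fraction of a lane's fragment mass within a bp interval).
#' @export
render_gel <- function(cfg) {
  if (!inherits(cfg, "gel_sim_config")) {
    abort_validation("`cfg` must be a gel_sim_config")
  }
  H <- cfg$image_height; W <- cfg$image_width
  cols <- lane_columns(cfg)
  rows <- seq_len(H)

  img <- matrix(0.08, H, W)
  img <- img + cfg$background_gradient * (rows - 1) / (H - 1)

  band_profile <- function(center, sigma, amplitude) {
    amplitude * exp(-(rows - center)^2 / (2 * sigma^2))
  }

  lane_profiles <- vector("list", cfg$k)
  band_centers <- vector("list", cfg$k)
  marker_rows <- migration_row(cfg$ladder_bp, cfg)
  sample_rows <- vector("list", cfg$k)

  for (i in seq_len(cfg$k)) {
    prof <- rep(0, H)
    centers <- numeric(0)
    spreads <- numeric(0)
    if (i == cfg$ladder_index) {
      for (ctr in marker_rows) {
        prof <- prof + band_profile(ctr, cfg$band_sigma, 0.6)
      }
      centers <- marker_rows
      spreads <- rep(cfg$band_sigma, length(marker_rows))
    } else {
      for (sp in lane_components(cfg$samples[[i]])) {
        if (sp$type == "bands") {
          ctrs <- migration_row(sp$bp, cfg)
          for (ctr in ctrs) {
            prof <- prof + band_profile(ctr, cfg$band_sigma, sp$amplitude)
          }
          centers <- c(centers, ctrs)
          spreads <- c(spreads, rep(cfg$band_sigma, length(ctrs)))
        } else {
          m <- migration_row(sp$median_bp, cfg)
          s_row <- cfg$migration_b * sp$sigma_log / log(10)
          s_eff <- sqrt(s_row^2 + cfg$band_sigma^2)
          prof <- prof + band_profile(m, s_eff, sp$amplitude)
          centers <- c(centers, m)
          spreads <- c(spreads, s_eff)
        }
      }
    }
    band_centers[[i]] <- centers
    sample_rows[[i]] <- spreads
    lane_cols <- cols$left[i]:cols$right[i]
    core_cols <- (cols$left[i] + cfg$band_inset):(cols$right[i] - cfg$band_inset)
    img[, lane_cols] <- img[, lane_cols] + cfg$lane_base
    img[, core_cols] <- img[, core_cols] + prof
    ## expected lane-mean signal above the track base
    lane_profiles[[i]] <- prof * length(core_cols) / length(lane_cols)
  }

  clean <- clip01(img)

  noisy <- with_local_seed(cfg$seed, {
    out <- img
    if (cfg$hole_rate > 0) {
      for (i in seq_len(cfg$k)) {
        ctrs <- band_centers[[i]]
        sprd <- sample_rows[[i]]
        if (length(ctrs) == 0) next
        for (j in seq_along(ctrs)) {
          nh <- stats::rpois(1, cfg$hole_rate)
          if (nh == 0) next
          for (h in seq_len(nh)) {
            hr <- round(ctrs[j] + stats::runif(1, -sprd[j], sprd[j]))
            hc <- sample((cols$left[i] + cfg$band_inset + 1L):
                           (cols$right[i] - cfg$band_inset - 1L), 1)
            rad <- sample(1:2, 1)
            rr <- max(1, hr - rad):min(H, hr + rad)
            cc <- max(1, hc - rad):min(W, hc + rad)
            disc <- outer(rr - hr, cc - hc, function(a, b) a^2 + b^2 <= rad^2)
            blk <- out[rr, cc, drop = FALSE]
            blk[disc] <- 0.08
            out[rr, cc] <- blk
          }
        }
      }
    }
    if (cfg$noise_sigma > 0) {
      out <- out + matrix(stats::rnorm(H * W, 0, cfg$noise_sigma), H, W)
    }
    out
  })

  boundaries <- as.integer(rbind(cols$left, cols$right))
  samples_tbl <- purrr::map_dfr(seq_len(cfg$k), function(i) {
    comps <- lane_components(cfg$samples[[i]])
    if (i == cfg$ladder_index) {
      tibble::tibble(lane = i, type = "ladder", median_bp = NA_real_,
                     sigma_log = NA_real_,
                     true_peak_bp = list(cfg$ladder_bp))
    } else if (length(comps) == 0L) {
      tibble::tibble(lane = i, type = "empty", median_bp = NA_real_,
                     sigma_log = NA_real_, true_peak_bp = list(numeric(0)))
    } else {
      ## the pushed-forward row profile of a log-normal smear peaks at the
      ## row of its median, so the median is the true peak bp of a smear
      peaks <- unlist(lapply(comps, function(sp) {
        if (sp$type == "bands") sp$bp else sp$median_bp
      }))
      one <- if (length(comps) == 1L) comps[[1]] else NULL
      tibble::tibble(
        lane = i,
        type = if (length(comps) > 1L) "mixed" else one$type,
        median_bp = if (!is.null(one) && one$type == "smear") one$median_bp else NA_real_,
        sigma_log = if (!is.null(one) && one$type == "smear") one$sigma_log else NA_real_,
        true_peak_bp = list(sort(peaks, decreasing = TRUE))
      )
    }
  })

  cfg_local <- cfg
  ## Analytic fraction of a lane's signal in [lo, hi] bp.
  ## axis = "row": fraction of fragment mass (plain log-normal CDF mass; the
  ##   rendered row profile is the pushforward density over migration rows).
  ## axis = "bp": what trapezoidal integration of that same row profile over
  ##   the calibrated bp axis reports. Re-parametrising the row-Gaussian in
  ##   ln(bp) drops the 1/bp Jacobian, so the bp-axis integrand is the
  ##   kernel of LN(mu + sigma^2, sigma): the size-biased log-normal CDF
  ##   mass in closed form.
  mass_in <- function(lane, lo, hi, axis = c("bp", "row")) {
    axis <- match.arg(axis)
    comps <- lane_components(cfg_local$samples[[lane]])
    if (lane == cfg_local$ladder_index) {
      comps <- list(list(type = "bands", bp = cfg_local$ladder_bp))
    }
    if (length(comps) != 1L) return(NA_real_)  # analytic mass: single-component lanes
    sp <- comps[[1]]
    if (sp$type == "smear") {
      ## rendered row profile includes the band point-spread: in ln(bp)
      ## units it adds (band_sigma * ln10 / migration_b)^2 in quadrature
      sig <- sqrt(sp$sigma_log^2 +
                    (cfg_local$band_sigma * log(10) / cfg_local$migration_b)^2)
      mu <- log(sp$median_bp)
      if (axis == "bp") mu <- mu + sig^2
      stats::plnorm(hi, mu, sig) - stats::plnorm(lo, mu, sig)
    } else {
      w <- if (axis == "bp") sp$bp else rep(1, length(sp$bp))
      sum(w[sp$bp >= lo & sp$bp <= hi]) / sum(w)
    }
  }

  truth <- structure(
    list(boundaries = boundaries,
         lanes = tibble::tibble(lane = seq_len(cfg$k), left = cols$left,
                                right = cols$right,
                                is_ladder = seq_len(cfg$k) == cfg$ladder_index),
         marker_rows = marker_rows,
         marker_rows_px = as.integer(round(marker_rows)),
         ladder_bp = cfg$ladder_bp,
         samples = samples_tbl,
         lane_profiles = lane_profiles,
         clean = clean,
         mass_in = mass_in,
         cfg = cfg),
    class = "gel_truth"
  )

  list(
    image = gel_image(clip01(noisy), polarity = "bands_bright", stage = "raw",
                      source = sprintf("simulated gel (seed %d)", cfg$seed)),
    truth = truth
  )
}

#' Agarose-percentage stress scenarios
#'
#' Phenomenological configurations emulating how gel density changes band
#' separation: the usable separation window for this broad-range ladder is
#' widest near 1.0% agarose, and moving away from it shrinks the rows-per-
#' decade separation coefficient while the band point-spread grows. At low
#' percentages closely spaced sub-kilobase bands merge first; at high
#' percentages the compression costs the multi-kilobase bands their
#' resolution. This is a documented stress fixture, not a physical model of
#' electrophoresis.
#'
#' @param pct Agarose percentage in `[0.5, 2.0]`.
#' @param seed Seed passed to [gel_sim_config()].
#' @param ... Further overrides passed to [gel_sim_config()].
#' @return A `gel_sim_config`.
#' @export
agarose_scenario <- function(pct, seed, ...) {
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) ||
      pct < 0.5 || pct > 2.0) {
    abort_validation(sprintf("`pct` must be in [0.5, 2.0], got %s", pct))
  }
  sep <- 1 - 0.55 * abs(pct - 1)
  b <- 140 * sep
  sigma <- 2 * (1 + 1.6 * abs(pct - 1))
  gel_sim_config(migration_b = b, band_sigma = sigma, seed = seed, ...)
}
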