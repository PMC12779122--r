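test_that("migration law is log-linear and strictly monotone", {
  cfg <- gel_sim_config(seed = 1)
  bpmax <- max(cfg$ladder_bp)
  expect_equal(migration_row(bpmax, cfg), cfg$migration_a)
  expect_equal(migration_row(bpmax / 10, cfg), cfg$migration_a + cfg$migration_b)

  bps <- sort(10^runif(50, 1.5, 4.3))
  rows <- migration_row(bps, cfg)
  expect_true(all(diff(rows) < 0))  # larger fragments migrate less

  expect_error(migration_row(0, cfg), class = "gelqc_error_validation")
  expect_error(migration_row(-10, cfg), class = "gelqc_error_validation")
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- gel_sim_config(seed = 99, hole_rate = 0.5)
  a <- render_gel(cfg)
  b <- render_gel(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$boundaries, b$truth$boundaries)
  # and the global RNG stream is left untouched
  set.seed(1); x1 <- runif(1)
  invisible(render_gel(cfg))
  set.seed(1); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("noise-free bands sit exactly at their migration rows", {
  cfg <- gel_sim_config(seed = 3, k = 3, noise_sigma = 0, background_gradient = 0,
                        samples = list(NULL, sim_bands(1000), sim_bands(250)))
  sim <- render_gel(cfg)
  px <- sim$image$pixels
  for (spec in list(list(lane = 2, bp = 1000), list(lane = 3, bp = 250))) {
    cols <- sim$truth$lanes$left[spec$lane]:sim$truth$lanes$right[spec$lane]
    profile <- rowMeans(px[, cols])
    expect_equal(which.max(profile), round(migration_row(spec$bp, cfg)))
  }
  # ladder: local maxima exactly at rounded marker rows
  lcols <- sim$truth$lanes$left[1]:sim$truth$lanes$right[1]
  lprof <- rowMeans(px[, lcols])
  pk <- gelqc:::local_peaks(lprof)
  expect_true(all(sim$truth$marker_rows_px %in% pk$idx))
})

test_that("a log-normal smear renders as its pushed-forward row density", {
  cfg <- gel_sim_config(seed = 4, noise_sigma = 0, background_gradient = 0)
  sim <- render_gel(cfg)
  sp <- cfg$samples[[2]]
  rows <- seq_len(cfg$image_height)
  m <- migration_row(sp$median_bp, cfg)
  s_row <- cfg$migration_b * sp$sigma_log / log(10)
  s_eff <- sqrt(s_row^2 + cfg$band_sigma^2)
  # lane-mean amplitude: band signal spans the lane minus the lateral inset
  core_frac <- (cfg$lane_width - 2 * cfg$band_inset) / cfg$lane_width
  analytic <- core_frac * sp$amplitude * exp(-(rows - m)^2 / (2 * s_eff^2))
  cols <- sim$truth$lanes$left[2]:sim$truth$lanes$right[2]
  rendered <- rowMeans(sim$image$pixels[, cols]) - cfg$lane_base - 0.08
  expect_lt(sqrt(sum((rendered - analytic)^2) / sum(analytic^2)), 0.01)
})

test_that("analytic interval masses match numerical integration of the render", {
  cfg <- gel_sim_config(seed = 6, noise_sigma = 0, background_gradient = 0)
  sim <- render_gel(cfg)
  prof <- sim$truth$lane_profiles[[2]]
  rows <- seq_along(prof)
  lo <- 150; hi <- 600
  r_hi <- migration_row(lo, cfg); r_lo <- migration_row(hi, cfg)
  inside <- rows >= r_lo & rows <= r_hi
  frac_row <- sum(prof[inside]) / sum(prof)
  expect_lt(abs(frac_row - sim$truth$mass_in(2, lo, hi, axis = "row")), 0.01)

  # bp-axis mass: weight each row by the bp width it spans under the log law
  bp_of_row <- 10^(log10(max(cfg$ladder_bp)) - (rows - cfg$migration_a) / cfg$migration_b)
  w <- abs(c(diff(bp_of_row), 0))
  frac_bp <- sum((prof * w)[inside]) / sum(prof * w)
  expect_lt(abs(frac_bp - sim$truth$mass_in(2, lo, hi, axis = "bp")), 0.01)
})

test_that("hole artifacts appear inside bands and denoising fills them", {
  cfg <- gel_sim_config(seed = 7, k = 3, hole_rate = 2, noise_sigma = 0,
                        samples = list(NULL, sim_bands(c(3000, 500)), sim_smear()))
  sim <- render_gel(cfg)
  clean <- sim$truth$clean
  holes <- which(sim$image$pixels < clean - 0.2)
  expect_gt(length(holes), 0)
  den <- gel_denoise(sim$image)
  expect_gt(mean(den$pixels[holes]), mean(sim$image$pixels[holes]))
})

test_that("agarose scenarios compress the expected size ranges", {
  mk <- function(pct) agarose_scenario(pct, seed = 1)
  spacing <- function(cfg, bp1, bp2) {
    abs(migration_row(bp2, cfg) - migration_row(bp1, cfg))
  }
  # low percentage: sub-kilobase separation shrinks
  expect_lt(spacing(mk(0.5), 100, 500), spacing(mk(1.0), 100, 500))
  # high percentage: multi-kilobase separation shrinks
  expect_lt(spacing(mk(2.0), 2000, 10000), spacing(mk(1.0), 2000, 10000))
  expect_error(agarose_scenario(0.4, seed = 1), class = "gelqc_error_validation")
  expect_error(agarose_scenario(2.5, seed = 1), class = "gelqc_error_validation")
})

test_that("simulator configuration is validated", {
  expect_error(gel_sim_config(), "seed")
  expect_error(gel_sim_config(seed = 1, migration_b = -5),
               class = "gelqc_error_validation")
  expect_error(gel_sim_config(seed = 1, k = 9, image_width = 100),
               class = "gelqc_error_validation")
  expect_error(gel_sim_config(seed = 1, samples = list(NULL, sim_smear())),
               class = "gelqc_error_validation")
  expect_error(sim_bands(c(100, -5)), class = "gelqc_error_validation")
})
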