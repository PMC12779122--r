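test_that("sample profiles average lane columns and record the baseline", {
  ml <- gel_markers(c(10, 40), c(1000, 100))
  cal <- build_calibration(ml, 50)
  ls <- lane_set(c(2, 6, 10, 14), 2, 1, image_width = 20)

  const <- as_denoised(matrix(0.25, 50, 20))
  prof <- sample_profile(const, ls, 2, cal)
  expect_true(all(prof$raw == 0.25))
  expect_equal(attr(prof, "baseline"), 0.25)
  expect_equal(prof$bp, cal$bp)

  # single bright band: argmax at band centre
  px <- matrix(0.1, 50, 20)
  px[24:26, 10:14] <- matrix(rep(c(0.5, 0.9, 0.5), 5), 3)
  prof2 <- sample_profile(as_denoised(px), ls, 2, cal)
  expect_lte(abs(which.max(prof2$raw) - 25), 1)

  expect_error(sample_profile(const, ls, 3, cal), class = "gelqc_error_validation")
})

test_that("smear profiles track the noise-free ground truth", {
  cfg <- gel_sim_config(seed = 51, background_gradient = 0)
  sim <- render_gel(cfg)
  img <- gel_denoise(sim$image)
  ls <- override_lanes(gel_detect_lanes(img, 9, 1), sim$truth$boundaries)
  cal <- truth_calibration(sim)
  prof <- suppressWarnings(sample_profile(img, ls, 3, cal))
  expect_gt(stats::cor(prof$raw, sim$truth$lane_profiles[[3]]), 0.95)
})

test_that("smoothing blend follows final = s * smooth + (1 - s) * raw exactly", {
  set.seed(5)
  prof <- as_gel_profile(bp = seq(2000, 100, by = -10), raw = runif(191))

  s0 <- profile_smooth(prof, s = 0)
  expect_identical(s0$final, s0$raw)

  s1 <- profile_smooth(prof, s = 1)
  expect_identical(s1$final, s1$smoothed)

  # affine in s: s = 0.5 equals the mean of the endpoints
  s05 <- profile_smooth(prof, s = 0.5)
  expect_equal(s05$final, (s0$final + s1$final) / 2, tolerance = 1e-12)

  # constants are preserved for any s
  cprof <- profile_smooth(as_gel_profile(seq(500, 100, by = -2), rep(0.3, 201)),
                          s = 0.7)
  expect_equal(cprof$final, rep(0.3, 201), tolerance = 1e-12)
  expect_equal(cprof$smoothed, rep(0.3, 201), tolerance = 1e-12)

  expect_error(profile_smooth(prof, s = 1.2), class = "gelqc_error_validation")
  expect_error(profile_smooth(prof, s = -0.1), class = "gelqc_error_validation")
})

test_that("peak calling finds constructed maxima and warns on flat curves", {
  bp <- seq(600, 100, by = -2)
  y <- pmax(0, 1 - abs(bp - 300) / 50)          # triangle centred at 300 bp
  prof <- profile_smooth(as_gel_profile(bp, y), s = 0)
  pk <- call_peaks(prof)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_bp, 300)

  flat <- profile_smooth(as_gel_profile(bp, rep(0.2, length(bp))), s = 0)
  expect_warning(pk0 <- call_peaks(flat), "flat")
  expect_equal(nrow(pk0), 0L)

  # two well-separated smears on a simulated gel recovered within 5%
  cfg <- gel_sim_config(seed = 52, k = 3,
    samples = list(NULL, list(sim_smear(300, 0.2), sim_smear(1500, 0.2)), sim_smear()))
  sim <- render_gel(cfg)
  img <- gel_denoise(sim$image)
  ls <- override_lanes(gel_detect_lanes(img, 3, 1), sim$truth$boundaries)
  q <- quantify_lane(img, ls, 2, truth_calibration(sim))
  expect_equal(nrow(q$peaks), 2L)
  got <- sort(q$peaks$peak_bp)
  expect_lt(abs(got[1] - 300) / 300, 0.05)
  expect_lt(abs(got[2] - 1500) / 1500, 0.05)
})

test_that("relative peak areas partition the curve and match Gaussian oracles", {
  gauss_profile <- function(amps, centers, sigma = 30) {
    bp <- seq(1, 1000, by = 1)
    y <- rep(0, length(bp))
    for (i in seq_along(amps)) {
      y <- y + amps[i] * exp(-(bp - centers[i])^2 / (2 * sigma^2))
    }
    profile_smooth(as_gel_profile(rev(bp), rev(y), baseline = 0), s = 0)
  }

  # single peak, zero baseline: exactly 100%
  p1 <- gauss_profile(1, 500)
  a1 <- peak_areas(p1, call_peaks(p1))
  expect_identical(a1$relative_area_pct, 100)

  # equal bumps: 50/50 within 1 pp; 2:1 within 1.5 pp; 9:1 within 1.5 pp
  for (case in list(c(1, 1, 50), c(2, 1, 66.667), c(9, 1, 90))) {
    p <- gauss_profile(case[1:2], c(250, 750))
    a <- peak_areas(p, call_peaks(p))
    expect_equal(nrow(a), 2L)
    tol <- if (case[1] == 1) 1 else 1.5
    expect_lt(abs(sort(a$relative_area_pct, decreasing = TRUE)[1] - case[3]), tol)
    expect_equal(sum(a$relative_area_pct), 100, tolerance = 1e-9)
    # bounds bracket each peak on the bp axis
    expect_true(all(a$left_bound_bp <= a$peak_bp & a$peak_bp <= a$right_bound_bp))
  }
})

test_that("percent-in-range integrates over the bp axis with endpoint handling", {
  # uniform block over [100, 600] bp, zero elsewhere
  bp <- seq(50, 650, by = 5)
  y <- as.numeric(bp >= 100 & bp <= 600)
  prof <- profile_smooth(as_gel_profile(rev(bp), rev(y)), s = 0)
  expect_equal(pct_in_range(prof, 50, 650), 100)
  expect_lt(abs(pct_in_range(prof, 100, 350) - 50), 1)

  # widening the range can only increase the percentage
  p <- pct_in_range(prof, 200, 300)
  for (w in c(50, 100, 200)) {
    p2 <- pct_in_range(prof, 200 - w, 300 + w)
    expect_gte(p2, p)
    p <- p2
  }

  # exact for piecewise-linear integrands: triangle on [100, 500]
  bp2 <- seq(100, 500, by = 4)
  tri <- pmax(0, 1 - abs(bp2 - 300) / 200)
  ptri <- profile_smooth(as_gel_profile(rev(bp2), rev(tri)), s = 0)
  # mass of the left half of a symmetric triangle is exactly 50%
  expect_equal(pct_in_range(ptri, 100, 300), 50, tolerance = 1e-9)

  expect_warning(out <- pct_in_range(prof, 2000, 3000), "outside")
  expect_equal(out, 0)
  expect_error(pct_in_range(prof, 300, 200), class = "gelqc_error_validation")
})

test_that("percent error is the absolute relative deviation in percent", {
  expect_equal(percent_error(110, 100), 10)
  expect_equal(percent_error(90, 100), 10)
  expect_equal(percent_error(250, 250), 0)
  expect_equal(percent_error(c(110, 90), c(100, 100)), c(10, 10))
  expect_error(percent_error(100, 0), class = "gelqc_error_validation")
})

test_that("low-area noise peaks can be filtered by area threshold", {
  bp <- seq(1, 1000, by = 1)
  y <- exp(-(bp - 300)^2 / (2 * 30^2)) + 0.03 * exp(-(bp - 800)^2 / (2 * 10^2))
  prof <- profile_smooth(as_gel_profile(rev(bp), rev(y), baseline = 0), s = 0)
  pk <- peak_areas(prof, call_peaks(prof, min_prominence = 0.01))
  expect_equal(nrow(pk), 2L)
  kept <- filter_peaks(pk, min_area_pct = 5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$peak_bp, 300)
  expect_identical(filter_peaks(pk, 0), pk)
})
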