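test_that("images load with luminance collapse, [0,1] rescale and polarity detection", {
  # constant mid-gray image survives unchanged
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 64, 64), p)
  img <- gel_read(p)
  expect_s3_class(img, "gel_image")
  expect_equal(img$stage, "raw")
  expect_true(all(abs(img$pixels - 0.5) <= 1 / 255))
  expect_equal(diff(range(img$pixels)), 0)

  # 8-bit endpoints map to exactly 0 and 1
  m <- matrix(0, 16, 16); m[, 9:16] <- 1
  png::writePNG(m, p)
  img2 <- gel_read(p)
  expect_setequal(unique(as.vector(img2$pixels)), c(0, 1))

  # RGB collapses to one channel
  arr <- array(0.25, dim = c(16, 16, 3))
  png::writePNG(arr, p)
  expect_equal(dim(gel_read(p)$pixels), c(16L, 16L))

  # polarity: mostly-dark image with a few bright pixels -> bands_bright
  d <- matrix(0.1, 32, 32); d[10:12, ] <- 0.9
  png::writePNG(d, p)
  expect_equal(gel_read(p)$polarity, "bands_bright")
  expect_equal(gel_read(p, polarity = "bands_dark")$polarity, "bands_dark")

  expect_error(gel_read(file.path(tempdir(), "no-such-file.png")),
               class = "gelqc_error_input")
})

test_that("a simulated gel round-trips through 8-bit PNG within quantisation", {
  sim <- render_gel(gel_sim_config(seed = 31))
  p <- withr::local_tempfile(fileext = ".png")
  gel_write_png(sim$image, p)
  back <- gel_read(p)
  expect_lte(max(abs(back$pixels - sim$image$pixels)), 1 / 255 + 1e-12)
})

test_that("cropping returns exact sub-blocks and validates bounds", {
  px <- matrix(runif(40 * 50), 40, 50)
  img <- gel_image(px, "bands_bright", "raw", "fixture")

  full <- gel_crop(img, gel_roi(1, 40, 1, 50))
  expect_identical(full$pixels, px)

  const <- gel_image(matrix(0.3, 40, 50), "bands_bright", "raw", "fixture")
  small <- gel_crop(const, gel_roi(5, 14, 7, 16))
  expect_equal(dim(small$pixels), c(10L, 10L))
  expect_true(all(small$pixels == 0.3))

  # crop of a simulated gel equals the matching slice of the render
  sim <- render_gel(gel_sim_config(seed = 8))
  l <- sim$truth$lanes$left[2]; r <- sim$truth$lanes$right[2]
  cr <- gel_crop(sim$image, gel_roi(50, 150, l, r))
  expect_identical(cr$pixels, sim$image$pixels[50:150, l:r])

  expect_error(gel_crop(img, gel_roi(1, 41, 1, 10)), "row_stop",
               class = "gelqc_error_validation")
  expect_error(gel_crop(img, gel_roi(1, 10, 1, 51)), "col_stop",
               class = "gelqc_error_validation")
  expect_error(gel_roi(10, 5, 1, 10), class = "gelqc_error_validation")
})

test_that("denoising preserves constants, fills holes, and reduces noise", {
  const <- gel_image(matrix(0.4, 32, 32), "bands_bright", "raw", "fixture")
  out <- gel_denoise(const)
  expect_equal(out$stage, "denoised")
  expect_true(all(abs(out$pixels - 0.4) < 1e-12))

  # dark interior hole inside a bright band is raised to near band level
  px <- matrix(0.1, 40, 40)
  px[11:30, 5:36] <- 0.8              # bright 20-px band
  px[20:21, 20:21] <- 0.1             # 2-px hole
  den <- gel_denoise(gel_image(px, "bands_bright", "raw", "fixture"))
  expect_true(all(den$pixels[20:21, 20:21] >= 0.9 * 0.8))

  # noisy simulated gel gets strictly closer to the clean render
  cfg <- gel_sim_config(seed = 13, noise_sigma = 0.05)
  sim <- render_gel(cfg)
  den <- gel_denoise(sim$image)
  expect_lt(rms(den$pixels, sim$truth$clean),
            rms(sim$image$pixels, sim$truth$clean))

  expect_error(gel_denoise(sim$image, median_size = 4),
               class = "gelqc_error_validation")
  expect_error(gel_denoise(sim$image, wiener_size = 2),
               class = "gelqc_error_validation")
})

test_that("denoising normalises polarity and maps [0,1] into [0,1]", {
  # dark bands on bright background get inverted to bright bands
  px <- matrix(0.9, 40, 40)
  px[15:25, 10:30] <- 0.2
  den <- gel_denoise(gel_image(px, "bands_dark", "raw", "fixture"))
  expect_equal(den$polarity, "bands_bright")
  expect_gt(mean(den$pixels[15:25, 10:30]), mean(den$pixels[1:10, 1:40]))

  # an already-bright image is not re-inverted
  den2 <- gel_denoise(gel_image(1 - px, "bands_bright", "raw", "fixture"))
  expect_gt(mean(den2$pixels[15:25, 10:30]), mean(den2$pixels[1:10, 1:40]))

  expect_true(all(den$pixels >= 0 & den$pixels <= 1))
})

test_that("hole filling never decreases a bright-band image", {
  set.seed(91)
  px <- matrix(runif(30 * 30), 30, 30)
  filled <- fill_holes(px)
  expect_true(all(filled >= px - 1e-12))
  # constant image is a fixed point
  expect_equal(fill_holes(matrix(0.6, 20, 20)), matrix(0.6, 20, 20))
})

test_that("contrast enhancement is display-only and expands low contrast", {
  const <- as_denoised(matrix(0.5, 64, 64))
  expect_equal(gel_enhance(const)$pixels, const$pixels)
  expect_equal(gel_enhance(const)$stage, "display")

  # two-level low-contrast image gains dynamic range
  px <- matrix(0.45, 64, 64)
  px[, 33:64] <- 0.55
  enh <- gel_enhance(as_denoised(px))
  expect_gt(diff(range(enh$pixels)), diff(range(px)))

  expect_error(gel_enhance(as_denoised(px), clip_limit = 0),
               class = "gelqc_error_validation")
  expect_error(gel_enhance(as_denoised(px), clip_limit = 1.5),
               class = "gelqc_error_validation")

  # quantification never touches the display image: results from the
  # denoised image are identical whether or not enhancement ran
  sd <- sim_denoised(3)
  ls <- gel_detect_lanes(sd$img, 9, 1)
  cal <- truth_calibration(sd$sim)
  before <- quantify_lane(sd$img, ls, 2, cal)
  invisible(gel_enhance(sd$img))
  after <- quantify_lane(sd$img, ls, 2, cal)
  expect_identical(before$peaks, after$peaks)
})
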