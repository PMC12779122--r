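# Shared fixtures: everything is generated in code at test time.

# a gel_image already at the denoised stage, for feeding detection stages
as_denoised <- function(px) {
  gel_image(px, polarity = "bands_bright", stage = "denoised", source = "fixture")
}

# render + denoise in one step
sim_denoised <- function(seed, ...) {
  sim <- render_gel(gel_sim_config(seed = seed, ...))
  list(sim = sim, img = gel_denoise(sim$image))
}

# build a calibration straight from simulator truth (bypasses detection)
truth_calibration <- function(sim) {
  ml <- gel_markers(sim$truth$marker_rows_px, sim$truth$ladder_bp)
  build_calibration(ml, nrow(as.matrix(sim$image)))
}

# quantify one lane of a denoised simulated gel
quantify_lane <- function(img, ls, lane, cal, s = 0.5, ...) {
  prof <- suppressWarnings(sample_profile(img, ls, lane, cal))
  prof <- profile_smooth(prof, s = s)
  pks <- suppressWarnings(call_peaks(prof, ...))
  list(profile = prof, peaks = peak_areas(prof, pks))
}

# dense calibration ladder: 1/16-decade knots over 75 bp - 10 kb, chosen so
# the piecewise-linear chord error (<= (ln10 * 1/16)^2 / 8 ~ 0.26% of bp)
# is negligible against the oracle tolerances
dense_ladder <- function() round(10000 * 10^(-seq(0, 2.125, by = 1 / 16)))

rms <- function(a, b) sqrt(mean((a - b)^2))
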