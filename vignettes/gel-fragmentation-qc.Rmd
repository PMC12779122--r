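---
title: "Gel densitometry for DNA fragmentation QC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gel densitometry for DNA fragmentation QC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelqc)
```

## The problem

Random fragmentation of genomic DNA is the first step of most NGS library
preparations, and its quality control question is always the same: *what is
the fragment size distribution of each sample, and how much of it lies in
the target window?* Capillary platforms answer this per sample at
considerable cost; a conventional agarose gel answers it for dozens of
samples at once — but only if the image can be quantified. Fragmented DNA
runs as a continuous *smear*, not a discrete band, so "read the band size
off the ladder" does not work: the whole lane profile has to be calibrated
and integrated.

`gelqc` implements that pipeline: denoise the gel image, find the lane
boundaries, calibrate pixel rows to base pairs from a user-specified
ladder, and reduce every sample lane to a bp-indexed intensity curve from
which peak sizes, relative peak areas, and the percent of signal inside a
target size range are computed. A synthetic gel simulator with exact
ground truth makes every stage testable without any real gel image.

## Image model and preprocessing

A gel image is a matrix of intensities in $[0,1]$; row 1 is the well end
and migration increases with row index. Both camera polarities occur in
practice (bright bands on dark background from UV transillumination, dark
bands from stained scans); polarity is auto-detected at load time — if the
median pixel is darker than the mean, the image is mostly background with
a bright minority, i.e. bands-bright — and can be overridden. After
`gel_denoise()` everything downstream assumes bright bands.

The denoising chain is, in order:

1. **Hole filling** by grayscale morphological reconstruction: regional
   minima not connected to the border (dust, bubbles inside bands) are
   raised to their surroundings. Reconstruction-by-dilation runs in
   compiled code (raster scans plus a FIFO queue). On a bands-bright
   image this never decreases any pixel.
2. **Median filter**, default $3\times3$: impulse noise removal that
   preserves step edges. The default size uses an exact vectorised
   9-element sorting network; larger windows use EBImage.
3. **Adaptive local-Wiener filter**, default $5\times5$: local mean and
   variance are estimated per window, the noise power is taken as the
   mean local variance, and smoothing is inversely proportional to local
   variance — flat regions collapse toward their mean while edges pass
   through.

All three operators map $[0,1]$ into $[0,1]$ and preserve constant
images exactly; those invariants are tested. Contrast-limited adaptive
histogram equalisation (`gel_enhance()`) exists **for display only** —
overlays and visual confirmation. Quantification always reads the
denoised image, and a test asserts bit-identical results whether or not
enhancement ran.

Filter window sizes are not prescribed by the underlying method; the
defaults (3 and 5) are the conventional defaults for these filters and
are exposed in the run configuration.

## Lane detection

Lanes are assumed vertical. Detection is a two-stage edge analysis:

1. a Canny edge map of the denoised image (Gaussian blur $\sigma = 1$,
   Sobel gradients, non-maximum suppression along the quantised gradient
   direction, hysteresis);
2. a vertical-edge-selective Sobel pass over that binary map, summed per
   column, so columns traversed by long vertical edge runs score highest.

The `2k` highest-scoring columns are selected under non-maximum
suppression (no two selections closer than `min_lane_width`, default
`image_width / (4k)`), sorted, and paired consecutively into `k` lanes.
Two details matter in practice:

* **Hysteresis thresholds.** Gel gradients form three populations —
  background noise, faint full-height lane-track borders, and strong band
  sides. A two-class split such as Otsu's lands between the last two and
  discards the faint lane borders entirely. The high threshold therefore
  uses the classic cumulative-histogram rule (the 64-bin edge below which
  70% of pixels fall), with `low = 0.4 * high`; both are overridable.
* **Sub-column localisation.** A 1-px edge line excites the vertical
  Sobel on its two flanking columns; maxima are picked on a lightly
  smoothed score and each boundary is re-centred at the local score
  centroid. A step edge lives between two pixel columns, so boundary
  positions are accurate to about one column.

Detected lane widths are finally checked for consistency: lanes in a gel
have roughly constant width, so if the detected widths spread by more
than half their median the requested `k` probably does not match the
image, and detection fails with an instruction to supply boundaries
manually. `override_lanes()` (and the `boundaries` config key) is the
programmatic replacement for interactive adjustment; overridden
boundaries are re-validated against all lane-set invariants.

## Ladder calibration

The ladder lane is averaged across its columns and min–max normalised;
each local maximum of that profile is one marker band. Peaks are accepted
by prominence (default 0.05 of the normalised range) and separation
(default one third of the profile length per marker); surplus peaks are
resolved by keeping the most prominent, with ties broken toward the lower
row. Markers match ladder sizes by row order — topmost peak, largest
fragment. Fewer peaks than markers is a hard calibration failure that
names both counts and points to `override_markers()`.

The row→bp map interpolates **linearly in bp against pixel row** between
marker knots. Migration physics is log-linear in size, so the linear
chord deliberately over-estimates bp between knots; we keep the linear
form because it is the method's defined behaviour, and we quantify the
cost instead of hiding it. For a knot gap of $\Delta$ decades the chord
exceeds the log-law curve by at most

$$\frac{1 + 10^\Delta}{2\,\cdot 10^{\Delta/2}} - 1 \approx \frac{(\ln 10 \cdot \Delta)^2}{8},$$

about 1% of bp for a $1/8$-decade gap and 0.26% for $1/16$ decade. A
property test verifies the implementation stays inside this bound on
simulated gels. Rows above the first or below the last knot are linearly
extrapolated from the two nearest knots and flagged; downstream profile
extraction warns when more than 5% of a lane's signal mass falls on
extrapolated rows.

## Quantification

Each sample lane is averaged across its columns (`sample_profile()`),
labelled with bp per row from the calibration, and smoothed by the blend

$$I = s\,I_{\text{smooth}} + (1 - s)\,I_{\text{raw}},\qquad s \in [0,1],$$

where $I_{\text{smooth}}$ is a Gaussian-weighted moving average (window
default 5% of the profile length, forced odd; kernel sd $(w-1)/5$,
edge-renormalised so constants are preserved). $s = 0$ is no smoothing,
$s = 1$ full smoothing; the blend is affine in $s$ and all of this is
asserted exactly in tests. The default $s = 0.5$ is a moderate choice —
the right value is image-dependent and it is a first-class user
parameter.

**Peak calling** finds local maxima of the final curve with prominence at
least 5% of the dynamic range above baseline and at least 25 bp apart
(both configurable). **Relative areas** split the baseline-subtracted
curve at the valley between adjacent peaks (profile ends outermost) and
integrate each segment trapezoidally over the calibrated bp axis; the
segments partition the curve, so areas sum to 100%. **Percent-in-range**
integrates the same curve over $[lo, hi]$ bp with linear interpolation at
the exact endpoints. An optional relative-area threshold
(`min_peak_area_pct`) discards low-area noise peaks after the fact.

The **baseline** is the per-lane minimum of the raw profile, subtracted
(with negative residuals clipped) before any integration. This is the
simplest baseline consistent with how such tools behave on real images,
and its known consequence is worth stating plainly: any background
residual above the single minimum — a gradient, uneven illumination —
survives subtraction and integrates over the full calibrated span, so
relative areas and percent-in-range read below their ideal values on
images with structured background. The simulator reproduces exactly this
behaviour when its background gradient is enabled; the oracle tests
(below) therefore run on gradient-free renders to verify the integrator
itself, and the realistic-noise tests assert detection and peak-location
accuracy, which are insensitive to the baseline.

### What bp-axis integration measures

The physical lane profile is a density over *migration distance*: the
intensity at a row is proportional to DNA mass per row. The percent
metrics integrate that curve over the *bp axis*, whose spacing per row
varies by the migration law. For a log-normal fragment distribution
$\ln X \sim N(\mu, \sigma^2)$ pushed through the affine-in-$\ln$(bp)
migration map, the rendered row profile is Gaussian, and substituting
$u = \ln(\text{bp})$ shows that the bp-axis integral weights the row
density by $e^u$ — i.e. bp-axis trapezoidal densitometry reports the mass
of the **size-biased** distribution $LN(\mu + \sigma^2, \sigma)$:

$$\frac{\int_{lo}^{hi} I\,\mathrm{d}(\text{bp})}{\int I\,\mathrm{d}(\text{bp})}
 = \Phi\!\Big(\tfrac{\ln hi - \mu - \sigma^2}{\sigma}\Big)
 - \Phi\!\Big(\tfrac{\ln lo - \mu - \sigma^2}{\sigma}\Big).$$

The simulator's ground truth exposes both closed forms —
`mass_in(lane, lo, hi, axis = "row")` for the plain fragment-mass
fraction and `axis = "bp"` for what the bp-axis integral reports — and
the percent-in-range oracle test compares like with like. For the same
reason, the true *peak* bp of a smear is the distribution **median**
(the row-Gaussian's mode maps to $e^\mu$), which is what the ground
truth records.

## The synthetic gel simulator

`gel_sim_config()` + `render_gel()` generate a gel image and a ground
truth sidecar that are exactly consistent:

* **Geometry**: `k` vertical lane tracks (default 9: one ladder + eight
  samples) of 30 px width on a 12 px pitch gap, a faint lane-track
  brightness step (0.12) over the background — the visible "track" a
  loaded lane shows — and band signal inset 5 px from the lane walls,
  because wells are cast narrower than the lane pitch and diffusing DNA
  does not reach the track edges.
* **Migration law**: $\text{row} = a + b(\log_{10} bp_{\max} -
  \log_{10} bp)$ with defaults $a = 20$, $b = 140$ rows/decade on a
  360-row image, so the default 14-marker 75 bp–10 kb ladder spans the
  frame with its closest bands ~13 rows apart.
* **Signal**: ladder markers and discrete bands are Gaussians in row
  space (sd `band_sigma`, default 2 px); a log-normal smear renders as
  its pushed-forward row density — a Gaussian with
  $\sigma_{\text{row}} = b\,\sigma_{\ln}/\ln 10$, widened by the band
  point-spread in quadrature. Default sample content is a smear with
  median 300 bp and $\sigma_{\ln} = 0.35$, a typical sonication target.
* **Corruption**: additive Gaussian noise (default $\sigma = 0.02$, up
  to 0.05 in stress tests), a vertical background tilt (default 0.05),
  and optional dark disc "hole" artifacts inside bands — the defects the
  preprocessing chain exists to remove. Rendering is fully determined by
  the mandatory seed and leaves the session RNG untouched.

What the simulator does **not** emulate: lane tilt or curvature
(detection assumes vertical lanes, as does the method), spatially
correlated illumination, saturation/blooming, camera point-spread across
columns, and inter-lane bleed. Passing tests therefore demonstrate
correctness of the algorithms under the stated image model, not
robustness to every real-world gel pathology; on real images the manual
override paths are the escape hatch the method itself prescribes.

`agarose_scenario(pct)` is a *phenomenological stress fixture*, not a
physical model: a single log-linear law cannot differentially compress
both size extremes, so the scenario maps agarose percentage to a
separation coefficient that peaks at 1.0% ($b = 140(1 - 0.55|pct-1|)$)
with a point-spread that grows away from it
($\sigma = 2(1 + 1.6|pct-1|)$). This reproduces the documented failure
pattern — at 0.5% closely spaced sub-kilobase bands merge first (their
log-spacing is smallest), at 2.0% the multi-kilobase bands lose
resolution — and the degradation tests assert exactly those orderings.

## Test design and problem sizes

The suite runs entirely on generated data: 50 seeded gels for boundary
recovery (±2 columns), 20 seeds for 14-marker localisation (±1 px) and
for smear peak recovery (mean absolute error < 5%), ten
median/$\sigma_{\ln}$ parameterizations for the percent-in-range oracle
(±2 pp against the size-biased closed form), and three two-Gaussian area
ratios (1:1, 2:1, 9:1; ±1.5 pp against exact ratios). The oracle gels
use a dense 1/16-decade calibration ladder and no noise or gradient so
that the calibration chord error (≤ 0.26% of bp) and background effects
stay well below the tolerance being tested — the sparse-ladder chord
bias and the noisy-image behaviour are covered by their own tests.
Degradation runs build calibration from ground-truth marker rows via the
override path for all agarose conditions uniformly, because far from the
1% optimum the dense ladder itself merges and the question under test is
sample-band recovery, not ladder detectability.

## Known limitations

* The linear-in-bp calibration over-estimates sizes between sparse
  ladder knots, worst mid-gap at the low-bp end of broad-range ladders;
  users who need accuracy there should run a denser ladder.
* The per-lane-minimum baseline under-reports relative areas and
  percent-in-range on images with structured background; flat-field
  correction is deliberately out of scope.
* `k` and the ladder lane index are user inputs; there is no automatic
  lane counting or ladder identification.
* Lanes must be vertical; tilted gels should be rotated upstream.
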