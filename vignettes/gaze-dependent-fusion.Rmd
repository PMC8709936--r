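---
title: "Gaze-dependent FIAO image fusion: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-dependent FIAO image fusion: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazefuse)
```

## The method

Flood-illumination adaptive optics (FIAO) ophthalmoscopy resolves the cone
mosaic of the living retina, but drusen — the sub-RPE deposits that mark
early age-related macular degeneration — appear in single FIAO frames as
poorly delineated, low-contrast blobs. Their contrast, however, is not
fixed: when the patient's gaze shifts, a druse's position within the field
of view changes, and the margin of the druse facing the field edge
brightens while the opposite margin fades. Structures that do not interact
with gaze position (the cone mosaic itself, patches of RPE atrophy) look
the same in every frame.

`gazefuse` turns that observation into an image-processing pipeline:

1. **Acquire** a 4°×4° field at nine fixation positions on a 3×3 grid with
   2° spacing, giving 25–50% overlap between adjacent fields.
2. **Register** all images rigidly (translation + rotation) into the frame
   of the central-fixation image.
3. **Fuse** the co-registered stack with a per-pixel statistic of spread.
   Pixels whose intensity varies with gaze (drusen margins) light up;
   static structure cancels.

The highest-contrast statistic is the *maximum pairwise standard
deviation*: at each canvas pixel, over every pair of images defined there,
the two-sample SD $|x_i-x_j|/\sqrt2$, maximized over pairs — equivalently
$(\max_i x_i - \min_i x_i)/\sqrt2$ over the defined values. Sample
(denominator $n-1$) conventions are used throughout, which gives the clean
dominance property that the max-pairwise SD is always at least the
$n$-sample SD, with equality exactly at coverage 2. The "covariance"
statistic is defined as the absolute mean of pairwise deviation products
$(x_i-\mu)(x_j-\mu)$ over pairs $i<j$, which is analytically
$\mathrm{var}/n$; it is provided because it behaves like the variance
rendering with a different display scale.

All fusion statistics run on *defined pixels only*. Canvas pixels outside
an image's footprint are undefined (NA), as are border pixels whose
bilinear support is incomplete, so no defined output value ever draws on
missing data. Spread statistics require at least two defined layers.

## Registration

Registration must survive ~50% overlap, fixation errors of up to a degree,
and small cyclotorsional rotations. The pipeline per image pair is:

1. Both images are smoothed with a circular mean ("pillbox") kernel
   (`lowpass()`, reflect boundary). The kernel radius should scale with
   image resolution: the default 25 px suits the rtx1's native ~1500 px
   4° fields; the 300 px phantom fields used in the tests use the
   scale-equivalent 5 px. The filter is registration-only; fusion always
   uses native intensities.
2. **Translation** comes from the peak of the cross-power spectrum
   (`phase_correlate()`), refined to subpixel precision by a local
   matrix-multiply DFT. Two robustness controls matter on strongly
   filtered images: a spectral regularization `lambda` (the cross-power is
   normalized by $|CP| + \lambda\,\overline{|CP|}$ rather than fully
   whitened, so empty high-frequency bins do not drown the signal), and a
   search window around the seed given by the nominal gaze offset. If the
   seeded estimate ends with poor quality the pair is re-estimated without
   the window, so real data always overrides a wrong prior.
3. **Rotation** is estimated by the Fourier–Mellin method
   (`estimate_rotation()`): Hann-windowed magnitude spectra are resampled
   on a log-polar grid, where rotation becomes a shift along the angle
   axis and scale a shift along log-radius. The scale channel is computed
   and then discarded (forced to 1) — gaze displacement cannot rescale the
   retina. Two details proved essential. The per-radius mean and scale of
   the log-polar maps are removed, because the radial spectral envelope is
   common to both images and otherwise pins the angular correlation at
   zero. And the angular shift is found by energy-weighted
   cross-correlation rather than fully whitened phase correlation:
   whitening amplifies the shared log-polar resampling-grid artifacts
   above the rotation signal. The estimate is iterated (estimate,
   derotate, re-estimate the residual) to remove the small-angle bias of a
   single pass. Rotation is estimated on the translation-aligned overlap
   crops, where the two images actually share content.
4. A **Gauss–Newton polish** on the native images refines all three
   parameters jointly by minimizing the photometrically adjusted SSD over
   the overlap. The cone mosaic makes this objective sharply curved, so
   the polish reaches a precision (a few hundredths of a pixel/degree)
   that the smooth filtered images cannot carry. This stage is the
   package's addition to the classic correlation pipeline; it can be
   disabled (`refine_native = FALSE`).

Per-pair estimates are combined by a quality-weighted linear least squares
over the whole pair graph (`solve_global()`), which generalizes simple
averaging of pairwise offsets: rotations are solved from the difference
constraints, then translations with the solved rotations folded in. Pair
quality is the Pearson correlation of the filtered images over the aligned
overlap (≈1 for faithful pairs). Robustness comes from three layers:
pairs below `q_min` (default 0.1) are dropped; after solving, residual
outliers are trimmed one at a time (a single bad pair inflates the
residuals of every pair sharing its images, so mass-trimming would
disconnect them); and pairs that disagree with the global consensus are
re-estimated with the consensus transform as seed
(`register_gaze_set(repair_rounds = )`). If an image cannot be connected
to the anchor by acceptable pairs, registration fails with a reason — the
analogue of the clinical failure mode of inaccurate fixation or poor image
quality.

The canvas is the union of all transformed footprints, centered on the
anchor (central-fixation) image. With the standard protocol the canvas
spans 8°×8° and per-pixel coverage runs from 1 (corners, a single
contributing image) to 8–9 near the center.

## Photometric normalization

Each acquisition has its own gain and offset (pupil centration, tear film,
illumination drift). Left uncorrected these register as spurious
gaze-dependent signal in any SD-type statistic, so by default each layer
is linearly rescaled to match the anchor layer's mean and SD over their
mutually defined pixels before fusion (`photometric_normalize()`). The
correction is exact for a linear photometric model and harmless when
layers already agree.

## The synthetic phantom

Clinical FIAO data cannot ship with a package, so `make_phantom()` +
`simulate_gaze_set()` generate test scenes with known ground truth:

* **Background**: a jittered hexagonal lattice of Gaussian bright spots
  (cone mosaic, 8 px spacing, SD 0.05 on a unit intensity range) over
  smooth reflectance mottle (Gaussian-filtered noise, correlation length
  ~12 px, SD 0.08), base level 0.5. A `background = "flat"` variant
  isolates the lesion model for polarity checks.
* **Drusen** are annuli: a flat-topped dark core (inner/outer diameter
  ratio 0.7) surrounded by a Gaussian rim whose half-maximum points sit
  exactly at the inner and outer radii, so the lesion-table diameter is
  recoverable from the rendered image to within a pixel. Rim gain is 0.30
  above background, core depth 0.12.
* **Margin modulation**: at rendering time the rim gain is multiplied by
  $1 + p\,a\,e\cos(\varphi-\psi)$, where $\psi$ points from the window
  center toward the lesion, $e$ is the lesion's eccentricity fraction in
  the window (0 at center, 1 at the field edge), $a$ is the modulation
  amplitude (0.5 for drusen, 0.25 for SDDs, which are reported to show
  lower contrast), and $p$ is the polarity (+1 drusen: near-edge margin
  brighter; −1 SDDs: near-edge margin darker). The cosine form is a
  modeling choice — clinically only the sign and the growth with
  eccentricity are established — so tests assert sign and ordering, not
  the functional form.
* **Atrophy** is a static hyper-bright patch (gain 0.35, amplitude 0) with
  a gradual border (15% of its radius): atrophic borders at this scale are
  tens of micrometers wide, and a border much sharper than the pixel grid
  would be an artifact of the phantom, not a feature of the tissue.
* **Acquisition variability** (`acquisition_params()`): Gaussian fixation
  error per axis (default SD 0.15°, radially truncated at 0.8° so every
  window stays on the phantom), uniform rotation (default ±1°), per-image
  gain/offset jitter (SDs 0.05/0.02), and additive Gaussian sensor noise
  (SD 0.02 of the unit range). Registration stress tests widen fixation
  error (SD 0.4°) and rotation (±2°).
* **Scale bookkeeping**: lesion sizes convert micrometers to pixels
  through the device scale 0.77 µm/px, while gaze geometry converts
  degrees to pixels through `px_per_deg` (default 75, i.e. 300×300 px per
  4° field, chosen so a full pipeline run takes seconds). These two
  scales are deliberately decoupled: micrometer arithmetic matches the
  device convention exactly, at the price that lesions are angularly
  larger than on the real instrument. For that reason the default lesion
  diameter range is 15–90 µm (small to intermediate drusen, the regime
  the method targets); a 320 µm druse (415 px) would not fit a 300 px
  field, although the generator accepts any range within the observed
  11–320 µm when asked.
* **Directional mode** reuses the same modulation model with the
  illumination-beam displacement in place of gaze eccentricity at 0.4×
  amplitude, and fixed fixation. Only the *ordering* (gaze-dependent
  fusion shows stronger drusen margins than the directional SD
  z-projection) is asserted, since no quantitative ratio is established.

What the phantom does *not* emulate: vessels and their shadows, intra-frame
eye motion and the device's internal frame averaging, optical blur
(wavefront-correction residuals), photoreceptor-level waveguiding physics,
and inter-session variability. Passing tests therefore demonstrate that
the pipeline recovers the geometry and contrast behavior the model
encodes, not clinical performance on patient images.

## Margin readout and the noise floor

Two statistics recur in the tests and in `scripts/acceptance.R`:

* The **margin fused value** of a lesion is the 90th percentile of the
  fused image over the rim band (within one rim sigma of the rim-peak
  radius). A high percentile, not the mean, because the cosine modulation
  has angular nodes: a margin "lights up" where the gaze geometry
  expresses it, and the readout should capture the achievable margin
  contrast, as a grader's eye does. Detection means the margin fused
  value exceeds the 99th percentile of the non-lesion background of the
  central field.
* The **noise floor** of a fused stack (`noise_floor()`) is a parametric
  bootstrap: every canvas pixel's defined layers are redrawn as Gaussian
  with that pixel's own observed across-layer SD, preserving the spatial
  pattern of effective noise (sensor noise, bilinear-interpolation
  attenuation, residual registration error), and the redrawn stacks are
  fused and quantiled. A lesion-free acquisition should not exceed this
  floor except by sampling fluctuation; coherent gaze-dependent structure
  exceeds it by a large factor.

## Numerical choices and degenerate inputs

* All internal computation is floating point; input intensities are used
  as read, with no histogram equalization (fusion statistics are
  intensity-sensitive).
* Pixel coordinates are 0-based with pixel centers at integer positions,
  x rightward, y downward; a rigid transform `(dx, dy, theta)` maps moving
  image coordinates `p` to `R(theta)(p - c) + c + (dx, dy)` about the
  image center `c`.
* Phase correlation of a constant image is an error (no spectral phase);
  an ambiguous Fourier–Mellin peak returns 0° flagged `low_quality`
  rather than a wild angle; rotations are reported in (−45°, 45°].
* Bilinear sampling marks an output defined only when all four neighbors
  are defined — conservative masks keep the fusion statistics honest at
  footprint borders.
* The 63 µm and 125 µm AREDS size-class boundaries are assigned to the
  intermediate class (closed interval). Count comparisons are reported as
  `100 · n_test / n_reference` (so 25 vs 10 reads as 250%), matching the
  field's reporting convention; percent increase is available as an
  option. Intergrader variability is the coefficient of variation,
  `100 · SD / mean`.
* Problem sizes in the shipped tests: 300 px phantom fields (75 px/deg),
  nine-image protocols, 200 random 16×16 stacks for the fusion oracle,
  two seeded acquisitions for registration recovery. A full
  register-assemble-fuse run at these sizes takes roughly ten seconds.

## Known limitations

* Rigid transforms only; no affine or non-rigid residuals, and no scale
  correction (the Fourier–Mellin scale channel is discarded by design).
* The registration quality threshold (0.1), minimum nominal overlap
  (0.2), spectral regularization (0.3) and repair thresholds (2 px /
  0.3°) are defaults chosen on phantom data, exposed as parameters.
* The fused image retains residual cone-mosaic background signal; no
  attempt is made to suppress it beyond what the statistics provide.
* The lesion detector (`detect_lesions()`) is a deliberately plain
  threshold-plus-connected-components helper for scoring phantoms; the
  clinical quantification it mirrors was manual, and no claim of
  replicating grader behavior is made.
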