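# gazefuse

Gaze-dependent image fusion for flood-illumination adaptive optics (FIAO)
ophthalmoscopy: registration of gaze-displaced retinal images and
per-pixel statistical fusion that highlights drusen.

## What it does, and for whom

Drusen — extracellular deposits under the retinal pigment epithelium and
the hallmark of early age-related macular degeneration — are frustrating
targets in en-face FIAO: in any single frame they are low-contrast,
poorly delineated blobs. But their contrast is *gaze-dependent*: when the
patient fixates off-center, the margin of a druse facing the edge of the
field of view brightens while the opposite margin fades. Structures that
do not vary with gaze (the cone mosaic, patches of RPE atrophy) look the
same in every frame.

`gazefuse` implements the image-processing side of gaze-dependent FIAO
imaging for researchers working with adaptive-optics fundus cameras:

* **Registration.** Nine 4°×4° images acquired at fixation offsets
  {−2°, 0°, +2°}² are aligned rigidly into the frame of the
  central-fixation image: pillbox low-pass filtering, FFT phase
  correlation for translation, Fourier–Mellin log-polar correlation for
  rotation (the scale channel is computed and discarded), an optional
  Gauss–Newton polish on the native images, and a quality-weighted
  least-squares consensus over all image pairs with outlier trimming and
  consensus-seeded repair.
* **Fusion.** The co-registered stack is reduced per pixel over its
  *defined* values only: `sum`, `mean`, sample `variance`/`sd`, a
  pairwise `covariance` statistic (= variance/n), and the
  highest-contrast rendering, the maximum pairwise standard deviation
  `max_pair_sd` = (max − min)/√2. Gaze-varying drusen margins light up;
  static structure cancels. Contrast inversion and percentile display
  normalization are provided, as is the directional-imaging variant (SD
  z-projection of a beam-displaced, fixed-fixation series).
* **Synthetic phantoms.** A generator for retina-like test scenes — cone
  mosaic, reflectance mottle, annular drusen with the gaze-dependent
  margin model, polarity-inverted subretinal drusenoid deposits (SDDs),
  static atrophy — with exact ground-truth transforms and lesion tables,
  so the whole pipeline is testable without patient data.
* **Quantification.** Ellipse-ROI diameters (major axis × 0.77 µm/px),
  AREDS size classes (<63 µm small, 63–125 µm intermediate, >125 µm
  large), annulus inner/outer ratios, modality count ratios, intergrader
  coefficients of variation, overlap geometry, and precision/recall
  scoring of detections against phantom truth.

## Worked example

Simulate a nine-position acquisition of a phantom with 10 drusen, 3 SDDs
and 2 atrophic patches, run the full pipeline, and score the drusen
margins against the image background:

```r
library(gazefuse)

phantom <- make_phantom(n_drusen = 10, n_sdd = 3, n_atrophy = 2, seed = 11)
sim     <- simulate_gaze_set(phantom, params = acquisition_params(seed = 11))
run     <- gaze_pipeline(sim$set, stat = "max_pair_sd", radius_px = 5)

run$registration
#> registration_result: 9 images, anchor 1, 20 pairs used, residual RMS 0.042 px
#>   img 1: dx    +0.00  dy    +0.00  theta +0.000 deg
#>   img 2: dx  -140.55  dy  -140.95  theta +1.852 deg
#>   ...
run$fused
#> fused_image: stat max_pair_sd, 610 x 640 px, 65.8% defined
#>   defined range [2.715e-07, 0.3285], coverage 0-6

proj <- project_lesions(sim$truth, run$stack)
bg   <- background_mask(run$fused, proj, run$stack, sim$truth$px_per_deg)
q99  <- quantile(run$fused$values[bg], 0.99)
margins <- sapply(which(proj$kind == "druse"),
                  function(k) quantile(rim_values(run$fused, proj[k, ]), 0.9))
sum(margins > q99)
#> 10        # all 10 drusen margins exceed the 99th background percentile
round(q99, 4)
#> 0.0534
```

The registration recovers each image's true transform to about a tenth of
a pixel (the nominal grid spacing is 150 px; the deviations are the
simulated fixation errors), and every druse margin rises far above the
background of the fused image, while the two atrophic patches stay below
it — the contrast behavior that makes the fused image a drusen map.

For file-based workflows the same steps are available as shell commands
(`inst/cli/gazefuse`): `simulate`, `register`, `fuse`, `directional`,
`quantify`, reading a JSON manifest of TIFF/PNG images and writing fused
TIFFs, registration JSON and measurement CSVs.

## Method notes

The scientific background, the phantom's forward model and its
assumptions, parameter defaults and the reasoning behind the numerical
design choices are documented in the methods vignette,
`vignettes/gaze-dependent-fusion.Rmd`.
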