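# Readout helpers for scoring fused images against phantom ground truth.

#' Fused-image values on a lesion's rim annulus
#'
#' @param fused a `fused_image` on the stack's canvas.
#' @param lesion one row of [project_lesions()].
#' @param width_sigma half-width of the rim band in units of the rim
#'   Gaussian sigma (default 1).
#' @return numeric vector of defined fused values on the rim band.
#' @export
rim_values <- function(fused, lesion, width_sigma = 1) {
  v <- fused$values
  nr <- nrow(v); nc <- ncol(v)
  xs <- rep(0:(nc - 1), each = nr) - lesion$cx_px
  ys <- rep(0:(nr - 1), times = nc) - lesion$cy_px
  r <- sqrt(xs^2 + ys^2)
  band <- abs(r - lesion$r_peak_px) <= width_sigma * lesion$rim_sigma_px
  out <- v[matrix(band, nr, nc)]
  out[is.finite(out)]
}

#' Fused-image values inside a lesion's full footprint
#'
#' @param fused a `fused_image`.
#' @param lesion one row of [project_lesions()].
#' @param dilate multiplier on the outer radius (default 1).
#' @return numeric vector of defined fused values in the disc.
#' @export
lesion_values <- function(fused, lesion, dilate = 1) {
  v <- fused$values
  nr <- nrow(v); nc <- ncol(v)
  xs <- rep(0:(nc - 1), each = nr) - lesion$cx_px
  ys <- rep(0:(nr - 1), times = nc) - lesion$cy_px
  inside <- (xs^2 + ys^2) <= (dilate * lesion$r_out_px)^2
  out <- v[matrix(inside, nr, nc)]
  out[is.finite(out)]
}

#' Non-lesion background mask of a fused canvas
#'
#' Pixels of the central field (within `central_deg` of the anchor center)
#' that are defined and lie outside every lesion footprint dilated by
#' `dilate`.
#'
#' @param fused a `fused_image`.
#' @param lesions data.frame from [project_lesions()] (may be empty).
#' @param stack the `registered_stack` the image was fused from (for the
#'   canvas origin and scale).
#' @param px_per_deg pixels per degree.
#' @param central_deg half-width of the analyzed central region in degrees
#'   (default 2, the native field).
#' @param dilate lesion exclusion dilation (default 1.5).
#' @return logical matrix, TRUE at background pixels.
#' @export
background_mask <- function(fused, lesions, stack, px_per_deg,
                            central_deg = 2, dilate = 1.5) {
  v <- fused$values
  nr <- nrow(v); nc <- ncol(v)
  xs <- rep(0:(nc - 1), each = nr) + stack$canvas_origin[1]
  ys <- rep(0:(nr - 1), times = nc) + stack$canvas_origin[2]
  # anchor image center in anchor coords
  half <- central_deg * px_per_deg
  cx <- (stack$fov_deg * px_per_deg - 1) / 2
  ok <- abs(xs - cx) <= half & abs(ys - cx) <= half
  if (nrow(lesions) > 0) {
    cxs <- lesions$cx_px + stack$canvas_origin[1]
    cys <- lesions$cy_px + stack$canvas_origin[2]
    for (k in seq_len(nrow(lesions))) {
      d2 <- (xs - cxs[k])^2 + (ys - cys[k])^2
      ok <- ok & d2 > (dilate * lesions$r_out_px[k])^2
    }
  }
  matrix(ok, nr, nc) & is.finite(v)
}

#' Noise floor of the maximum-pairwise-SD statistic for a stack
#'
#' A parametric bootstrap of the stack's incoherent inter-layer
#' variability: each canvas pixel's defined layers are redrawn as Gaussian
#' with that pixel's own observed across-layer SD (so the spatial pattern
#' of effective noise - sensor noise, interpolation attenuation, residual
#' registration error - is preserved), the redrawn stacks are fused with
#' [max_pairwise_sd()], and the requested quantile is returned. A fused
#' image with no gaze-varying structure should not exceed this floor
#' except by sampling fluctuation; gaze-varying lesions exceed it by a
#' large factor, because their inter-layer variability is coherent, not
#' noise-like.
#'
#' @param stack a `registered_stack`.
#' @param prob quantile (default 0.999).
#' @param nrep bootstrap replicates averaged (default 3).
#' @param seed RNG seed for the simulation.
#' @return list with `floor` (the quantile), `sigma` (median per-pixel
#'   effective noise SD, for reference).
#' @export
noise_floor <- function(stack, prob = 0.999, nrep = 3, seed = 1L) {
  stopifnot(inherits(stack, "registered_stack"))
  L <- stack$layers
  def <- !is.na(L)
  n <- rowSums(def, dims = 2)
  L0 <- L; L0[!def] <- 0
  s1 <- rowSums(L0, dims = 2); s2 <- rowSums(L0^2, dims = 2)
  v <- pmax((s2 - s1^2 / pmax(n, 1)) / pmax(n - 1, 1), 0)
  sd_px <- sqrt(v)
  sd_px[n < 2] <- 0
  set.seed(as.integer(seed))
  qs <- vapply(seq_len(nrep), function(r) {
    sim <- stack
    noise <- array(stats::rnorm(length(L)), dim = dim(L)) *
      array(sd_px, dim = dim(L))
    noise[!def] <- NA_real_
    sim$layers <- noise
    f <- max_pairwise_sd(sim)
    stats::quantile(f$values[is.finite(f$values)], prob, names = FALSE)
  }, numeric(1))
  list(floor = mean(qs),
       sigma = stats::median(sd_px[n >= min(4, max(n))]))
}

#' Run the full gaze-dependent pipeline on a set
#'
#' Convenience wrapper: register, assemble, photometric-normalize (on by
#' default for SD-type statistics), fuse.
#'
#' @param set a [gaze_set()].
#' @param stat fusion statistic (default `"max_pair_sd"`).
#' @param normalize photometrically normalize layers to the anchor before
#'   fusing (default TRUE).
#' @param ... passed to [register_gaze_set()].
#' @return list with `registration`, `stack`, `fused`.
#' @export
gaze_pipeline <- function(set, stat = "max_pair_sd", normalize = TRUE, ...) {
  reg <- register_gaze_set(set, ...)
  if (!reg$success)
    stop("gaze_pipeline: registration failed: ", reg$failure_reason)
  stack <- assemble_stack(set, reg)
  if (normalize) stack <- photometric_normalize(stack)
  list(registration = reg, stack = stack, fused = fuse(stack, stat))
}
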