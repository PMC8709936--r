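# Per-pixel statistical fusion of a registered stack.
#
# All statistics run over the *defined* layer values at each canvas pixel;
# undefined (NA) pixels never contribute. The sample (n-1) convention is
# used throughout, which makes the two-sample pairwise SD |x_i - x_j|/sqrt(2)
# and guarantees max_pairwise_sd >= sd with equality exactly at coverage 2.

fusion_stats <- c("sum", "mean", "sd", "variance", "covariance", "max_pair_sd")

new_fused_image <- function(values, coverage, stat, inverted = FALSE,
                            scale_um_per_px = NA_real_) {
  structure(list(values = values, coverage = coverage, stat = stat,
                 inverted = inverted, scale_um_per_px = scale_um_per_px),
            class = "fused_image")
}

#' Fuse a registered stack with a per-pixel statistic
#'
#' Per canvas pixel, over the `n` defined layer values `x_1..x_n`:
#' `sum` and `mean` are the obvious reductions (defined for n >= 1);
#' `variance` is the sample variance (n - 1 denominator), `sd` its square
#' root; `covariance` is the absolute mean over all pairs i < j of
#' `(x_i - mu)(x_j - mu)`, which equals variance / n; `max_pair_sd` is
#' delegated to [max_pairwise_sd()]. Statistics of spread require n >= 2;
#' pixels below the requirement are undefined in the output. The
#' spread statistics are what make gaze-varying structures (drusen margins)
#' light up while static structures (atrophy, the cone mosaic) stay dark.
#'
#' @param stack a `registered_stack`.
#' @param stat one of `"sum"`, `"mean"`, `"sd"`, `"variance"`,
#'   `"covariance"`, `"max_pair_sd"`.
#' @return an object of class `fused_image` with `values`, `coverage`,
#'   `stat`, `inverted`.
#' @export
fuse <- function(stack, stat = "max_pair_sd") {
  stopifnot(inherits(stack, "registered_stack"))
  if (!stat %in% fusion_stats)
    stop("fuse: unknown statistic '", stat, "' (use ",
         paste(fusion_stats, collapse = ", "), ")")
  if (stat == "max_pair_sd") return(max_pairwise_sd(stack))
  L <- stack$layers
  def <- !is.na(L)
  n <- rowSums(def, dims = 2)
  L0 <- L; L0[!def] <- 0
  s1 <- rowSums(L0, dims = 2)
  vals <- switch(stat,
    sum = ifelse(n >= 1, s1, NA_real_),
    mean = ifelse(n >= 1, s1 / n, NA_real_),
    {
      s2 <- rowSums(L0^2, dims = 2)
      v <- (s2 - s1^2 / n) / (n - 1)
      v[n < 2] <- NA_real_
      v <- pmax(v, 0)
      switch(stat, variance = v, sd = sqrt(v), covariance = v / n)
    })
  new_fused_image(vals, n, stat, scale_um_per_px = stack$scale_um_per_px)
}

#' Maximum pairwise standard deviation fusion
#'
#' Per canvas pixel, over all pairs (i, j) of layers defined there, the
#' two-sample sample SD is `|x_i - x_j| / sqrt(2)`; this statistic takes the
#' maximum over pairs, which equals `(max - min) / sqrt(2)` over the defined
#' values. It is the highest-contrast rendering of gaze-varying structures
#' among the fusion statistics. Pixels with coverage < 2 are undefined.
#'
#' @param stack a `registered_stack`.
#' @return a `fused_image` with `stat = "max_pair_sd"`.
#' @export
max_pairwise_sd <- function(stack) {
  stopifnot(inherits(stack, "registered_stack"))
  L <- stack$layers
  def <- !is.na(L)
  n <- rowSums(def, dims = 2)
  hi <- matrix(-Inf, dim(L)[1], dim(L)[2])
  lo <- matrix(Inf, dim(L)[1], dim(L)[2])
  for (k in seq_len(dim(L)[3])) {
    hi <- pmax(hi, L[, , k], na.rm = TRUE)
    lo <- pmin(lo, L[, , k], na.rm = TRUE)
  }
  vals <- (hi - lo) / sqrt(2)
  vals[n < 2] <- NA_real_
  new_fused_image(vals, n, "max_pair_sd",
                  scale_um_per_px = stack$scale_um_per_px)
}

#' Invert the contrast of a fused image
#'
#' Defined values `v` map to `(max_defined - v) + min_defined`; undefined
#' pixels are preserved and the `inverted` flag is toggled. Inverted
#' rendering sometimes gives better subjective drusen contrast.
#'
#' @param fused a `fused_image` with at least one defined pixel.
#' @return the inverted `fused_image`.
#' @export
invert <- function(fused) {
  stopifnot(inherits(fused, "fused_image"))
  def <- is.finite(fused$values)
  if (!any(def)) stop("invert: no defined pixels")
  hi <- max(fused$values[def]); lo <- min(fused$values[def])
  out <- fused
  out$values[def] <- (hi - fused$values[def]) + lo
  out$inverted <- !fused$inverted
  out
}

#' Match each layer's photometry to the anchor layer
#'
#' Per-acquisition gain and offset differences (pupil centration, tear film,
#' illumination drift) would register as spurious gaze-dependent signal in
#' SD-type fusion. This step linearly rescales each layer so its mean and SD
#' over the pixels mutually defined with the anchor layer match the
#' anchor's. Layers with no mutual region (or zero variance there) are left
#' unchanged with a warning.
#'
#' @param stack a `registered_stack`.
#' @param anchor layer index to match against (default the stack's anchor).
#' @return the normalized `registered_stack`.
#' @export
photometric_normalize <- function(stack, anchor = stack$anchor) {
  stopifnot(inherits(stack, "registered_stack"))
  L <- stack$layers
  n <- dim(L)[3]
  ref <- L[, , anchor]
  for (k in seq_len(n)) {
    if (k == anchor) next
    lay <- L[, , k]
    mut <- !is.na(ref) & !is.na(lay)
    if (!any(mut)) {
      warning("photometric_normalize: layer ", k,
              " shares no defined pixels with the anchor; left unchanged")
      next
    }
    mr <- mean(ref[mut]); ml <- mean(lay[mut])
    sr <- stats::sd(ref[mut]); sl <- stats::sd(lay[mut])
    if (!is.finite(sl) || sl == 0) {
      warning("photometric_normalize: layer ", k,
              " constant on the mutual region; left unchanged")
      next
    }
    L[, , k] <- (lay - ml) * (sr / sl) + mr
  }
  stack$layers <- L
  stack
}

#' Directional-imaging standard-deviation z-projection
#'
#' For a series acquired at fixed fixation with the illumination beam
#' displaced in the pupil, the images share one field of view and are
#' already co-registered; the directional image is the per-pixel sample SD
#' across the series (the SD z-projection of the stack).
#'
#' @param images list of >= 2 co-registered numeric matrices of identical
#'   dimensions.
#' @param scale_um_per_px physical scale recorded on the output.
#' @return a `fused_image` with `stat = "sd"`.
#' @export
directional_fuse <- function(images, scale_um_per_px = 0.77) {
  if (!is.list(images) || length(images) < 2)
    stop("directional_fuse: need at least 2 images")
  fuse(stack_from_layers(images, scale_um_per_px), "sd")
}

#' Percentile display normalization of a fused image
#'
#' Maps the 0.5-99.5 percentile range of the defined pixels to [0, 1],
#' clipping the tails, for Fig-style rendering without hot-pixel artifacts.
#' Raw statistic values are left untouched in the `fused_image` itself.
#'
#' @param fused a `fused_image`.
#' @param probs lower/upper clip percentiles (default `c(0.005, 0.995)`).
#' @return numeric matrix in [0, 1] with NA at undefined pixels.
#' @export
display_normalize <- function(fused, probs = c(0.005, 0.995)) {
  stopifnot(inherits(fused, "fused_image"))
  def <- is.finite(fused$values)
  q <- stats::quantile(fused$values[def], probs, names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  out <- (fused$values - q[1]) / (q[2] - q[1])
  out[def] <- pmin(pmax(out[def], 0), 1)
  out
}

#' Write a fused image to disk (display TIFF + raw TIFF + JSON sidecar)
#'
#' @param fused a `fused_image`.
#' @param prefix output path prefix; writes `<prefix>.tif` (16-bit,
#'   display-normalized), `<prefix>_raw.tif` (32-bit float raw statistic),
#'   and `<prefix>.json` (stat, inversion flag, coverage summary).
#' @return character vector of the written paths, invisibly.
#' @export
write_fused <- function(fused, prefix) {
  stopifnot(inherits(fused, "fused_image"))
  disp <- display_normalize(fused)
  disp[!is.finite(disp)] <- 0
  p1 <- paste0(prefix, ".tif")
  tiff::writeTIFF(disp, p1, bits.per.sample = 16)
  raw <- fused$values
  raw[!is.finite(raw)] <- 0
  p2 <- paste0(prefix, "_raw.tif")
  tiff::writeTIFF(raw / max(raw, 1e-300), p2, bits.per.sample = 32)
  p3 <- paste0(prefix, ".json")
  cov <- fused$coverage
  jsonlite::write_json(list(
    stat = fused$stat, inverted = fused$inverted,
    scale_um_per_px = fused$scale_um_per_px,
    coverage = list(min = min(cov), max = max(cov), mean = mean(cov)),
    defined_fraction = mean(is.finite(fused$values)),
    raw_max = max(fused$values, na.rm = TRUE)),
    p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}

#' @export
print.fused_image <- function(x, ...) {
  def <- is.finite(x$values)
  cat(sprintf("fused_image: stat %s%s, %d x %d px, %.1f%% defined\n",
              x$stat, if (x$inverted) " (inverted)" else "",
              nrow(x$values), ncol(x$values), 100 * mean(def)))
  if (any(def))
    cat(sprintf("  defined range [%.4g, %.4g], coverage %d-%d\n",
                min(x$values[def]), max(x$values[def]),
                min(x$coverage), max(x$coverage)))
  invisible(x)
}
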