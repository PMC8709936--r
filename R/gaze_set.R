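#' Construct a single gaze-position acquisition
#'
#' A `gaze_image` bundles one en-face retinal image with the nominal fixation
#' offset (in degrees) at which it was acquired. Intensities are stored as
#' floating point exactly as read; no rescaling or equalization is applied,
#' because the downstream fusion statistics are intensity-sensitive.
#'
#' @param pixels numeric matrix (rows = y, columns = x).
#' @param gaze_deg length-2 numeric, nominal fixation offset `(x, y)` in
#'   degrees. The axes are abstract planar coordinates; no anatomical
#'   direction (nasal/temporal) is assumed.
#' @param id character label.
#' @return An object of class `gaze_image`.
#' @export
gaze_image <- function(pixels, gaze_deg, id = "img") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("gaze_image: pixels must be a non-empty matrix")
  gaze_deg <- as.numeric(gaze_deg)
  if (length(gaze_deg) != 2 || any(!is.finite(gaze_deg)))
    stop("gaze_image: gaze_deg must be two finite numbers")
  structure(list(pixels = pixels, gaze_deg = gaze_deg, id = as.character(id)),
            class = "gaze_image")
}

#' Construct a set of gaze-displaced acquisitions
#'
#' The standard acquisition protocol images a 4 degree by 4 degree field at
#' nine fixation positions separated by 2 degrees (a 3x3 grid), giving 25-50%
#' overlap between adjacent images; `gaze_set` holds any such collection.
#'
#' @param images list of [gaze_image()] objects, all with identical pixel
#'   dimensions and pairwise-distinct gaze positions.
#' @param fov_deg field-of-view width in degrees (default 4).
#' @param scale_um_per_px physical scale in micrometers per pixel
#'   (default 0.77).
#' @return An object of class `gaze_set`.
#' @export
gaze_set <- function(images, fov_deg = 4, scale_um_per_px = 0.77) {
  if (!is.list(images) || length(images) < 2)
    stop("gaze_set: need at least 2 images")
  if (!all(vapply(images, inherits, logical(1), "gaze_image")))
    stop("gaze_set: images must be gaze_image objects")
  dims <- vapply(images, function(g) dim(g$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("gaze_set: all images must have identical dimensions")
  gz <- t(vapply(images, function(g) g$gaze_deg, numeric(2)))
  if (anyDuplicated(gz))
    stop("gaze_set: gaze positions must be unique")
  if (!is.numeric(fov_deg) || fov_deg <= 0)
    stop("gaze_set: fov_deg must be positive")
  structure(list(images = images, fov_deg = as.numeric(fov_deg),
                 scale_um_per_px = as.numeric(scale_um_per_px)),
            class = "gaze_set")
}

#' @export
print.gaze_set <- function(x, ...) {
  d <- dim(x$images[[1]]$pixels)
  cat(sprintf("gaze_set: %d images of %d x %d px, fov %g deg, %g um/px\n",
              length(x$images), d[1], d[2], x$fov_deg, x$scale_um_per_px))
  gz <- t(vapply(x$images, function(g) g$gaze_deg, numeric(2)))
  ids <- vapply(x$images, function(g) g$id, character(1))
  for (i in seq_along(ids))
    cat(sprintf("  %-12s gaze (%+.2f, %+.2f) deg\n", ids[i], gz[i, 1], gz[i, 2]))
  invisible(x)
}

#' @export
length.gaze_set <- function(x) length(x$images)

#' Gaze offsets of a set as an n x 2 matrix (degrees)
#' @param x a `gaze_set`.
#' @return numeric matrix with columns `x`, `y`.
#' @export
gaze_offsets <- function(x) {
  stopifnot(inherits(x, "gaze_set"))
  m <- t(vapply(x$images, function(g) g$gaze_deg, numeric(2)))
  colnames(m) <- c("x", "y")
  rownames(m) <- vapply(x$images, function(g) g$id, character(1))
  m
}

#' Pixels-per-degree scale implied by a set's image width and field of view
#' @param x a `gaze_set`.
#' @return pixels per degree (from image width / fov).
#' @export
px_per_deg <- function(x) {
  stopifnot(inherits(x, "gaze_set"))
  ncol(x$images[[1]]$pixels) / x$fov_deg
}

#' Construct an ellipse region of interest
#'
#' Ellipses are the annotation primitive used by graders to mark drusen;
#' the major-axis diameter in pixels times the image scale gives the druse
#' diameter in micrometers. Axes are normalized so `a >= b`; if given
#' swapped, they are exchanged and the orientation rotated by 90 degrees
#' (with a warning).
#'
#' @param center_px length-2 numeric, 0-based center `(x, y)` in pixels.
#' @param semi_axes_px length-2 numeric `(a, b)`, semi-axes in pixels.
#' @param angle_deg major-axis orientation in degrees.
#' @param label free-text label.
#' @param modality one of `"color_fundus"`, `"native_fiao"`,
#'   `"gaze_dependent"`.
#' @param id character identifier.
#' @return An object of class `ellipse_roi`.
#' @export
ellipse_roi <- function(center_px, semi_axes_px, angle_deg = 0, label = "",
                        modality = c("gaze_dependent", "color_fundus", "native_fiao"),
                        id = "roi") {
  modality <- match.arg(modality)
  a <- semi_axes_px[1]; b <- semi_axes_px[2]
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a <= 0)
    stop("ellipse_roi: semi-axes must be positive")
  if (a < b) {
    warning("ellipse_roi: a < b; swapping axes and rotating angle by 90 degrees")
    tmp <- a; a <- b; b <- tmp
    angle_deg <- angle_deg + 90
  }
  structure(list(center_px = as.numeric(center_px),
                 semi_axes_px = c(a = as.numeric(a), b = as.numeric(b)),
                 angle_deg = as.numeric(angle_deg),
                 label = as.character(label), modality = modality,
                 id = as.character(id)),
            class = "ellipse_roi")
}
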