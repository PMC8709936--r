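# Internal numeric helpers shared by registration, fusion and simulation.
#
# Image convention used throughout the package: a 2-D image is a numeric
# matrix with rows indexing y (downward) and columns indexing x (rightward).
# Pixel coordinates are 0-based with pixel centers at integer positions, so
# pixel (x, y) lives at matrix element [y + 1, x + 1].

#' @keywords internal
#' @noRd
img_center <- function(img) {
  # geometric center in 0-based (x, y) pixel coordinates
  c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
}

#' Bilinear sampling of a matrix at fractional 0-based coordinates.
#'
#' Returns a list with `values` and a logical `defined` vector; a sample is
#' defined only when all four bilinear neighbors fall inside the image (and,
#' when `mask` is given, are themselves defined), so no defined output ever
#' draws on out-of-bounds or masked-out data.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of 0-based sample coordinates.
#' @param mask optional logical matrix marking defined input pixels.
#' @keywords internal
#' @noRd
bilinear_sample <- function(img, x, y, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & (x0 + 1) <= (nc - 1) & (y0 + 1) <= (nr - 1)
  # exact hits on the last row/column are still fully determined
  edge_x <- x0 == (nc - 1) & fx == 0 & y0 >= 0
  edge_y <- y0 == (nr - 1) & fy == 0 & x0 >= 0
  inside <- inside | (edge_x & (y0 + 1) <= (nr - 1)) | (edge_y & (x0 + 1) <= (nc - 1)) |
    (edge_x & edge_y)
  values <- rep(NA_real_, length(x))
  if (any(inside)) {
    xi <- pmin(x0[inside], nc - 2); yi <- pmin(y0[inside], nr - 2)
    gx <- x[inside] - xi; gy <- y[inside] - yi
    i00 <- yi + 1 + xi * nr
    v00 <- img[i00];       v10 <- img[i00 + nr]
    v01 <- img[i00 + 1];   v11 <- img[i00 + nr + 1]
    values[inside] <- (1 - gx) * (1 - gy) * v00 + gx * (1 - gy) * v10 +
      (1 - gx) * gy * v01 + gx * gy * v11
    if (!is.null(mask)) {
      ok <- mask[i00] & mask[i00 + nr] & mask[i00 + 1] & mask[i00 + nr + 1]
      values[inside][!ok] <- NA_real_
      inside[inside] <- ok
    }
  }
  list(values = values, defined = inside)
}

#' Resample an image under a rigid transform about its center.
#'
#' Output pixel (x, y) takes the value of the input at
#' `R(-theta) (p - c - t) + c`, i.e. the returned image is the input
#' translated by `t = (dx, dy)` pixels and rotated by `theta` degrees about
#' the image center. Pixels mapping outside the input are NA.
#' @keywords internal
#' @noRd
rigid_resample <- function(img, dx = 0, dy = 0, theta_deg = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ctr <- img_center(img)
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  th <- -theta_deg * pi / 180
  ux <- xs - ctr[1] - dx
  uy <- ys - ctr[2] - dy
  sx <- cos(th) * ux - sin(th) * uy + ctr[1]
  sy <- sin(th) * ux + cos(th) * uy + ctr[2]
  out <- bilinear_sample(img, sx, sy)
  matrix(out$values, nr, nc)
}

#' Reflect-pad a matrix by `r` pixels on every side.
#' @keywords internal
#' @noRd
pad_reflect <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  if (r >= nr || r >= nc) stop("pad radius exceeds image dimensions")
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  img[ri, ci, drop = FALSE]
}

#' 2-D Hann window (outer product of 1-D Hann windows).
#' @keywords internal
#' @noRd
hann2d <- function(nr, nc) {
  wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(nr) / (nr + 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(nc) / (nc + 1))
  outer(wy, wx)
}

#' Quadrant swap so the zero-frequency bin sits at the matrix center.
#' @keywords internal
#' @noRd
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2)), drop = FALSE]
}

#' Rotation matrix for an angle in degrees (x right, y down; positive angle
#' rotates x toward y, i.e. clockwise on screen).
#' @keywords internal
#' @noRd
rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}
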