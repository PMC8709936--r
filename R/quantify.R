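# Drusen measurement and comparison utilities: diameters, AREDS size
# classes, annulus ratios, modality count comparisons, intergrader
# variability, and detection scoring against phantom ground truth.

#' Druse diameter from an ellipse annotation
#'
#' The diameter is the major-axis length of the grader's ellipse times the
#' image scale: `2 * a * scale`.
#'
#' @param roi an [ellipse_roi()] (or anything with `semi_axes_px`).
#' @param scale_um_per_px micrometers per pixel (default 0.77).
#' @return diameter in micrometers.
#' @export
diameter_um <- function(roi, scale_um_per_px = 0.77) {
  stopifnot(scale_um_per_px > 0)
  2 * unname(roi$semi_axes_px[1]) * scale_um_per_px
}

#' AREDS drusen size class from a diameter
#'
#' Small < 63 um; intermediate 63-125 um (boundaries inclusive);
#' large > 125 um.
#'
#' @param diameter_um diameter(s) in micrometers, positive.
#' @return factor with levels small < intermediate < large.
#' @export
classify_size <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("classify_size: diameters must be positive")
  cls <- ifelse(diameter_um < 63, "small",
                ifelse(diameter_um <= 125, "intermediate", "large"))
  factor(cls, levels = c("small", "intermediate", "large"), ordered = TRUE)
}

#' Inner-to-outer diameter ratio of a druse annulus
#'
#' The dark druse center corresponds to the summit and the bright annulus
#' to the slopes, so inner/outer is a dimensionless shape measure
#' comparable across modalities.
#'
#' @param inner_um,outer_um inner and outer diameters, `0 < inner <= outer`.
#' @return `inner_um / outer_um`.
#' @export
annulus_ratio <- function(inner_um, outer_um) {
  if (any(inner_um <= 0) || any(inner_um > outer_um))
    stop("annulus_ratio: need 0 < inner <= outer")
  inner_um / outer_um
}

#' Drusen count in one modality as a percentage of a reference modality
#'
#' Reported in the convention `100 * n_test / n_reference`, so detecting
#' 25 drusen where the reference shows 10 reads as 250%.
#'
#' @param n_test,n_reference counts; reference must be positive.
#' @param percent_increase if `TRUE`, report `100 * (n_test - n_ref) / n_ref`
#'   instead (not the default convention).
#' @return percentage.
#' @export
count_ratio <- function(n_test, n_reference, percent_increase = FALSE) {
  if (any(n_reference <= 0)) stop("count_ratio: reference count must be > 0")
  if (percent_increase) 100 * (n_test - n_reference) / n_reference
  else 100 * n_test / n_reference
}

#' Intergrader variability as a coefficient of variation
#'
#' `100 * sample SD / mean` over the per-grader values of one measurement.
#'
#' @param values numeric vector, one value per grader (>= 2 values).
#' @return percentage CV.
#' @export
intergrader_cv <- function(values) {
  if (length(values) < 2) stop("intergrader_cv: need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("intergrader_cv: mean is zero")
  100 * stats::sd(values) / m
}

#' Score detected lesion centers against a ground-truth table
#'
#' Greedy nearest-neighbor matching: candidate pairs within `tol_um` are
#' accepted in order of increasing distance, each detection and each truth
#' lesion used at most once. With no detections, precision is undefined and
#' reported as 0 with `precision_defined = FALSE`.
#'
#' @param detected n x 2 matrix of detected centers (pixels).
#' @param truth m x 2 matrix of true centers (pixels).
#' @param tol_um matching tolerance in micrometers.
#' @param scale_um_per_px micrometers per pixel (default 0.77).
#' @return list with `precision`, `recall`, `matches` (data.frame
#'   `detected`, `truth`, `dist_px`), `precision_defined`.
#' @export
match_detections <- function(detected, truth, tol_um = 30,
                             scale_um_per_px = 0.77) {
  stopifnot(tol_um > 0)
  detected <- matrix(as.numeric(detected), ncol = 2)
  truth <- matrix(as.numeric(truth), ncol = 2)
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0) {
    return(list(precision = 0, recall = if (nt == 0) 1 else 0,
                matches = data.frame(detected = integer(0),
                                     truth = integer(0),
                                     dist_px = numeric(0)),
                precision_defined = FALSE))
  }
  tol_px <- tol_um / scale_um_per_px
  dmat <- outer(detected[, 1], truth[, 1], "-")^2 +
          outer(detected[, 2], truth[, 2], "-")^2
  dmat <- sqrt(dmat)
  cand <- which(dmat <= tol_px, arr.ind = TRUE)
  used_d <- logical(nd); used_t <- logical(nt)
  matches <- list()
  if (nrow(cand) > 0) {
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE
      matches[[length(matches) + 1]] <-
        data.frame(detected = i, truth = j, dist_px = dmat[i, j])
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(detected = integer(0), truth = integer(0),
               dist_px = numeric(0))
  list(precision = nrow(matches) / nd,
       recall = if (nt == 0) 1 else nrow(matches) / nt,
       matches = matches, precision_defined = TRUE)
}

#' Simple threshold-plus-connected-components lesion detector
#'
#' A deliberately plain detector for scoring the pipeline on phantoms:
#' thresholds the fused image at a percentile of its defined pixels, labels
#' connected components (8-connectivity), discards components smaller than
#' `min_area_px`, and returns component centroids. The clinical
#' quantification this package mirrors was manual; this makes no attempt to
#' replicate grader behavior.
#'
#' @param fused a `fused_image`.
#' @param prob threshold percentile of the defined pixels (default 0.99).
#' @param min_area_px minimum component area (default 10).
#' @return data.frame with `cx_px`, `cy_px` (0-based), `area_px`.
#' @export
detect_lesions <- function(fused, prob = 0.99, min_area_px = 10) {
  stopifnot(inherits(fused, "fused_image"))
  v <- fused$values
  def <- is.finite(v)
  thr <- stats::quantile(v[def], prob, names = FALSE)
  bw <- matrix(0, nrow(v), ncol(v))
  bw[def & v > thr] <- 1
  lab <- label_components(bw)
  if (max(lab) == 0)
    return(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      area_px = integer(0)))
  idx <- which(lab > 0)
  comp <- lab[idx]
  ys <- (idx - 1) %% nrow(v)
  xs <- (idx - 1) %/% nrow(v)
  area <- tabulate(comp)
  cx <- rowsum(xs, comp)[, 1] / area
  cy <- rowsum(ys, comp)[, 1] / area
  keep <- area >= min_area_px
  data.frame(cx_px = cx[keep], cy_px = cy[keep], area_px = area[keep])
}

# 8-connected component labeling; uses EBImage when available, otherwise an
# iterative label-propagation fallback
label_components <- function(bw) {
  if (requireNamespace("EBImage", quietly = TRUE))
    return(EBImage::bwlabel(bw))
  lab <- matrix(seq_along(bw), nrow(bw), ncol(bw))
  lab[bw == 0] <- 0
  nr <- nrow(bw); nc <- ncol(bw)
  repeat {
    new <- lab
    shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (s in shifts) {
      sh <- matrix(0, nr, nc)
      rs <- max(1, 1 + s[1]):min(nr, nr + s[1])
      cs <- max(1, 1 + s[2]):min(nc, nc + s[2])
      sh[rs, cs] <- lab[rs - s[1], cs - s[2]]
      upd <- bw > 0 & sh > 0 & (new == 0 | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, u, nomatch = 1) * (lab > 0)
  lab
}
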