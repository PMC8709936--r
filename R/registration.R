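# Rigid registration of gaze-displaced images.
#
# Pipeline: low-pass filter -> per-pair rotation (Fourier-Mellin log-polar)
# -> per-pair translation (phase correlation, seeded by the nominal gaze
# offset) -> quality-weighted global least squares over the pair graph.
#
# Transform convention: a rigid transform (dx, dy, theta) maps a point p in
# the moving image to R(theta) (p - c) + c + (dx, dy) in the reference
# image, with c the geometric image center and theta in degrees.

#' Low-pass filter an image with a circular mean (pillbox) kernel
#'
#' Convolves the image with a normalized disc kernel of the given pixel
#' radius using reflected boundaries. This removes the cone-mosaic spatial
#' frequencies and sensor noise before registration; fusion always operates
#' on the unfiltered images.
#'
#' @param image numeric matrix.
#' @param radius_px kernel radius in pixels (default 25).
#' @param kernel `"disc"` for the pillbox kernel or `"gaussian"` for a
#'   Gaussian with sigma = radius_px / 2.
#' @return filtered matrix with the same dimensions.
#' @export
lowpass <- function(image, radius_px = 25, kernel = c("disc", "gaussian")) {
  kernel <- match.arg(kernel)
  r <- as.integer(radius_px)
  if (r < 1) stop("lowpass: radius_px must be >= 1")
  if (r > min(dim(image)) / 2)
    stop("lowpass: radius exceeds half the smaller image dimension")
  off <- -r:r
  d2 <- outer(off^2, off^2, "+")
  k <- if (kernel == "disc") (d2 <= r^2) * 1 else exp(-d2 / (2 * (r / 2)^2))
  k <- k / sum(k)
  padded <- pad_reflect(image, r)
  nr <- nrow(padded); nc <- ncol(padded)
  kbig <- matrix(0, nr, nc)
  # embed kernel centered on (1,1) so circular convolution is centered
  idx <- function(o, n) ((o %% n) + n) %% n + 1L
  kbig[idx(off, nr), idx(off, nc)] <- k
  conv <- Re(stats::fft(stats::fft(padded) * stats::fft(kbig), inverse = TRUE)) /
    (nr * nc)
  conv[(r + 1):(nr - r), (r + 1):(nc - r), drop = FALSE]
}

#' FFT phase correlation for translation estimation
#'
#' Estimates the shift (dx, dy) such that translating `mov` by (dx, dy)
#' aligns it with `ref`, from the peak of the inverse FFT of the normalized
#' cross-power spectrum. With `upsample > 1` the peak is refined to
#' 1/upsample pixel by a local matrix-multiply DFT. Because the FFT is
#' circular, the shift is only determined modulo the image size; `seed_px`
#' selects the wrap branch nearest a prior estimate (default (0, 0), i.e.
#' shifts in [-N/2, N/2)).
#'
#' @param ref,mov numeric matrices of identical dimensions, non-constant.
#' @param upsample integer >= 1 subpixel refinement factor.
#' @param seed_px length-2 numeric prior shift used to unwrap the peak.
#' @param search_radius_px if non-NULL, restrict the peak search to shifts
#'   within this circular-wrap distance of `seed_px` per axis; with a
#'   trustworthy prior this rejects spurious far-field peaks.
#' @param lambda spectral regularization: the cross-power spectrum is
#'   normalized by `|CP| + lambda * mean(|CP|)`. 0 (default) is classic
#'   fully whitened phase correlation; larger values weight bins by energy,
#'   which is more robust when much of the spectrum carries no signal
#'   (e.g. strongly low-pass-filtered images).
#' @return list with `dx_px`, `dy_px`, `quality` (peak correlation in
#'   [0, 1]).
#' @export
phase_correlate <- function(ref, mov, upsample = 1, seed_px = c(0, 0),
                            search_radius_px = NULL, lambda = 0) {
  if (!all(dim(ref) == dim(mov)))
    stop("phase_correlate: images must have identical dimensions")
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0)
    stop("phase_correlate: constant image has no spectral phase")
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- stats::fft(ref - mean(ref)); Fm <- stats::fft(mov - mean(mov))
  cp0 <- Fr * Conj(Fm)
  cpw <- cp0 / pmax(Mod(cp0), .Machine$double.eps)   # whitened, for quality
  cp <- if (lambda > 0) cp0 / (Mod(cp0) + lambda * mean(Mod(cp0)) +
                                 .Machine$double.eps) else cpw
  corr <- Re(stats::fft(cp, inverse = TRUE)) / (nr * nc)
  if (!is.null(search_radius_px)) {
    wrapd <- function(v, n, s) { d <- (v - s) %% n; pmin(d, n - d) }
    corr[wrapd(0:(nr - 1), nr, seed_px[2]) > search_radius_px, ] <- -Inf
    corr[, wrapd(0:(nc - 1), nc, seed_px[1]) > search_radius_px] <- -Inf
  }
  pk <- arrayInd(which.max(corr), dim(corr))
  # 0-based peak, unwrapped to the branch nearest the seed
  unwrap <- function(v, n, s) {
    cand <- v + c(-n, 0, n)
    cand[which.min(abs(cand - s))]
  }
  dy <- unwrap(pk[1] - 1, nr, seed_px[2])
  dx <- unwrap(pk[2] - 1, nc, seed_px[1])
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  fine_eval <- function(m, sy, sx) {
    Re(exp(2i * pi * outer(sy, fy)) %*% m %*%
         exp(2i * pi * outer(fx, sx))) / (nr * nc)
  }
  if (upsample > 1) {
    us <- as.integer(upsample)
    sy <- dy + seq(-1, 1, by = 1 / us)
    sx <- dx + seq(-1, 1, by = 1 / us)
    fine <- fine_eval(cp, sy, sx)
    pk2 <- arrayInd(which.max(fine), dim(fine))
    dy <- sy[pk2[1]]; dx <- sx[pk2[2]]
  }
  quality <- max(min(fine_eval(cpw, dy, dx)[1, 1], 1), 0)
  list(dx_px = dx, dy_px = dy, quality = quality)
}

# Log-polar resampling of the centered magnitude spectrum.
# Rows index angle over [0, 180) degrees, columns index log-radius. The
# per-radius mean and scale are removed: the radial spectral envelope is
# shared by any two images of the same scene and would otherwise pin the
# angular correlation peak at zero rotation.
log_polar_spectrum <- function(image, n_theta, n_r, r_min, r_max) {
  w <- hann2d(nrow(image), ncol(image))
  M <- Mod(fftshift2(stats::fft((image - mean(image)) * w)))
  M <- log1p(M)
  cx <- floor(ncol(M) / 2); cy <- floor(nrow(M) / 2)
  ang <- (seq_len(n_theta) - 1) * pi / n_theta
  rad <- exp(seq(log(r_min), log(r_max), length.out = n_r))
  xs <- cx + outer(cos(ang), rad)
  ys <- cy + outer(sin(ang), rad)
  s <- bilinear_sample(M, as.vector(xs), as.vector(ys))
  v <- s$values; v[!s$defined] <- 0
  lp <- matrix(v, n_theta, n_r)
  mu <- colMeans(lp)
  sd_r <- sqrt(colMeans(sweep(lp, 2, mu)^2))
  sweep(sweep(lp, 2, mu), 2, pmax(sd_r, 1e-12), "/")
}

# Unnormalized circular cross-correlation peak with matrix-DFT subpixel
# refinement; quality is the normalized correlation coefficient at the
# peak. Used on log-polar maps, where full phase whitening would amplify
# the shared resampling-grid artifacts over the rotation signal.
xcorr_peak <- function(a, b, upsample = 8) {
  nr <- nrow(a); nc <- ncol(a)
  cp <- stats::fft(a) * Conj(stats::fft(b))
  corr <- Re(stats::fft(cp, inverse = TRUE)) / (nr * nc)
  pk <- arrayInd(which.max(corr), dim(corr))
  dy <- pk[1] - 1; if (dy > nr / 2) dy <- dy - nr
  dx <- pk[2] - 1; if (dx > nc / 2) dx <- dx - nc
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  sy <- dy + seq(-1, 1, by = 1 / upsample)
  sx <- dx + seq(-1, 1, by = 1 / upsample)
  fine <- Re(exp(2i * pi * outer(sy, fy)) %*% cp %*%
               exp(2i * pi * outer(fx, sx))) / (nr * nc)
  pk2 <- arrayInd(which.max(fine), dim(fine))
  norm <- sqrt(sum(a^2) * sum(b^2))
  list(dy = sy[pk2[1]], dx = sx[pk2[2]],
       quality = max(min(fine[pk2] * nr * nc / max(norm, 1e-300), 1), 0))
}

#' Rotation estimation via Fourier-Mellin log-polar correlation
#'
#' Both images are Hann-windowed and their centered magnitude spectra
#' resampled on a log-polar grid with the per-radius mean and scale removed
#' (the radial spectral envelope is common to both images and carries no
#' rotation information). A rotation of the image is a translation along
#' the angle axis of the log-polar map, recovered from the peak of the
#' cross-correlation of the two maps, refined to subdegree precision and
#' iterated (estimate, derotate, re-estimate the residual) until
#' convergence. The log-radius shift corresponds to a scale change; it is
#' computed but discarded (scale forced to 1), since gaze displacement
#' cannot rescale the retina. The returned angle is wrapped into (-45, 45].
#'
#' @param ref,mov numeric matrices of identical dimensions, non-constant.
#' @param n_theta angular bins over 180 degrees (default 720).
#' @param n_r log-radius bins (default 128).
#' @param upsample subpixel refinement factor for the angular peak.
#' @param max_iter refinement iterations (default 3).
#' @param q_min minimum acceptable peak quality; below it the estimate is
#'   ambiguous and `theta_deg = 0` is returned with `low_quality = TRUE`.
#' @return list with `theta_deg`, `quality`, `low_quality`, and the
#'   discarded `scale` estimate.
#' @export
estimate_rotation <- function(ref, mov, n_theta = 720, n_r = 128,
                              upsample = 8, max_iter = 3, q_min = 0.02) {
  if (!all(dim(ref) == dim(mov)))
    stop("estimate_rotation: images must have identical dimensions")
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0)
    stop("estimate_rotation: constant image has no spectral phase")
  r_max <- min(dim(ref)) / 2 - 2
  r_min <- 4
  lp1 <- log_polar_spectrum(ref, n_theta, n_r, r_min, r_max)
  total <- 0; quality <- 0; scale <- 1
  cur <- mov
  for (it in seq_len(max_iter)) {
    lp2 <- log_polar_spectrum(cur, n_theta, n_r, r_min, r_max)
    pk <- xcorr_peak(lp1, lp2, upsample = upsample)
    # sign convention: theta is the rotation of the transform mapping mov
    # onto ref, matching the translation returned by phase_correlate()
    step <- pk$dy * 180 / n_theta
    step <- ((step + 90) %% 180) - 90
    if (it == 1) scale <- exp(-pk$dx * log(r_max / r_min) / (n_r - 1))
    quality <- pk$quality
    total <- total + step
    if (abs(step) < 90 / n_theta || it == max_iter) break
    cur <- rigid_resample(mov, 0, 0, total)
    cur[is.na(cur)] <- mean(cur, na.rm = TRUE)
  }
  theta <- ((total + 90) %% 180) - 90
  if (theta > 45) theta <- theta - 90
  if (theta <= -45) theta <- theta + 90
  low <- quality < q_min
  list(theta_deg = if (low) 0 else theta, quality = quality,
       low_quality = low, scale = scale)
}

#' Nominal field overlap fraction of two square fields
#'
#' Area of the intersection of two axis-aligned `fov_deg` x `fov_deg`
#' squares whose centers are offset by `(dx_deg, dy_deg)`, as a fraction of
#' one field's area. For the standard protocol (4 degree field, 2 degree
#' steps) cardinal neighbors overlap by 0.50 and diagonal neighbors by 0.25.
#'
#' @param fov_deg field width in degrees.
#' @param dx_deg,dy_deg center offset in degrees.
#' @return overlap fraction in [0, 1].
#' @export
overlap_fraction <- function(fov_deg, dx_deg, dy_deg) {
  stopifnot(fov_deg > 0)
  wx <- pmax(0, fov_deg - abs(dx_deg))
  wy <- pmax(0, fov_deg - abs(dy_deg))
  wx * wy / fov_deg^2
}

# Direct intensity-based Gauss-Newton polish of one pairwise rigid
# transform on the native images. Minimizes the photometrically-adjusted
# SSD between ref and the transformed mov over the overlap; the cone-mosaic
# texture makes the objective sharply curved, giving subpixel/subdegree
# precision that the smooth low-pass-filtered images cannot provide.
refine_pair_native <- function(ref, mov, d0, th0, n_iter = 10,
                               max_px = 30000) {
  nr <- nrow(ref); nc <- ncol(ref)
  ctr <- c((nc - 1) / 2, (nr - 1) / 2)
  xs <- rep(0:(nc - 1), each = nr); ys <- rep(0:(nr - 1), times = nc)
  p <- c(d0, th0)
  for (it in seq_len(n_iter)) {
    th <- p[3] * pi / 180
    ux <- xs - ctr[1] - p[1]; uy <- ys - ctr[2] - p[2]
    mx <- cos(th) * ux + sin(th) * uy + ctr[1]
    my <- -sin(th) * ux + cos(th) * uy + ctr[2]
    s <- bilinear_sample(mov, mx, my)
    ok <- which(s$defined)
    if (length(ok) < 500) return(list(p = p, ok = FALSE))
    if (length(ok) > max_px) ok <- ok[seq(1, length(ok),
                                          by = ceiling(length(ok) / max_px))]
    gx <- bilinear_sample(mov, mx[ok] + 0.5, my[ok])$values -
      bilinear_sample(mov, mx[ok] - 0.5, my[ok])$values
    gy <- bilinear_sample(mov, mx[ok], my[ok] + 0.5)$values -
      bilinear_sample(mov, mx[ok], my[ok] - 0.5)$values
    g_ok <- is.finite(gx) & is.finite(gy)
    gx <- gx[g_ok]; gy <- gy[g_ok]
    idx <- ok[g_ok]
    mv <- s$values[idx]; rv <- ref[cbind(ys[idx] + 1, xs[idx] + 1)]
    ab <- stats::lm.fit(cbind(mv, 1), rv)$coefficients  # gain/offset match
    res <- ab[1] * mv + ab[2] - rv
    Jdx <- -(cos(th) * gx - sin(th) * gy)
    Jdy <- -(sin(th) * gx + cos(th) * gy)
    dmx <- (-sin(th) * ux[idx] + cos(th) * uy[idx]) * pi / 180
    dmy <- (-cos(th) * ux[idx] - sin(th) * uy[idx]) * pi / 180
    J <- cbind(Jdx, Jdy, gx * dmx + gy * dmy) * ab[1]
    dp <- tryCatch(solve(crossprod(J), crossprod(J, -res)),
                   error = function(e) NULL)
    if (is.null(dp) || any(!is.finite(dp))) return(list(p = p, ok = FALSE))
    p <- p + as.vector(dp)
    if (sqrt(sum(dp[1:2]^2)) < 1e-4 && abs(dp[3]) < 1e-5) break
  }
  list(p = p, ok = TRUE)
}

# overlap crops of two equal-size images given an integer-rounded shift of
# the transform mapping b onto a
overlap_crops <- function(a, b, d) {
  nr <- nrow(a); nc <- ncol(a)
  dx <- round(d[1]); dy <- round(d[2])
  if (abs(dx) >= nc - 8 || abs(dy) >= nr - 8) return(NULL)
  xs <- max(0, dx):min(nc - 1, nc - 1 + dx)
  ys <- max(0, dy):min(nr - 1, nr - 1 + dy)
  list(a = a[ys + 1, xs + 1, drop = FALSE],
       b = b[ys + 1 - dy, xs + 1 - dx, drop = FALSE])
}

#' Estimate pairwise rigid transforms between all overlapping image pairs
#'
#' For every unordered pair of images whose nominal overlap (from the gaze
#' offsets and field of view) is at least `min_overlap_frac`, estimates the
#' rigid transform mapping image `j` onto image `i` on low-pass-filtered
#' images in four steps: (1) translation by regularized phase correlation,
#' seeded with the nominal gaze offset converted to pixels and searched
#' within `search_radius_px` of the seed; (2) Fourier-Mellin rotation
#' ([estimate_rotation()]) on the translation-aligned overlap crops, where
#' the content of the two images actually coincides; (3) translation of the
#' derotated image; (4) an optional Gauss-Newton polish of all three
#' parameters on the native images. Pair
#' quality is the Pearson correlation of the filtered images over the
#' aligned overlap, so it is ~1 for faithful pairs and near 0 for failures.
#' Low-quality pairs are kept and flagged; the global solve decides what to
#' drop.
#'
#' @param set a [gaze_set()].
#' @param radius_px low-pass filter radius in pixels. The default 25 matches
#'   the native resolution of the rtx1 device (~1500 px across a 4-degree
#'   field); for images at other resolutions scale it proportionally
#'   (e.g. 5 for 300 px fields).
#' @param min_overlap_frac minimum nominal overlap to attempt a pair
#'   (default 0.2).
#' @param upsample subpixel factor for translation refinement (default 10).
#' @param search_radius_px translation search radius around the nominal
#'   seed, in pixels; defaults to 45% of the image width, enough for two
#'   images whose fixation errors pull in opposite directions.
#' @param lambda spectral regularization for the translation stages
#'   (default 0.3); see [phase_correlate()].
#' @param refine_native polish each pair's transform by direct
#'   intensity-based Gauss-Newton minimization on the native (unfiltered)
#'   images (default TRUE); the coarse stages run on the filtered images,
#'   the polish recovers the subpixel/subdegree precision their smoothness
#'   cannot carry.
#' @param kernel low-pass kernel, see [lowpass()].
#' @return data.frame with columns `i`, `j`, `dx_px`, `dy_px`, `theta_deg`,
#'   `quality`, `rot_quality`; the transform maps image `j` onto image `i`.
#' @export
register_pairs <- function(set, radius_px = 25, min_overlap_frac = 0.2,
                           upsample = 10, search_radius_px = NULL,
                           lambda = 0.3, refine_native = TRUE,
                           kernel = "disc") {
  stopifnot(inherits(set, "gaze_set"))
  n <- length(set)
  ppd <- px_per_deg(set)
  gz <- gaze_offsets(set)
  if (is.null(search_radius_px))
    search_radius_px <- round(0.45 * ncol(set$images[[1]]$pixels))
  filt <- lapply(set$images, function(g) lowpass(g$pixels, radius_px, kernel))
  derot <- function(img, th) {
    if (th == 0) return(img)
    out <- rigid_resample(img, 0, 0, th)
    out[is.na(out)] <- mean(out, na.rm = TRUE)
    out
  }
  estimate_one <- function(i, j, seed, srad) {
    pc0 <- phase_correlate(filt[[i]], filt[[j]], upsample = upsample,
                           seed_px = seed, search_radius_px = srad,
                           lambda = lambda)
    d0 <- c(pc0$dx_px, pc0$dy_px)
    oc <- overlap_crops(filt[[i]], filt[[j]], d0)
    rot <- if (is.null(oc)) list(theta_deg = 0, quality = 0)
           else estimate_rotation(oc$a, oc$b)
    theta <- rot$theta_deg
    pc <- phase_correlate(filt[[i]], derot(filt[[j]], theta),
                          upsample = upsample, seed_px = d0,
                          search_radius_px = 20, lambda = lambda)
    d1 <- c(pc$dx_px, pc$dy_px)
    if (refine_native) {
      gn <- refine_pair_native(set$images[[i]]$pixels,
                               set$images[[j]]$pixels, d1, theta)
      if (gn$ok && sqrt(sum((gn$p[1:2] - d1)^2)) < 10 &&
          abs(gn$p[3] - theta) < 2) {
        d1 <- gn$p[1:2]; theta <- gn$p[3]
      }
    }
    # quality: Pearson correlation over the aligned overlap
    movf <- derot(filt[[j]], theta)
    oc2 <- overlap_crops(filt[[i]], movf, d1)
    q <- if (is.null(oc2)) 0 else
      suppressWarnings(stats::cor(as.vector(oc2$a), as.vector(oc2$b)))
    if (!is.finite(q)) q <- 0
    data.frame(i = i, j = j, dx_px = d1[1], dy_px = d1[2],
               theta_deg = theta, quality = max(q, 0),
               rot_quality = rot$quality)
  }
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dg <- gz[j, ] - gz[i, ]
      if (overlap_fraction(set$fov_deg, dg[1], dg[2]) < min_overlap_frac) next
      seed <- dg * ppd
      est <- estimate_one(i, j, seed, search_radius_px)
      if (est$quality < 0.4) {
        # the data disagree with the nominal prior; retry with an
        # unrestricted search and keep the better-supported estimate
        est2 <- estimate_one(i, j, seed, NULL)
        if (est2$quality > est$quality) est <- est2
      }
      rows[[length(rows) + 1]] <- est
    }
  }
  do.call(rbind, rows)
}

# connected components of the pair graph restricted to retained pairs
graph_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$i[k]; b <- edges$j[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Solve per-image transforms from pairwise estimates by weighted least
#' squares
#'
#' Generalizes averaging of pairwise offsets to a quality-weighted linear
#' least-squares consensus over the whole pair graph: rotations are solved
#' from the difference constraints `theta_j - theta_i = theta_ij`, then
#' translations from `t_j - t_i = R(theta_i) d_ij`. The anchor image is
#' fixed at the identity. Pairs with quality below `q_min` are dropped; if
#' the remaining graph does not connect every image to the anchor the
#' registration fails (the typical clinical failure mode of inaccurate
#' fixation or poor image quality).
#'
#' @param pairs data.frame from [register_pairs()].
#' @param n_images number of images in the set.
#' @param anchor index of the image fixed at the identity (default 1).
#' @param q_min minimum pair quality retained (default 0.1).
#' @param max_trim_rounds robust re-solve rounds: after each solve, pairs
#'   whose residual is far outside the consensus (more than 5x the median
#'   residual, and above 1 px or 0.15 degrees) are dropped and the system
#'   re-solved, provided the graph stays connected. Set 0 to disable.
#' @return an object of class `registration_result`: list with `transforms`
#'   (data.frame `dx_px`, `dy_px`, `theta_deg`, one row per image), `anchor`,
#'   `used_pairs`, `success`, `failure_reason`, `residual_rms_px`.
#' @export
solve_global <- function(pairs, n_images, anchor = 1, q_min = 0.1,
                         max_trim_rounds = 6) {
  keep <- pairs[pairs$quality >= q_min, , drop = FALSE]
  fail <- function(reason) {
    structure(list(transforms = NULL, anchor = anchor, used_pairs = keep,
                   success = FALSE, failure_reason = reason,
                   residual_rms_px = NA_real_),
              class = "registration_result")
  }
  if (nrow(keep) == 0) return(fail("insufficient overlap/quality"))
  comp <- graph_components(n_images, keep)
  if (length(unique(comp)) > 1) {
    orphans <- which(comp != comp[anchor])
    return(fail(paste0("insufficient overlap/quality: image(s) ",
                       paste(orphans, collapse = ", "),
                       " disconnected from anchor")))
  }
  free <- setdiff(seq_len(n_images), anchor)
  solve_once <- function(keep) {
    m <- nrow(keep)
    w <- keep$quality
    A <- matrix(0, m, length(free))
    for (k in seq_len(m)) {
      ji <- match(keep$j[k], free); ii <- match(keep$i[k], free)
      if (!is.na(ji)) A[k, ji] <- 1
      if (!is.na(ii)) A[k, ii] <- -1
    }
    wls <- function(b) stats::lm.wfit(A, b, w)$coefficients
    theta <- numeric(n_images)
    theta[free] <- wls(keep$theta_deg)
    # translation constraints with the solved rotations folded in
    d <- t(vapply(seq_len(m), function(k) {
      rot2(theta[keep$i[k]]) %*% c(keep$dx_px[k], keep$dy_px[k])
    }, numeric(2)))
    tx <- numeric(n_images); ty <- numeric(n_images)
    tx[free] <- wls(d[, 1])
    ty[free] <- wls(d[, 2])
    res_t <- sqrt((A %*% tx[free] - d[, 1])^2 + (A %*% ty[free] - d[, 2])^2)
    res_th <- abs(A %*% theta[free] - keep$theta_deg)
    list(theta = theta, tx = tx, ty = ty,
         res_t = as.vector(res_t), res_th = as.vector(res_th))
  }
  sol <- solve_once(keep)
  for (round in seq_len(max_trim_rounds)) {
    # one outlier at a time: a single bad pair inflates the residuals of
    # every pair sharing its images, so mass-trimming would disconnect them
    excess <- pmax(sol$res_t / pmax(1, 5 * stats::median(sol$res_t)),
                   sol$res_th / pmax(0.15, 5 * stats::median(sol$res_th)))
    if (max(excess) <= 1 || nrow(keep) <= length(free)) break
    dropped <- FALSE
    for (k in order(excess, decreasing = TRUE)) {
      if (excess[k] <= 1) break
      trial <- keep[-k, , drop = FALSE]
      if (length(unique(graph_components(n_images, trial))) == 1) {
        keep <- trial
        sol <- solve_once(keep)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  transforms <- data.frame(dx_px = sol$tx, dy_px = sol$ty,
                           theta_deg = sol$theta)
  structure(list(transforms = transforms, anchor = anchor, used_pairs = keep,
                 success = TRUE, failure_reason = NULL,
                 residual_rms_px = sqrt(mean(sol$res_t^2))),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  if (!x$success) {
    cat("registration_result: FAILED -", x$failure_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("registration_result: %d images, anchor %d, %d pairs used, residual RMS %.3f px\n",
              nrow(x$transforms), x$anchor, nrow(x$used_pairs),
              x$residual_rms_px))
  tr <- x$transforms
  for (i in seq_len(nrow(tr)))
    cat(sprintf("  img %d: dx %+8.2f  dy %+8.2f  theta %+6.3f deg\n",
                i, tr$dx_px[i], tr$dy_px[i], tr$theta_deg[i]))
  invisible(x)
}

# relative transform (j onto i) implied by a set of global transforms
implied_pair <- function(tr, i, j) {
  Ri <- rot2(-tr$theta_deg[i])
  d <- Ri %*% c(tr$dx_px[j] - tr$dx_px[i], tr$dy_px[j] - tr$dy_px[i])
  c(d[1], d[2], tr$theta_deg[j] - tr$theta_deg[i])
}

#' Register a full gaze set (pairs + global solve + consensus repair)
#'
#' Runs [register_pairs()] and [solve_global()], then gives pairs that
#' disagree with the global consensus a second chance: each such pair is
#' re-estimated with the consensus relative transform as seed (tight
#' translation search, consensus rotation, Gauss-Newton polish) and the
#' system is re-solved. A pair whose first estimate locked onto a spurious
#' correlation peak - typically when a large inter-image rotation smears
#' the translation peak - is usually recovered this way. The anchor
#' defaults to the image whose gaze offset is closest to (0, 0), the
#' central fixation image of the standard protocol.
#'
#' @inheritParams register_pairs
#' @inheritParams solve_global
#' @param anchor anchor image index, or `NULL` to pick the most central gaze.
#' @param repair_rounds consensus re-estimation rounds (default 2; 0
#'   disables).
#' @return a `registration_result`.
#' @export
register_gaze_set <- function(set, radius_px = 25, min_overlap_frac = 0.2,
                              upsample = 10, q_min = 0.1, anchor = NULL,
                              repair_rounds = 2, kernel = "disc") {
  if (is.null(anchor)) {
    gz <- gaze_offsets(set)
    anchor <- unname(which.min(gz[, 1]^2 + gz[, 2]^2))
  }
  pairs <- register_pairs(set, radius_px = radius_px,
                          min_overlap_frac = min_overlap_frac,
                          upsample = upsample, kernel = kernel)
  res <- solve_global(pairs, length(set), anchor = anchor, q_min = q_min)
  for (round in seq_len(repair_rounds)) {
    if (!res$success) break
    pred <- t(vapply(seq_len(nrow(pairs)), function(k) {
      implied_pair(res$transforms, pairs$i[k], pairs$j[k])
    }, numeric(3)))
    dev_t <- sqrt((pairs$dx_px - pred[, 1])^2 + (pairs$dy_px - pred[, 2])^2)
    dev_th <- abs(pairs$theta_deg - pred[, 3])
    flagged <- which(dev_t > 2 | dev_th > 0.3)
    if (length(flagged) == 0) break
    for (k in flagged) {
      i <- pairs$i[k]; j <- pairs$j[k]
      gn <- refine_pair_native(set$images[[i]]$pixels,
                               set$images[[j]]$pixels,
                               pred[k, 1:2], pred[k, 3])
      if (!gn$ok) next
      pairs$dx_px[k] <- gn$p[1]; pairs$dy_px[k] <- gn$p[2]
      pairs$theta_deg[k] <- gn$p[3]
      filt_i <- lowpass(set$images[[i]]$pixels, radius_px, kernel)
      filt_j <- lowpass(set$images[[j]]$pixels, radius_px, kernel)
      mv <- if (gn$p[3] != 0) {
        m <- rigid_resample(filt_j, 0, 0, gn$p[3])
        m[is.na(m)] <- mean(m, na.rm = TRUE); m
      } else filt_j
      oc <- overlap_crops(filt_i, mv, gn$p[1:2])
      q <- if (is.null(oc)) 0 else
        suppressWarnings(stats::cor(as.vector(oc$a), as.vector(oc$b)))
      pairs$quality[k] <- if (is.finite(q)) max(q, 0) else 0
    }
    res <- solve_global(pairs, length(set), anchor = anchor, q_min = q_min)
  }
  res
}

#' Re-express a registration result relative to a different anchor
#'
#' @param result a successful `registration_result`.
#' @param anchor new anchor index.
#' @return a `registration_result` with the new anchor at the identity.
#' @export
reanchor <- function(result, anchor) {
  stopifnot(inherits(result, "registration_result"), result$success)
  tr <- result$transforms
  # compose with the inverse of the new anchor's transform
  th0 <- tr$theta_deg[anchor]
  t0 <- c(tr$dx_px[anchor], tr$dy_px[anchor])
  R0i <- rot2(-th0)
  out <- tr
  for (k in seq_len(nrow(tr))) {
    out$theta_deg[k] <- tr$theta_deg[k] - th0
    v <- R0i %*% (c(tr$dx_px[k], tr$dy_px[k]) - t0)
    out$dx_px[k] <- v[1]; out$dy_px[k] <- v[2]
  }
  result$transforms <- out
  result$anchor <- anchor
  result
}

#' Serialize a registration result to JSON
#'
#' @param result a `registration_result`.
#' @param path output path.
#' @param ids optional character vector of image ids.
#' @return `path`, invisibly.
#' @export
write_registration <- function(result, path, ids = NULL) {
  obj <- list(success = result$success,
              failure_reason = result$failure_reason,
              anchor = result$anchor,
              residual_rms_px = result$residual_rms_px,
              transforms = if (is.null(result$transforms)) NULL else
                cbind(id = if (is.null(ids)) seq_len(nrow(result$transforms))
                      else ids, result$transforms),
              pairs = result$used_pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Resample registered images onto a common expanded canvas
#'
#' The canvas is the union of all transformed image footprints, expressed in
#' the anchor image's coordinate frame (the central image of the protocol
#' stays centered). Each native, unfiltered image is resampled into the
#' canvas with bilinear interpolation; canvas pixels with no source data are
#' NA, and border pixels whose bilinear support is incomplete are also NA so
#' that no defined pixel draws on undefined data.
#'
#' @param set a [gaze_set()].
#' @param result a successful `registration_result` for `set`.
#' @return an object of class `registered_stack`: list with `layers` (3-D
#'   array, canvas rows x cols x images, NA = undefined), `canvas_origin`
#'   (anchor-frame 0-based (x, y) of canvas pixel (0, 0)), `anchor`, `ids`,
#'   and the set's `fov_deg`/`scale_um_per_px`.
#' @export
assemble_stack <- function(set, result) {
  stopifnot(inherits(set, "gaze_set"),
            inherits(result, "registration_result"))
  if (!result$success)
    stop("assemble_stack: registration failed: ", result$failure_reason)
  n <- length(set)
  img1 <- set$images[[1]]$pixels
  nr <- nrow(img1); nc <- ncol(img1)
  ctr <- img_center(img1)
  tr <- result$transforms
  corners <- cbind(x = c(0, nc - 1, 0, nc - 1), y = c(0, 0, nr - 1, nr - 1))
  all_pts <- do.call(rbind, lapply(seq_len(n), function(k) {
    p <- t(rot2(tr$theta_deg[k]) %*% t(sweep(corners, 2, ctr)))
    sweep(p, 2, c(ctr[1] + tr$dx_px[k], ctr[2] + tr$dy_px[k]), "+")
  }))
  x0 <- floor(min(all_pts[, 1])); x1 <- ceiling(max(all_pts[, 1]))
  y0 <- floor(min(all_pts[, 2])); y1 <- ceiling(max(all_pts[, 2]))
  cw <- x1 - x0 + 1; ch <- y1 - y0 + 1
  qx <- rep(0:(cw - 1), each = ch) + x0   # anchor-frame coords
  qy <- rep(0:(ch - 1), times = cw) + y0
  layers <- array(NA_real_, dim = c(ch, cw, n))
  for (k in seq_len(n)) {
    Ri <- rot2(-tr$theta_deg[k])
    ux <- qx - ctr[1] - tr$dx_px[k]
    uy <- qy - ctr[2] - tr$dy_px[k]
    sx <- Ri[1, 1] * ux + Ri[1, 2] * uy + ctr[1]
    sy <- Ri[2, 1] * ux + Ri[2, 2] * uy + ctr[2]
    s <- bilinear_sample(set$images[[k]]$pixels, sx, sy)
    layers[, , k] <- matrix(s$values, ch, cw)
  }
  structure(list(layers = layers, canvas_origin = c(x0, y0),
                 anchor = result$anchor,
                 ids = vapply(set$images, function(g) g$id, character(1)),
                 fov_deg = set$fov_deg,
                 scale_um_per_px = set$scale_um_per_px),
            class = "registered_stack")
}

#' Build a registered stack directly from co-registered arrays
#'
#' For data that is already aligned (e.g. directional-imaging series), wraps
#' a list of equal-size matrices as a fully defined `registered_stack`.
#'
#' @param layers list of numeric matrices with identical dimensions.
#' @param scale_um_per_px physical scale (default 0.77).
#' @return a `registered_stack`.
#' @export
stack_from_layers <- function(layers, scale_um_per_px = 0.77) {
  if (length(layers) < 1) stop("stack_from_layers: need at least one layer")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("stack_from_layers: layer dimensions differ")
  arr <- array(unlist(layers), dim = c(dims[1, 1], dims[2, 1], length(layers)))
  structure(list(layers = arr, canvas_origin = c(0, 0), anchor = 1L,
                 ids = as.character(seq_along(layers)), fov_deg = NA_real_,
                 scale_um_per_px = scale_um_per_px),
            class = "registered_stack")
}

#' Per-pixel coverage of a registered stack
#'
#' @param stack a `registered_stack`.
#' @return integer matrix counting the defined layers at each canvas pixel.
#' @export
coverage_map <- function(stack) {
  stopifnot(inherits(stack, "registered_stack"))
  rowSums(!is.na(stack$layers), dims = 2)
}

#' @export
print.registered_stack <- function(x, ...) {
  d <- dim(x$layers)
  cov <- coverage_map(x)
  cat(sprintf("registered_stack: %d layers on a %d x %d canvas (origin %g, %g)\n",
              d[3], d[1], d[2], x$canvas_origin[1], x$canvas_origin[2]))
  cat(sprintf("  coverage: min %d, max %d, mean %.2f\n",
              min(cov), max(cov), mean(cov)))
  invisible(x)
}
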