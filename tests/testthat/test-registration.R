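test_that("lowpass matches a direct convolution oracle", {
  # constant image is a fixed point of any normalized low-pass kernel
  const <- matrix(4.2, 30, 30)
  expect_equal(lowpass(const, 7), const)
  expect_equal(lowpass(const, 3, kernel = "gaussian"), const)

  # brute-force convolution with reflect padding on a small noisy image
  set.seed(7)
  img <- matrix(rnorm(24 * 24), 24, 24)
  r <- 3
  off <- -r:r
  k <- (outer(off^2, off^2, "+") <= r^2) * 1
  k <- k / sum(k)
  ref_idx <- function(i, n) {          # reflect (edge-mirrored) indexing
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  oracle <- matrix(0, 24, 24)
  for (y in 1:24) for (x in 1:24) {
    acc <- 0
    for (dy in off) for (dx in off) {
      acc <- acc + k[dy + r + 1, dx + r + 1] *
        img[ref_idx(y + dy, 24), ref_idx(x + dx, 24)]
    }
    oracle[y, x] <- acc
  }
  expect_equal(lowpass(img, r), oracle, tolerance = 1e-12)

  expect_error(lowpass(img, 13), "radius exceeds")
})

test_that("phase correlation recovers exact, integer and subpixel shifts", {
  img <- smooth_field(128, sigma = 2, seed = 42)
  set.seed(43)
  img <- img + rnorm(length(img), 0, 1e-3)  # keep the full spectrum alive

  self <- phase_correlate(img, img)
  expect_equal(c(self$dx_px, self$dy_px), c(0, 0))
  expect_gt(self$quality, 0.9)

  shifted <- circ_shift(img, -7, 3)  # mov needs (+7, -3) to align
  pc <- phase_correlate(img, shifted)
  expect_identical(c(pc$dx_px, pc$dy_px), c(7, -3))

  # subpixel shift created by resampling, recovered with upsampling
  mov <- gazefuse:::rigid_resample(img, -2.5, 0, 0)
  mov[is.na(mov)] <- mean(mov, na.rm = TRUE)
  pc2 <- phase_correlate(img, mov, upsample = 10)
  expect_lt(abs(pc2$dx_px - 2.5), 0.25)
  expect_lt(abs(pc2$dy_px), 0.25)

  expect_error(phase_correlate(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
  expect_error(phase_correlate(img, img[1:64, ]), "dimensions")
})

test_that("Fourier-Mellin rotation estimation recovers small rotations", {
  img <- smooth_field(128, sigma = 2, seed = 42)

  self <- estimate_rotation(img, img)
  expect_lt(abs(self$theta_deg), 0.1)
  expect_false(self$low_quality)
  expect_equal(self$scale, 1, tolerance = 0.05)

  for (th in c(1.5, -3)) {
    mov <- gazefuse:::rigid_resample(img, 0, 0, -th)  # transform rotation th
    mov[is.na(mov)] <- mean(mov, na.rm = TRUE)
    est <- estimate_rotation(img, mov)
    expect_lt(abs(est$theta_deg - th), 0.2)
    expect_true(est$theta_deg > -45 && est$theta_deg <= 45)
  }

  # rotation followed by translation: two-stage recovery
  mov <- gazefuse:::rigid_resample(img, -5, -5, -1)
  mov[is.na(mov)] <- mean(mov, na.rm = TRUE)
  est <- estimate_rotation(img, mov)
  expect_lt(abs(est$theta_deg - 1), 0.2)
  der <- gazefuse:::rigid_resample(mov, 0, 0, est$theta_deg)
  der[is.na(der)] <- mean(der, na.rm = TRUE)
  pc <- phase_correlate(img, der, upsample = 10)
  expect_lt(abs(pc$dx_px - 5), 0.5)
  expect_lt(abs(pc$dy_px - 5), 0.5)

  expect_error(estimate_rotation(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
})

test_that("overlap_fraction reproduces the protocol geometry", {
  expect_equal(overlap_fraction(4, 2, 0), 0.5)
  expect_equal(overlap_fraction(4, 2, 2), 0.25)
  expect_equal(overlap_fraction(4, 0, 0), 1)
  expect_equal(overlap_fraction(4, 4, 0), 0)
  # symmetry and monotonicity over a grid of offsets
  for (dx in seq(0, 5, by = 0.5)) for (dy in seq(0, 5, by = 0.5)) {
    f <- overlap_fraction(4, dx, dy)
    expect_equal(f, overlap_fraction(4, -dx, dy))
    expect_equal(f, overlap_fraction(4, dx, -dy))
    expect_equal(f, overlap_fraction(4, dy, dx))
    expect_gte(f, overlap_fraction(4, dx + 0.5, dy))
    expect_gte(f, overlap_fraction(4, dx, dy + 0.5))
  }
})

test_that("pair enumeration follows the overlap-geometry oracle", {
  sim <- tiny_protocol_sim()
  pairs <- register_pairs(sim$set, radius_px = 3)
  # oracle: enumerate admissible pairs directly from the gaze geometry
  gz <- gaze_offsets(sim$set)
  want <- list()
  for (i in 1:8) for (j in (i + 1):9) {
    if (overlap_fraction(4, gz[j, 1] - gz[i, 1], gz[j, 2] - gz[i, 2]) >= 0.2)
      want[[length(want) + 1]] <- c(i, j)
  }
  expect_equal(nrow(pairs), length(want))
  expect_equal(unname(as.matrix(pairs[, c("i", "j")])),
               do.call(rbind, want))
  # with zero acquisition jitter, estimates match the nominal offsets
  ppd <- px_per_deg(sim$set)
  for (k in seq_len(nrow(pairs))) {
    nominal <- (gz[pairs$j[k], ] - gz[pairs$i[k], ]) * ppd
    expect_lt(abs(pairs$dx_px[k] - nominal[1]), 0.3)
    expect_lt(abs(pairs$dy_px[k] - nominal[2]), 0.3)
    expect_lt(abs(pairs$theta_deg[k]), 0.1)
  }
})

test_that("identical content overrides the nominal gaze prior", {
  img <- smooth_field(128, sigma = 3, seed = 9)
  set <- gaze_set(list(gaze_image(img, c(0, 0), "a"),
                       gaze_image(img, c(2, 0), "b")))
  pairs <- register_pairs(set, radius_px = 3)
  expect_lt(abs(pairs$dx_px), 0.1)
  expect_lt(abs(pairs$dy_px), 0.1)
  expect_lt(abs(pairs$theta_deg), 0.1)
  expect_gt(pairs$quality, 0.9)
})

test_that("global solve reproduces consistent pairs and flags disconnection", {
  # exactly consistent pairwise offsets -> exact recovery
  truth <- data.frame(dx_px = c(0, 10, -5, 20), dy_px = c(0, -3, 7, 1),
                      theta_deg = c(0, 0.5, -0.25, 1))
  mk_pairs <- function(q = 1) {
    rows <- list()
    for (i in 1:3) for (j in (i + 1):4) {
      d <- gazefuse:::rot2(-truth$theta_deg[i]) %*%
        c(truth$dx_px[j] - truth$dx_px[i], truth$dy_px[j] - truth$dy_px[i])
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = j, dx_px = d[1], dy_px = d[2],
        theta_deg = truth$theta_deg[j] - truth$theta_deg[i],
        quality = q, rot_quality = q)
    }
    do.call(rbind, rows)
  }
  res <- solve_global(mk_pairs(), 4, anchor = 1)
  expect_true(res$success)
  expect_equal(res$transforms$dx_px, truth$dx_px, tolerance = 1e-8)
  expect_equal(res$transforms$dy_px, truth$dy_px, tolerance = 1e-8)
  expect_equal(res$transforms$theta_deg, truth$theta_deg, tolerance = 1e-8)
  expect_lt(res$residual_rms_px, 1e-8)

  # noisy offsets: Monte-Carlo recovery within 0.5 px RMS
  set.seed(123)
  rmses <- replicate(20, {
    noisy <- mk_pairs()
    noisy$dx_px <- noisy$dx_px + rnorm(nrow(noisy), 0, 0.5)
    noisy$dy_px <- noisy$dy_px + rnorm(nrow(noisy), 0, 0.5)
    r <- solve_global(noisy, 4, anchor = 1, max_trim_rounds = 0)
    sqrt(mean((r$transforms$dx_px - truth$dx_px)^2 +
              (r$transforms$dy_px - truth$dy_px)^2))
  })
  expect_lt(mean(rmses), 0.5)

  # an image whose pairs all fall below q_min disconnects the graph
  bad <- mk_pairs()
  bad$quality[bad$i == 4 | bad$j == 4] <- 0.01
  res_bad <- solve_global(bad, 4, anchor = 1)
  expect_false(res_bad$success)
  expect_match(res_bad$failure_reason, "disconnected")
})

test_that("relative transforms are anchor-invariant", {
  run <- default_phantom_run()
  res <- run$pipe$registration
  re2 <- reanchor(res, 5)
  # the pairwise relative transform j->i must not depend on the anchor
  rel <- function(r, i, j) {
    Ri <- gazefuse:::rot2(-r$transforms$theta_deg[i])
    d <- Ri %*% c(r$transforms$dx_px[j] - r$transforms$dx_px[i],
                  r$transforms$dy_px[j] - r$transforms$dy_px[i])
    c(d, r$transforms$theta_deg[j] - r$transforms$theta_deg[i])
  }
  for (pr in list(c(1, 5), c(2, 7), c(3, 9))) {
    expect_equal(rel(res, pr[1], pr[2]), rel(re2, pr[1], pr[2]),
                 tolerance = 1e-6)
  }
  expect_equal(re2$transforms$dx_px[5], 0)
  expect_equal(re2$transforms$theta_deg[5], 0)
})

test_that("canvas assembly matches the rectangle-geometry oracle", {
  sim <- tiny_protocol_sim()
  reg <- register_gaze_set(sim$set, radius_px = 3)
  expect_true(reg$success)
  stack <- assemble_stack(sim$set, reg)
  cov <- coverage_map(stack)
  w <- nrow(sim$set$images[[1]]$pixels)
  ppd <- px_per_deg(sim$set)

  # canvas spans the union of the 9 fields: 8 degrees on each side
  expect_equal(dim(cov), c(2L, 2L) * w, tolerance = 0.05)

  # analytic coverage oracle from rectangle intersections (zero jitter, so
  # transforms are the nominal integer shifts); pixels within 2 px of any
  # rectangle edge are excluded, since there the conservative
  # bilinear-support rule legitimately differs from the ideal geometry
  gz <- gaze_offsets(sim$set)
  x0 <- stack$canvas_origin[1]; y0 <- stack$canvas_origin[2]
  xs <- col(cov) - 1 + x0
  ys <- row(cov) - 1 + y0
  oracle <- matrix(0L, nrow(cov), ncol(cov))
  decided <- matrix(TRUE, nrow(cov), ncol(cov))
  for (k in 1:9) {
    dx <- gz[k, 1] * ppd; dy <- gz[k, 2] * ppd
    deep_in <- xs > dx + 2 & xs < dx + w - 3 & ys > dy + 2 & ys < dy + w - 3
    deep_out <- xs < dx - 2 | xs > dx + w + 1 | ys < dy - 2 | ys > dy + w + 1
    oracle <- oracle + deep_in
    decided <- decided & (deep_in | deep_out)
  }
  expect_gt(mean(decided), 0.5)
  expect_true(all(oracle[decided] == cov[decided]))
  # the four canvas corners are covered by exactly one image
  expect_equal(cov[3, 3], 1)
  expect_equal(cov[nrow(cov) - 2, ncol(cov) - 2], 1)

  # single-layer stack: canvas equals the image, fully defined
  single <- stack_from_layers(list(sim$set$images[[1]]$pixels))
  expect_equal(dim(single$layers)[1:2], dim(sim$set$images[[1]]$pixels))
  expect_true(all(coverage_map(single) == 1))
})

test_that("registering a set against itself yields identity transforms", {
  img <- smooth_field(96, sigma = 2.5, seed = 4)
  grid <- protocol_grid()
  set <- gaze_set(lapply(1:9, function(k) gaze_image(img, grid[k, ],
                                                     sprintf("p%d", k))))
  reg <- register_gaze_set(set, radius_px = 3)
  expect_true(reg$success)
  expect_lt(max(abs(reg$transforms$dx_px)), 0.1)
  expect_lt(max(abs(reg$transforms$dy_px)), 0.1)
  expect_lt(max(abs(reg$transforms$theta_deg)), 0.1)
})

test_that("registration results serialize to JSON", {
  run <- default_phantom_run()
  p <- file.path(withr::local_tempdir(), "reg.json")
  write_registration(run$pipe$registration, p,
                     ids = vapply(run$sim$set$images, function(g) g$id,
                                  character(1)))
  obj <- jsonlite::read_json(p)
  expect_true(obj$success)
  expect_equal(length(obj$transforms), 9)
  expect_equal(obj$anchor, unname(run$pipe$registration$anchor))
})
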