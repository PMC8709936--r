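test_that("phantom generation is deterministic and respects lesion ranges", {
  p1 <- make_phantom(n_drusen = 20, n_sdd = 2, n_atrophy = 1,
                     diameter_range_um = c(11, 320), seed = 42)
  p2 <- make_phantom(n_drusen = 20, n_sdd = 2, n_atrophy = 1,
                     diameter_range_um = c(11, 320), seed = 42)
  expect_identical(p1$master, p2$master)
  expect_identical(p1$lesions, p2$lesions)

  expect_equal(sum(p1$lesions$kind == "druse"), 20)
  expect_true(all(p1$lesions$diameter_um >= 11 &
                  p1$lesions$diameter_um <= 320))
  expect_true(all(p1$lesions$polarity[p1$lesions$kind == "druse"] == 1))
  expect_true(all(p1$lesions$polarity[p1$lesions$kind == "sdd"] == -1))
  expect_true(all(p1$lesions$modulation_amplitude[p1$lesions$kind == "atrophy"] == 0))
  # SDDs get lower modulation amplitude than drusen
  expect_true(all(p1$lesions$modulation_amplitude[p1$lesions$kind == "sdd"] == 0.25))

  expect_error(make_phantom(diameter_range_um = c(5, 100)), "11")

  empty <- make_phantom(0, 0, 0, seed = 1)
  expect_equal(nrow(empty$lesions), 0)
})

test_that("rendered rims follow the gaze-modulation model", {
  params0 <- acquisition_params(fixation_sigma_deg = 0, rotation_range_deg = 0,
                                gain_jitter = 0, offset_jitter = 0,
                                noise_sigma = 0, seed = 1)

  # lesion at the window center: zero eccentricity, isotropic rim
  ph <- phantom_with_lesions("druse", 0, 0, 60)
  set.seed(1)
  r <- render_gaze_image(ph, c(0, 0), params = params0)
  geo <- gazefuse:::lesion_geometry(ph, ph$lesions[1, ])
  w <- nrow(r$image$pixels)
  pl <- data.frame(cx_px = (w - 1) / 2, cy_px = (w - 1) / 2,
                   r_peak_px = geo$r_peak, rim_sigma_px = geo$sigma,
                   psi_rad = 0)
  h <- rim_half_means(r$image$pixels, pl)
  expect_equal(unname(h["near"]), unname(h["far"]), tolerance = 1e-6)

  # druse toward the right field edge: right rim brighter than left
  ph_r <- phantom_with_lesions("druse", 1.4, 0, 60)
  set.seed(1)
  rr <- render_gaze_image(ph_r, c(0, 0), params = params0)
  pl_r <- pl
  pl_r$cx_px <- (w - 1) / 2 + 1.4 * ph_r$px_per_deg
  h_r <- rim_half_means(rr$image$pixels, pl_r)  # psi = 0 points right
  expect_gt(h_r["near"], h_r["far"])

  # SDD in the same position: inverted polarity, right rim darker
  ph_s <- phantom_with_lesions("sdd", 1.4, 0, 60)
  set.seed(1)
  rs <- render_gaze_image(ph_s, c(0, 0), params = params0)
  h_s <- rim_half_means(rs$image$pixels, pl_r)
  expect_lt(h_s["near"], h_s["far"])
})

test_that("zero-jitter simulation reproduces the nominal protocol exactly", {
  sim <- tiny_protocol_sim()
  tt <- sim$truth$transforms
  gz <- gaze_offsets(sim$set)
  ppd <- px_per_deg(sim$set)
  expect_equal(tt$dx_px, unname(gz[, 1] * ppd))
  expect_equal(tt$dy_px, unname(gz[, 2] * ppd))
  expect_true(all(tt$theta_deg == 0))

  # adjacent cardinal pairs share 50% nominal overlap, diagonal 25%
  expect_equal(overlap_fraction(sim$set$fov_deg, 2, 0), 0.5)
  expect_equal(overlap_fraction(sim$set$fov_deg, 2, 2), 0.25)

  sim2 <- tiny_protocol_sim()
  expect_identical(sim$set$images[[4]]$pixels, sim2$set$images[[4]]$pixels)
})

test_that("margin polarity holds in every rendered image of a lesion phantom", {
  ph <- make_phantom(n_drusen = 2, n_sdd = 2, n_atrophy = 0,
                     diameter_range_um = c(40, 60), background = "flat",
                     seed = 5)
  sim <- simulate_gaze_set(ph, params = acquisition_params(seed = 5))
  w <- nrow(sim$set$images[[1]]$pixels)
  tested <- 0
  for (k in seq_along(sim$set$images)) {
    img <- sim$set$images[[k]]$pixels
    pls <- project_lesions_image(sim$truth, k)
    for (li in seq_len(nrow(pls))) {
      pl <- pls[li, ]
      if (pl$confluent || pl$e < 0.15 || pl$e > 0.95) next
      margin <- pl$r_out_px + 3 * pl$rim_sigma_px
      if (pl$cx_px < margin || pl$cx_px > w - 1 - margin ||
          pl$cy_px < margin || pl$cy_px > w - 1 - margin) next
      h <- rim_half_means(img, pl)
      tested <- tested + 1
      if (pl$kind == "druse") expect_gt(h["near"], h["far"])
      else expect_lt(h["near"], h["far"])
    }
  }
  expect_gt(tested, 5)
})

test_that("rendered druse geometry matches the lesion table", {
  params0 <- acquisition_params(fixation_sigma_deg = 0, rotation_range_deg = 0,
                                gain_jitter = 0, offset_jitter = 0,
                                noise_sigma = 0, seed = 1)
  d_um <- 60
  ph <- phantom_with_lesions("druse", 0, 0, d_um)
  set.seed(1)
  r <- render_gaze_image(ph, c(0, 0), params = params0)
  img <- r$image$pixels - 0.5
  w <- nrow(img); ctr <- (w - 1) / 2
  xs <- rep(0:(w - 1), each = w) - ctr
  ys <- rep(0:(w - 1), times = w) - ctr
  rad <- sqrt(xs^2 + ys^2)
  prof <- vapply(seq(0.5, 60, by = 0.5), function(r0) {
    mean(img[matrix(abs(rad - r0) < 0.5, w, w)])
  }, numeric(1))
  radii <- seq(0.5, 60, by = 0.5)
  peak <- max(prof)
  # outermost radius where the rim still reaches half its peak height
  r_out_meas <- max(radii[prof >= peak / 2])
  r_out_true <- (d_um / ph$scale_um_per_px) / 2
  expect_lt(abs(r_out_meas - r_out_true), 1)   # 1 px fidelity
  # innermost half-maximum radius gives the annulus ratio
  rim_band <- radii > 5
  r_in_meas <- min(radii[rim_band][prof[rim_band] >= peak / 2])
  expect_equal(r_in_meas / r_out_meas, ph$annulus_ratio, tolerance = 0.05)
})

test_that("directional rendering keeps the field fixed and is aligned", {
  ph <- phantom_with_lesions("druse", 1, 0.5, 60)
  imgs <- simulate_directional_set(ph, params = acquisition_params(seed = 3))
  expect_equal(length(imgs), 5)
  expect_true(all(vapply(imgs, function(m) all(dim(m) == dim(imgs[[1]])),
                         logical(1))))
  # beams displace illumination, not fixation: the lesion stays put, so a
  # noiseless pair differs only by the rim modulation, not by translation
  ph0 <- phantom_with_lesions("druse", 1, 0.5, 60)
  imgs0 <- simulate_directional_set(
    ph0, params = acquisition_params(gain_jitter = 0, offset_jitter = 0,
                                     noise_sigma = 0, seed = 3))
  d <- abs(imgs0[[2]] - imgs0[[1]])
  expect_lt(mean(d > 1e-9), 0.2)   # differences confined to the rim region
})
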