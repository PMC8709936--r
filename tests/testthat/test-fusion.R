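test_that("per-pixel fusion statistics match hand computations", {
  # three constant layers carrying the canonical value triple {1, 3, 7}
  st <- stack_of(matrix(1, 4, 4), matrix(3, 4, 4), matrix(7, 4, 4))
  expect_equal(fuse(st, "sum")$values, matrix(11, 4, 4))
  expect_equal(fuse(st, "mean")$values, matrix(11 / 3, 4, 4))
  expect_equal(fuse(st, "variance")$values, matrix(28 / 3, 4, 4),
               tolerance = 1e-12)   # sample variance of {1,3,7}
  expect_equal(fuse(st, "sd")$values, matrix(sqrt(28 / 3), 4, 4))
  # |mean pairwise deviation product| = variance / n
  expect_equal(fuse(st, "covariance")$values, matrix(28 / 9, 4, 4),
               tolerance = 1e-12)
  expect_equal(fuse(st, "max_pair_sd")$values, matrix(6 / sqrt(2), 4, 4))

  # brute force over the three pairs confirms the covariance identity
  x <- c(1, 3, 7); mu <- mean(x)
  pairs <- combn(3, 2)
  cov_brute <- abs(mean(apply(pairs, 2, function(p)
    (x[p[1]] - mu) * (x[p[2]] - mu))))
  expect_equal(cov_brute, 28 / 9, tolerance = 1e-12)
  sd_brute <- max(apply(pairs, 2, function(p) abs(x[p[1]] - x[p[2]]) / sqrt(2)))
  expect_equal(sd_brute, 6 / sqrt(2))

  idem <- stack_of(matrix(2, 3, 3), matrix(2, 3, 3), matrix(2, 3, 3))
  expect_true(all(fuse(idem, "sd")$values == 0))

  expect_error(fuse(st, "median"), "unknown statistic")
})

test_that("coverage minima make under-covered pixels undefined", {
  a <- matrix(1, 3, 3); b <- matrix(5, 3, 3)
  a[1, 1] <- NA; b[1, 1] <- NA   # coverage 0
  b[2, 2] <- NA                  # coverage 1
  st <- stack_of(a, b)
  m <- fuse(st, "mean")
  expect_true(is.na(m$values[1, 1]))
  expect_equal(m$values[2, 2], 1)      # mean defined from a single layer
  expect_equal(m$coverage[2, 2], 1)
  s <- fuse(st, "sd")
  expect_true(is.na(s$values[2, 2]))   # spread needs coverage >= 2
  expect_equal(s$values[3, 3], 4 / sqrt(2))
  mp <- max_pairwise_sd(st)
  expect_true(is.na(mp$values[2, 2]))
})

test_that("fusion statistics agree with a per-pixel oracle on masked stacks", {
  set.seed(31)
  n_layers <- 5
  layers <- lapply(seq_len(n_layers), function(k) {
    m <- matrix(rnorm(8 * 8), 8, 8)
    m[sample(64, 12)] <- NA
    m
  })
  st <- do.call(stack_of, layers)
  fsd <- fuse(st, "sd")$values
  fmp <- max_pairwise_sd(st)$values
  fcv <- fuse(st, "covariance")$values
  for (y in 1:8) for (x in 1:8) {
    v <- vapply(layers, function(m) m[y, x], numeric(1))
    v <- v[!is.na(v)]
    if (length(v) < 2) {
      expect_true(is.na(fsd[y, x]))
      expect_true(is.na(fmp[y, x]))
    } else {
      expect_equal(fsd[y, x], sd(v), tolerance = 1e-12)
      expect_equal(fmp[y, x], (max(v) - min(v)) / sqrt(2), tolerance = 1e-12)
      expect_equal(fcv[y, x], var(v) / length(v), tolerance = 1e-12)
    }
  }
})

test_that("fusion invariances: layer order, intensity shift, dominance", {
  set.seed(77)
  layers <- lapply(1:6, function(k) {
    m <- matrix(rnorm(10 * 10, mean = 5), 10, 10)
    m[sample(100, 15)] <- NA
    m
  })
  st <- do.call(stack_of, layers)
  perm <- do.call(stack_of, layers[c(4, 1, 6, 2, 5, 3)])
  for (stat in c("sum", "mean", "sd", "variance", "covariance",
                 "max_pair_sd")) {
    expect_equal(fuse(st, stat)$values, fuse(perm, stat)$values)
  }
  shifted <- do.call(stack_of, lapply(layers, function(m) m + 3))
  expect_equal(fuse(shifted, "sd")$values, fuse(st, "sd")$values,
               tolerance = 1e-9)
  expect_equal(fuse(shifted, "max_pair_sd")$values,
               fuse(st, "max_pair_sd")$values, tolerance = 1e-9)
  n <- fuse(st, "mean")$coverage
  expect_equal(fuse(shifted, "mean")$values, fuse(st, "mean")$values + 3)
  expect_equal(fuse(shifted, "sum")$values, fuse(st, "sum")$values + 3 * n)

  # max-pairwise SD dominates the n-sample SD, equality exactly at n = 2
  mp <- max_pairwise_sd(st)$values
  sdv <- fuse(st, "sd")$values
  both <- !is.na(mp)
  expect_true(all(mp[both] >= sdv[both] - 1e-12))
  at2 <- both & fuse(st, "sd")$coverage == 2
  expect_equal(mp[at2], sdv[at2], tolerance = 1e-12)
  gt2 <- both & fuse(st, "sd")$coverage > 2
  expect_true(any(mp[gt2] > sdv[gt2]))
})

test_that("invert is an involution on the defined pixels", {
  v <- matrix(c(0, 2, 5, NA), 2, 2)
  f <- gazefuse:::new_fused_image(v, matrix(2, 2, 2), "sd")
  inv <- invert(f)
  expect_equal(inv$values[1:3], c(5, 3, 0))
  expect_true(is.na(inv$values[2, 2]))
  expect_true(inv$inverted)
  back <- invert(inv)
  expect_equal(back$values, f$values)
  expect_false(back$inverted)

  const <- gazefuse:::new_fused_image(matrix(3, 2, 2), matrix(2, 2, 2), "sd")
  expect_equal(invert(const)$values, const$values)
})

test_that("photometric normalization removes per-layer gain and offset", {
  base <- smooth_field(32, sigma = 1.5, seed = 5)
  st <- stack_of(base, base + 10)
  norm <- photometric_normalize(st, anchor = 1)
  expect_lt(max(fuse(norm, "sd")$values), 1e-6)

  st2 <- stack_of(base, base)
  norm2 <- photometric_normalize(st2, anchor = 1)
  expect_equal(norm2$layers[, , 2], base)

  st3 <- stack_of(base, base * 1.2 + 0.3)
  norm3 <- photometric_normalize(st3, anchor = 1)
  expect_equal(mean(norm3$layers[, , 2]), mean(base), tolerance = 1e-9)
  expect_equal(sd(norm3$layers[, , 2]), sd(base), tolerance = 1e-9)

  # no mutually defined pixels: layer left unchanged, with a warning
  a <- base; a[1:16, ] <- NA
  b <- base; b[17:32, ] <- NA
  expect_warning(norm4 <- photometric_normalize(stack_of(a, b), anchor = 1),
                 "no defined pixels")
  expect_equal(norm4$layers[, , 2], b)
})

test_that("directional fusion is the SD z-projection", {
  same <- replicate(5, matrix(2, 6, 6), simplify = FALSE)
  expect_true(all(directional_fuse(same)$values == 0))

  imgs <- lapply(c(2, 2, 2, 2, 12), function(v) matrix(v, 3, 3))
  f <- directional_fuse(imgs)
  expect_equal(f$values, matrix(sd(c(2, 2, 2, 2, 12)), 3, 3))
  expect_equal(f$values[1], 4.4721, tolerance = 1e-4)
  expect_equal(f$stat, "sd")

  expect_error(directional_fuse(imgs[1]), "at least 2")
})

test_that("display normalization and fused-image output files", {
  set.seed(8)
  v <- matrix(rexp(400), 20, 20)
  v[1:5] <- NA
  f <- gazefuse:::new_fused_image(v, matrix(3, 20, 20), "max_pair_sd")
  disp <- display_normalize(f)
  expect_true(all(disp[is.finite(disp)] >= 0 & disp[is.finite(disp)] <= 1))
  expect_true(all(is.na(disp[is.na(v)])))

  prefix <- file.path(withr::local_tempdir(), "fused")
  paths <- write_fused(f, prefix)
  expect_true(all(file.exists(paste0(prefix, c(".tif", "_raw.tif", ".json")))))
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(side$stat, "max_pair_sd")
  expect_false(side$inverted)
  expect_equal(side$coverage$max, 3)
})
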