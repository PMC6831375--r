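test_that("quantization matches closed forms and the binning oracle", {
  # SUVs spanning 2.5..10 with 64 bins: bin width 7.5/64
  vals <- seq(2.5, 10, length.out = 200)
  vol <- make_volume(vals)
  q <- quantize(vol, list(mask = array(TRUE, dim(vol$values))), 64)
  expect_equal(diff(q$bin_edges)[1], 7.5 / 64)
  expect_equal(q$bin_edges[1], 2.5)
  expect_equal(q$bin_edges[65], 10)
  expect_equal(max(q$levels, na.rm = TRUE), 64L)  # max voxel in the top bin
  expect_false(q$degenerate)
  # independent one-pass binning oracle
  w <- 7.5 / 64
  oracle <- pmin(floor((vals - 2.5) / w) + 1, 64)
  expect_equal(as.vector(q$levels), as.integer(oracle))
})

test_that("constant tumor quantization is degenerate with a single level", {
  vol <- make_volume(rep(5, 27))
  q <- quantize(vol, list(mask = array(TRUE, dim(vol$values))), 64)
  expect_true(q$degenerate)
  expect_true(all(q$levels[q$mask] == 1L))
})

test_that("1-D strip [1,2,1,2] reproduces the hand-enumerated co-occurrence features", {
  vol <- make_volume(c(1, 2, 1, 2))
  q <- quantize(vol, list(mask = array(TRUE, c(4, 1, 1))), 2)
  m <- nglcm(q)
  expect_equal(m$p[1, 2], 0.5)
  expect_equal(m$p[2, 1], 0.5)
  expect_equal(m$p[1, 1], 0)
  f <- nglcm_features(m)
  expect_equal(f$entropy_bits, 1.0)
  expect_equal(f$uniformity, 0.5)
  expect_equal(f$dissimilarity, 1.0)
  expect_equal(f$homogeneity, 0.5)
  expect_equal(f$inverse_difference_moment, 0.5)
})

test_that("constant tumor co-occurrence collapses to a point mass", {
  vol <- make_volume(rep(5, 27))
  q <- quantize(vol, list(mask = array(TRUE, c(27, 1, 1))), 64)
  m <- nglcm(q)
  expect_equal(m$p[1, 1], 1)
  f <- nglcm_features(m)
  expect_equal(f$entropy_bits, 0)
  expect_equal(f$uniformity, 1)
  expect_equal(f$dissimilarity, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$inverse_difference_moment, 1)
})

test_that("single-voxel mask has no valid pairs", {
  vol <- make_volume(c(5, 1, 1))
  mask <- array(c(TRUE, FALSE, FALSE), c(3, 1, 1))
  q <- quantize(vol, list(mask = mask), 4)
  expect_error(nglcm(q), "no valid voxel pairs")
  expect_error(ngtdm(q), "neighbor")
})

test_that("uniform co-occurrence over a 64x64 support has exactly 12 bits of entropy", {
  p <- matrix(1 / 4096, 64, 64)
  m <- structure(list(p = p, n_pairs = 4096L, n_directions = 26L,
                      distance_voxels = 1L), class = "nglcm_matrix")
  expect_equal(nglcm_features(m)$entropy_bits, 12)
})

test_that("co-occurrence matrix equals the brute-force pairwise oracle", {
  for (s in 1:6) {
    q <- random_quantized(c(6L, 6L, 6L), 8L, seed = s, p_mask = if (s %% 2) 1 else 0.7)
    m <- nglcm(q)
    expect_equal(sum(m$p), 1, tolerance = 1e-12)
    expect_equal(m$p, t(m$p))
    lv <- q$levels; lv[is.na(lv)] <- 0L
    expect_equal(m$p, oracle_nglcm(lv, q$mask, q$n_bins), tolerance = 1e-12)
  }
})

test_that("gray-tone difference table equals the per-voxel oracle", {
  for (s in 1:6) {
    q <- random_quantized(c(6L, 5L, 4L), 8L, seed = 100 + s, p_mask = if (s %% 2) 1 else 0.7)
    t_ <- ngtdm(q)
    lv <- q$levels; lv[is.na(lv)] <- 0L
    o <- oracle_ngtdm(lv, q$mask, q$n_bins)
    expect_equal(t_$s, o$s, tolerance = 1e-12)
    expect_equal(t_$p_i, o$p_i, tolerance = 1e-12)
    expect_equal(t_$n_valid_voxels, o$n)
    expect_equal(sum(t_$p_i), 1, tolerance = 1e-12)
    expect_true(all(t_$s >= 0))
    expect_true(all(t_$s[t_$p_i == 0] == 0))
  }
})

test_that("3x3 single-slice plane with a bright center matches the hand enumeration", {
  # center level 2 amid level 1: s(2) = 1; corners |1 - 4/3|, edges |1 - 6/5|
  vals <- matrix(1, 3, 3); vals[2, 2] <- 2
  vol <- make_volume(vals)
  q <- quantize(vol, list(mask = array(TRUE, c(3, 3, 1))), 2)
  t_ <- ngtdm(q)
  expect_equal(t_$s[2], 1)
  expect_equal(t_$s[1], 4 * (1 / 3) + 4 * (1 / 5))
  expect_equal(t_$p_i, c(8 / 9, 1 / 9))
  f <- ngtdm_features(t_)
  ps <- (8 / 9) * (32 / 15) + (1 / 9) * 1      # sum p_i s_i = 271/135
  expect_equal(f$coarseness, 1 / (1e-6 + ps))
  expect_equal(f$contrast, (8 / 81) * (47 / 135))
  expect_equal(f$busyness, ps / (4 / 3))
  expect_equal(f$complexity, (2 / 9) * ps)
})

test_that("constant tumor gray-tone features: capped coarseness, flagged contrast/busyness", {
  vol <- make_volume(rep(5, 27))
  q <- quantize(vol, list(mask = array(TRUE, c(3, 3, 3))), 64)
  t_ <- ngtdm(q)
  expect_true(all(t_$s == 0))
  f <- ngtdm_features(t_)
  expect_equal(f$coarseness, 1e6)
  expect_true(is.na(f$contrast))
  expect_true(is.na(f$busyness))
})

test_that("all nine features equal the independent oracle on small random phantoms", {
  for (s in 1:5) {
    q <- random_quantized(c(5L, 5L, 5L), 6L, seed = 200 + s)
    m <- nglcm(q); t_ <- ngtdm(q)
    lv <- q$levels; lv[is.na(lv)] <- 0L
    o <- oracle_features(oracle_nglcm(lv, q$mask, q$n_bins),
                         oracle_ngtdm(lv, q$mask, q$n_bins)$s,
                         oracle_ngtdm(lv, q$mask, q$n_bins)$p_i,
                         oracle_ngtdm(lv, q$mask, q$n_bins)$n)
    f <- c(nglcm_features(m), ngtdm_features(t_)[c("coarseness", "contrast",
                                                   "busyness", "complexity")])
    for (nm in names(o)) expect_equal(f[[nm]], o[[nm]], tolerance = 1e-10)
  }
})

test_that("entropy and uniformity respect their occupancy bounds", {
  for (s in 1:5) {
    q <- random_quantized(c(6L, 6L, 6L), 10L, seed = 300 + s)
    m <- nglcm(q)
    f <- nglcm_features(m)
    k <- sum(m$p > 0)
    expect_lte(f$entropy_bits, log2(k) + 1e-12)
    expect_gte(f$uniformity, 1 / k - 1e-12)
  }
})

test_that("features are invariant under monotone affine rescaling of SUV", {
  ph <- generate_pet_phantom(phantom_spec(rng_seed = 5L))
  seg <- segment_fixed_threshold(ph$volume, array(TRUE, dim(ph$volume$values)))
  f1 <- texture_features(ph$volume, seg, n_bins = 16)
  scaled <- suv_volume(2.5 * ph$volume$values + 1, ph$volume$voxel_spacing_mm)
  f2 <- texture_features(scaled, seg, n_bins = 16)
  for (nm in c("uniformity", "entropy_bits", "dissimilarity", "homogeneity",
               "inverse_difference_moment", "coarseness", "contrast",
               "busyness", "complexity")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-10)
  }
})
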