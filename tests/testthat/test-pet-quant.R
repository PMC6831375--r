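make_box_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

test_that("uniform avid tumor in a clean background is segmented exactly", {
  dims <- c(12L, 12L, 12L)
  vol <- array(1, dims)
  tumor <- make_box_mask(dims, c(4, 4, 4), c(8, 8, 8))
  vol[tumor] <- 5
  seg <- segment_fixed_threshold(suv_volume(vol, c(2, 2, 2)),
                                 array(TRUE, dims))
  expect_identical(seg$mask, tumor)
  expect_equal(seg$n_voxels, sum(tumor))
  expect_true(all(vol[seg$mask] >= seg$threshold_suv))
})

test_that("largest 26-connected component is kept when the ROI holds two blobs", {
  dims <- c(20L, 12L, 8L)
  vol <- array(1, dims)
  big <- make_box_mask(dims, c(2, 2, 2), c(6, 6, 5))    # 100 voxels
  small <- make_box_mask(dims, c(14, 8, 2), c(17, 12, 2)) # 20 voxels
  vol[big] <- 6; vol[small] <- 6
  seg <- segment_fixed_threshold(suv_volume(vol, c(2, 2, 2)), array(TRUE, dims))
  expect_identical(seg$mask, big)
  expect_equal(seg$n_components, 2L)
  # flood-fill oracle agrees on the retained component
  ff <- oracle_flood_fill(vol >= 2.5, c(2L, 2L, 2L))
  expect_identical(seg$mask, ff)
})

test_that("no voxel above threshold raises the no-avid-lesion error", {
  vol <- suv_volume(array(1, c(6, 6, 6)), c(2, 2, 2))
  expect_error(segment_fixed_threshold(vol, array(TRUE, c(6, 6, 6))),
               "no avid lesion")
})

test_that("segmentation is restricted to the seed ROI and flags boundary contact", {
  dims <- c(10L, 10L, 10L)
  vol <- array(6, dims)  # everything avid
  roi <- make_box_mask(dims, c(3, 3, 3), c(7, 7, 7))
  seg <- segment_fixed_threshold(suv_volume(vol, c(2, 2, 2)), roi)
  expect_identical(seg$mask, roi)          # mask never leaves the ROI
  expect_false(seg$roi_touches_boundary)
  seg2 <- segment_fixed_threshold(suv_volume(vol, c(2, 2, 2)),
                                  make_box_mask(dims, c(1, 3, 3), c(5, 7, 7)))
  expect_true(seg2$roi_touches_boundary)
})

test_that("segmentation ignores voxel values outside the seed ROI", {
  dims <- c(10L, 10L, 10L)
  roi <- make_box_mask(dims, c(3, 3, 3), c(7, 7, 7))
  vol1 <- array(1, dims); vol1[roi] <- 4
  vol2 <- vol1
  vol2[!roi] <- runif(sum(!roi), 0, 2.4)   # relabel the outside
  s1 <- segment_fixed_threshold(suv_volume(vol1, c(2, 2, 2)), roi)
  s2 <- segment_fixed_threshold(suv_volume(vol2, c(2, 2, 2)), roi)
  expect_identical(s1$mask, s2$mask)
})

test_that("metabolic indices match closed forms", {
  # 10x10x10 uniform SUV-5 tumor at 2 mm isotropic: MTV 8 mL, TLG 40
  dims <- c(14L, 14L, 14L)
  vol <- array(1, dims)
  tumor <- make_box_mask(dims, c(3, 3, 3), c(12, 12, 12))
  vol[tumor] <- 5
  v <- suv_volume(vol, c(2, 2, 2))
  mi <- metabolic_indices(v, segment_fixed_threshold(v, array(TRUE, dims)))
  expect_equal(mi$mtv_ml, 8.0)
  expect_equal(mi$suvmean, 5.0)
  expect_equal(mi$suvmax, 5.0)
  expect_equal(mi$tlg, 40.0)

  # single voxel SUV 3 at 1 mm isotropic
  vol1 <- array(1, c(5, 5, 5)); vol1[3, 3, 3] <- 3
  v1 <- suv_volume(vol1, c(1, 1, 1))
  mi1 <- metabolic_indices(v1, segment_fixed_threshold(v1, array(TRUE, c(5, 5, 5))))
  expect_equal(mi1$mtv_ml, 0.001)
  expect_equal(mi1$tlg, 0.003)
})

test_that("TLG identity and direct-summation check hold on random phantoms", {
  for (s in 1:5) {
    ph <- generate_pet_phantom(phantom_spec(rng_seed = s))
    seg <- segment_fixed_threshold(ph$volume, array(TRUE, dim(ph$volume$values)))
    mi <- metabolic_indices(ph$volume, seg)
    expect_equal(mi$tlg, mi$mtv_ml * mi$suvmean)
    voxel_ml <- prod(ph$volume$voxel_spacing_mm) / 1000
    expect_equal(mi$tlg, sum(ph$volume$values[seg$mask]) * voxel_ml)
    expect_gte(mi$suvmax, mi$suvmean)
    expect_gte(mi$suvmean, seg$threshold_suv)
  }
})

test_that("raising the threshold never enlarges the mask", {
  ph <- generate_pet_phantom(phantom_spec(heterogeneity_sigma = 0.5, rng_seed = 11L))
  roi <- array(TRUE, dim(ph$volume$values))
  prev <- NULL
  for (thr in c(2.5, 3.5, 4.5, 6)) {
    seg <- tryCatch(segment_fixed_threshold(ph$volume, roi, threshold = thr),
                    error = function(e) NULL)
    if (is.null(seg)) break
    if (!is.null(prev)) expect_true(all(prev$mask[seg$mask]))
    prev <- seg
  }
})
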