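test_that("a rasterized disc recovers the closed-form 2D descriptors", {
  f <- extract_2d_features(raster_disc(20))
  expect_equal(unname(f["circularity"]), 1, tolerance = 0.05)
  expect_equal(unname(f["elongation"]), 1, tolerance = 0.06)
  expect_gte(f[["compactness"]], 0.95)
  expect_lte(f[["compactness"]], 1)
  expect_equal(unname(f["moment"]), 1 / (2 * pi), tolerance = 0.01)
})

test_that("elongation tracks the axis ratio of an ellipse", {
  f <- extract_2d_features(raster_ellipse(40, 20))
  expect_equal(unname(f["elongation"]), 0.5, tolerance = 0.05)
  expect_lt(f[["elongation"]], extract_2d_features(raster_disc(20))[["elongation"]])
})

test_that("degenerate single-pixel masks are handled", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  f <- extract_2d_features(m)
  expect_equal(unname(f["circularity"]), 1)
  expect_equal(unname(f["elongation"]), 1)
  expect_equal(unname(f["moment"]), 0)
  expect_true(is.finite(f[["compactness"]]))
  expect_error(extract_2d_features(matrix(0, 4, 4)),
               class = "rusmote_empty_mask")
})

test_that("multi-component slices keep the largest component", {
  m <- matrix(0, 20, 20)
  m[3:12, 3:12] <- 1   # 100 px
  m[16:17, 16:17] <- 1 # 4 px speck
  expect_message(f <- extract_2d_features(m), "components")
  solo <- extract_2d_features(matrix(1, 10, 10))
  expect_equal(unname(f), unname(solo))
})

test_that("a solid cube matches closed-form 3D descriptors exactly", {
  cube <- roi_volume(array(1, c(10, 10, 10)), c(1, 1, 1), "cube")
  f <- extract_3d_features(cube)
  expect_equal(unname(f["volume"]), 1000)
  expect_equal(unname(f["surface_area"]), 600)
  expect_equal(unname(f["sphericity"]), pi^(1 / 3) * 6000^(2 / 3) / 600,
               tolerance = 1e-12)
  expect_equal(unname(f["centroid_offset"]), 0)

  expect_error(extract_3d_features(roi_volume(array(0, c(3, 3, 3)))),
               class = "rusmote_empty_mask")
})

test_that("whole-voxel translation leaves every feature unchanged", {
  ell <- raster_ellipsoid(c(6, 5, 4))
  big <- array(FALSE, dim(ell$mask) + c(6, 4, 2))
  big[4 + seq_len(dim(ell$mask)[1]),
      3 + seq_len(dim(ell$mask)[2]),
      1 + seq_len(dim(ell$mask)[3])] <- ell$mask
  expect_equal(feature_vector(roi_volume(big, ell$spacing)),
               feature_vector(ell))
})

test_that("in-plane 90-degree rotation changes dimensionless features < 5%", {
  ell <- raster_ellipsoid(c(8, 5, 4))
  rot <- roi_volume(aperm(ell$mask, c(2, 1, 3)), ell$spacing)
  f0 <- feature_vector(ell)
  f1 <- feature_vector(rot)
  dimless <- c("circularity", "elongation", "compactness", "moment",
               "sphericity")
  expect_lt(max(abs(f1[dimless] - f0[dimless]) / abs(f0[dimless])), 0.05)
})

test_that("halving the voxel size leaves dimensionless features within 5%", {
  coarse <- raster_ellipsoid(c(20, 15, 12), spacing = c(1, 1, 1))
  fine <- raster_ellipsoid(c(40, 30, 24), spacing = c(0.5, 0.5, 0.5))
  f1 <- feature_vector(coarse)
  f2 <- feature_vector(fine)
  dimless <- c("circularity", "elongation", "compactness", "moment",
               "sphericity")
  expect_lt(max(abs(f2[dimless] - f1[dimless]) / abs(f1[dimless])), 0.05)
  # the dimensional features agree on the physical scale
  expect_equal(unname(f2["volume"]), unname(f1["volume"]), tolerance = 0.05)
})

test_that("stretching one axis lowers elongation and sphericity monotonically", {
  stretch <- c(1, 1.5, 2.2, 3.2)
  sph <- elo <- numeric(length(stretch))
  for (i in seq_along(stretch)) {
    f <- feature_vector(raster_ellipsoid(c(6 * stretch[i], 6, 5)))
    sph[i] <- f[["sphericity"]]
    elo[i] <- f[["elongation"]]
  }
  expect_true(all(diff(sph) < 0))
  expect_true(all(diff(elo) < 0))
})

test_that("a sphere is more spherical than an equal-volume prolate ellipsoid", {
  # 3:1 prolate with the same volume: axes (a, b, b) with a = 3 b
  b <- round((10^3 / 3)^(1 / 3))
  sphere <- feature_vector(raster_ellipsoid(c(10, 10, 10)))
  prolate <- feature_vector(raster_ellipsoid(c(3 * b, b, b)))
  expect_gt(sphere[["sphericity"]], prolate[["sphericity"]])
})

test_that("voxel surface area dominates the equivalent-sphere bound", {
  for (ax in list(c(8, 8, 8), c(10, 6, 5), c(12, 4, 4))) {
    f <- extract_3d_features(raster_ellipsoid(ax))
    a_sphere <- pi^(1 / 3) * (6 * f[["volume"]])^(2 / 3)
    expect_gte(f[["surface_area"]], 0.98 * a_sphere)
  }
})

test_that("roi_feature_table assembles the canonical 8-column dataset", {
  vols <- list(make_ellipsoid_roi("nodule", seed = 1),
               make_ellipsoid_roi("nonnodule", seed = 2))
  ds <- roi_feature_table(vols, c(1, -1))
  expect_equal(ds$feature_names, FEATURE_COLUMNS)
  expect_equal(nrow(ds$features), 2)
  expect_true(all(is.finite(ds$features)))
  expect_error(roi_feature_table(vols, 1), class = "rusmote_shape_mismatch")
})
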