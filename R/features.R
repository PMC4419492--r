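# Shape descriptors for nodule candidate ROIs: four 2D features computed on
# the largest axial slice and four 3D features computed on the whole mask.

# 4-direction Crofton perimeter of a binary 2D mask, in pixel units.
# Counts 2x2 pixel configurations and weights them with the standard
# integral-geometry LUT; nearly unbiased for smooth blobs, which plain
# staircase contour length is not.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  # configuration code of the 2x2 block whose bottom-right cell is (i, j)
  code <- m[2:nr, 2:nc] + 4L * m[2:nr, 1:(nc - 1L)] +
    2L * m[1:(nr - 1L), 2:nc] + 8L * m[1:(nr - 1L), 1:(nc - 1L)]
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

# Largest 4-connected foreground component of a 2D mask (logical matrix).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  message(sprintf("mask has %d components; keeping the largest (%d px)",
                  length(sizes), max(sizes)))
  lab == which.max(sizes)
}

# Foreground pixels with at least one 4-neighbor background pixel (image
# border counts as background).
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

#' 2D shape features of a binary slice
#'
#' Computes, on the largest connected component of the slice:
#' * `circularity`: radius of the largest inscribed circle (distance-transform
#'   maximum) over the circumscribed radius (maximum centroid-to-boundary
#'   distance); 1 for a disc.
#' * `elongation`: minimum over maximum centroid-to-boundary distance
#'   (`r_min / r_max`); small for elongated shapes.
#' * `compactness`: `4 * pi * A / P^2` with the Crofton perimeter estimate;
#'   1 for a disc.
#' * `moment`: the rotation/translation/scale-invariant normalized second
#'   moment `eta20 + eta02`; `1 / (2 * pi)` for a disc.
#'
#' Ratio features are clamped to 1 to absorb discretization overshoot. A
#' single-pixel mask is degenerate: ratios are defined as 1 and the moment 0.
#'
#' @param slice_mask logical or 0/1 matrix with at least one foreground pixel.
#' @param spacing in-plane pixel size `(dx, dy)` in mm; the Crofton estimator
#'   assumes near-isotropic pixels and uses `sqrt(dx * dy)` as its scale.
#' @return named numeric vector `circularity`, `elongation`, `compactness`,
#'   `moment`.
#' @export
extract_2d_features <- function(slice_mask, spacing = c(1, 1)) {
  mask <- matrix(slice_mask > 0.5, nrow(slice_mask))
  if (!any(mask)) {
    abort_rusmote("slice mask has no foreground pixels", "rusmote_empty_mask")
  }
  mask <- largest_component(mask)
  dx <- spacing[1]; dy <- spacing[2]
  npix <- sum(mask)
  if (npix == 1) {
    return(c(circularity = 1, elongation = 1,
             compactness = 4 * pi * dx * dy / (2 * (dx + dy))^2, moment = 0))
  }
  area <- npix * dx * dy
  s2d <- sqrt(dx * dy)
  perim <- crofton_perimeter(mask) * s2d
  compactness <- min(1, 4 * pi * area / perim^2)

  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 1] * dx; py <- idx[, 2] * dy
  cx <- mean(px); cy <- mean(py)
  bd <- boundary_pixels(mask)
  bdist <- sqrt((bd[, 1] * dx - cx)^2 + (bd[, 2] * dy - cy)^2)
  r_max <- max(bdist); r_min <- min(bdist)
  elongation <- if (r_max == 0) 1 else min(1, r_min / r_max)

  # inscribed radius from the Euclidean distance transform, padded so the
  # image border is treated as background
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  r_ins <- max(EBImage::distmap(pad)) * s2d
  circularity <- if (r_max == 0) 1 else min(1, r_ins / r_max)

  mu <- sum(((px - cx)^2 + (py - cy)^2)) * dx * dy  # mu20 + mu02
  moment <- mu / area^2

  c(circularity = circularity, elongation = elongation,
    compactness = compactness, moment = moment)
}

#' 3D shape features of a binary volume
#'
#' * `volume`: foreground voxel count times the voxel volume (mm^3).
#' * `surface_area`: exposed voxel faces under 6-connectivity, each weighted
#'   by its physical face area (mm^2).
#' * `sphericity`: `pi^(1/3) * (6 V)^(2/3) / A`, clamped to 1; equals 1 for a
#'   perfect sphere and decreases as the shape elongates.
#' * `centroid_offset`: mean over axial slices of the in-plane distance
#'   between the slice centroid and the projected volume centroid, divided by
#'   the volume-equivalent radius `(3 V / (4 pi))^(1/3)`; near 0 for compact
#'   blobs and straight in-plane structures, larger for tilted vessel-like
#'   tubes.
#'
#' @param roi an [roi_volume()] with a nonempty mask.
#' @return named numeric vector `surface_area`, `volume`, `sphericity`,
#'   `centroid_offset`.
#' @export
extract_3d_features <- function(roi) {
  mask <- roi$mask
  sp <- roi$spacing
  nfg <- sum(mask)
  if (nfg == 0) {
    abort_rusmote("ROI mask has no foreground voxels", "rusmote_empty_mask")
  }
  vol <- nfg * prod(sp)

  d <- dim(mask)
  m <- array(0L, d + 2L)
  m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  faces_along <- function(axis) sum(abs(apply(m, setdiff(1:3, axis), diff)))
  surf <- faces_along(1) * sp[2] * sp[3] +
    faces_along(2) * sp[1] * sp[3] +
    faces_along(3) * sp[1] * sp[2]
  sphericity <- min(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / surf)

  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 1] * sp[1]; py <- idx[, 2] * sp[2]
  cx <- mean(px); cy <- mean(py)
  per_slice <- function(v) vapply(split(v, idx[, 3]), mean, numeric(1))
  offs <- sqrt((per_slice(px) - cx)^2 + (per_slice(py) - cy)^2)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  c(surface_area = surf, volume = vol, sphericity = sphericity,
    centroid_offset = mean(offs) / r_eq)
}

#' Full 8-feature vector of an ROI
#'
#' The four 2D features are computed on the axial slice with the largest
#' foreground area (ties: lowest slice index) and combined with the four 3D
#' features in the canonical column order `circularity, elongation,
#' compactness, moment, surface_area, volume, sphericity, centroid_offset`.
#'
#' @param roi an [roi_volume()] with a nonempty mask.
#' @return named numeric vector of length 8.
#' @export
feature_vector <- function(roi) {
  areas <- apply(roi$mask, 3, sum)
  if (all(areas == 0)) {
    abort_rusmote("ROI mask has no foreground voxels", "rusmote_empty_mask")
  }
  z <- which.max(areas)  # first maximum = lowest slice index
  f2 <- extract_2d_features(roi$mask[, , z], roi$spacing[1:2])
  f3 <- extract_3d_features(roi)
  c(f2, f3)[FEATURE_COLUMNS]
}

#' Feature table from a list of ROI volumes
#'
#' @param volumes list of [roi_volume()] objects.
#' @param labels vector of `+1`/`-1`, one per volume (nodule = +1).
#' @return a [labeled_dataset()] with one row per volume, ids taken from the
#'   volumes.
#' @export
roi_feature_table <- function(volumes, labels) {
  if (length(volumes) != length(labels)) {
    abort_rusmote("volumes and labels must have the same length",
                  "rusmote_shape_mismatch")
  }
  feats <- t(vapply(volumes, feature_vector, numeric(8)))
  labeled_dataset(feats, labels, FEATURE_COLUMNS,
                  vapply(volumes, function(v) v$id, character(1)))
}
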