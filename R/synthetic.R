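# Seeded synthetic generators: imbalanced two-cluster feature datasets
# (optionally with planted boundary-noise points) and toy nodule /
# non-nodule voxel masks, so every stage of the pipeline can be exercised
# without any external data.

#' Specification for the Gaussian imbalanced generator
#'
#' @param n_min,n_maj class sizes (minority = +1).
#' @param dim feature dimension (default 8, the size of the shape-feature
#'   vector).
#' @param separation distance between the class centers in units of the
#'   within-class standard deviation. The default 3 yields clusters that
#'   overlap enough for a plain SVM to lose minority recall at ratio ~6
#'   without being unlearnable.
#' @param minority_scale,majority_scale isotropic within-class standard
#'   deviations.
#' @param noise_fraction fraction of majority samples (in `[0, 0.05]`)
#'   replanted as boundary noise inside the minority cloud;
#'   `round(noise_fraction * n_maj)` points are planted.
#' @param seed integer seed.
#' @return an object of class `generator_spec`.
#' @export
gaussian_spec <- function(n_min, n_maj, dim = 8, separation = 3,
                          minority_scale = 1, majority_scale = 1,
                          noise_fraction = 0, seed = 1) {
  if (noise_fraction < 0 || noise_fraction > 0.05) {
    abort_rusmote("noise_fraction must be in [0, 0.05]", "rusmote_bad_spec")
  }
  if (separation < 0 || n_min < 1 || n_maj < 1 || dim < 1) {
    abort_rusmote("invalid generator spec", "rusmote_bad_spec")
  }
  structure(list(n_min = as.integer(n_min), n_maj = as.integer(n_maj),
                 dim = as.integer(dim), separation = separation,
                 minority_scale = minority_scale,
                 majority_scale = majority_scale,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "generator_spec")
}

# Uniform draws from a ball: direction from an isotropic normal, radius from
# the volume-uniform radial law U^(1/dim).
runif_ball <- function(n, dim, radius, center) {
  z <- matrix(stats::rnorm(n * dim), n, dim)
  z <- z / sqrt(rowSums(z^2))
  r <- radius * stats::runif(n)^(1 / dim)
  sweep(z * r, 2, center, "+")
}

#' Generate an imbalanced two-cluster Gaussian dataset
#'
#' Minority samples are drawn around the origin, majority samples around a
#' center `separation` standard deviations away. When `noise_fraction > 0`,
#' `round(noise_fraction * n_maj)` randomly chosen majority rows are replaced
#' by planted boundary-noise points: uniform draws inside the minority
#' class's empirical average radius that also lie beyond the 99th percentile
#' of the majority's center distances, so they satisfy both clauses of the
#' boundary-noise rule by construction.
#'
#' @param spec a [gaussian_spec()].
#' @return a [labeled_dataset()] (minority rows first); the attribute
#'   `planted_noise` holds the dataset row indices of the planted points.
#' @export
make_gaussian_imbalanced <- function(spec) {
  if (!inherits(spec, "generator_spec")) {
    abort_rusmote("spec must be a generator_spec", "rusmote_bad_spec")
  }
  withr::with_seed(spec$seed, {
    p <- spec$dim
    xmin <- matrix(stats::rnorm(spec$n_min * p, sd = spec$minority_scale),
                   spec$n_min, p)
    center_maj <- c(spec$separation *
                      (spec$minority_scale + spec$majority_scale) / 2,
                    rep(0, p - 1))
    xmaj <- sweep(matrix(stats::rnorm(spec$n_maj * p,
                                      sd = spec$majority_scale),
                         spec$n_maj, p),
                  2, center_maj, "+")
    planted <- integer()
    k <- round(spec$noise_fraction * spec$n_maj)
    if (k > 0) {
      c_min <- colMeans(xmin)
      r_min <- mean(sqrt(rowSums(sweep(xmin, 2, c_min, "-")^2)))
      c_maj <- colMeans(xmaj)
      thr <- stats::quantile(sqrt(rowSums(sweep(xmaj, 2, c_maj, "-")^2)),
                             0.99, names = FALSE)
      pts <- matrix(numeric(), 0, p)
      for (i in seq_len(200)) {
        cand <- runif_ball(5000, p, r_min, c_min)
        ok <- sqrt(rowSums(sweep(cand, 2, c_maj, "-")^2)) > thr
        pts <- rbind(pts, cand[ok, , drop = FALSE])
        if (nrow(pts) >= k) break
      }
      if (nrow(pts) < k) {
        abort_rusmote(
          "could not plant boundary noise; separation too small relative to the minority radius",
          "rusmote_infeasible_noise")
      }
      planted <- sort(sample.int(spec$n_maj, k))
      xmaj[planted, ] <- pts[seq_len(k), ]
    }
    ds <- labeled_dataset(
      rbind(xmin, xmaj),
      c(rep(1, spec$n_min), rep(-1, spec$n_maj)),
      paste0("f", seq_len(p)),
      c(sprintf("min_%04d", seq_len(spec$n_min)),
        sprintf("maj_%04d", seq_len(spec$n_maj))))
    attr(ds, "planted_noise") <- spec$n_min + planted
    ds
  })
}

#' Generate a toy nodule or non-nodule ROI mask
#'
#' `"nodule"` produces a near-spherical ellipsoid (pairwise axis ratios
#' within `[0.8, 1.25]`) with a mild random surface perturbation;
#' `"nonnodule"` produces an elongated vessel-like capsule (long/short axis
#' ratio >= 3) tilted out of plane. Volume dimensions stay within the
#' reference ranges: 10-50 voxels in plane and 5-13 layers.
#'
#' @param kind `"nodule"` or `"nonnodule"`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param seed integer seed; the same seed reproduces the identical mask.
#' @return an [roi_volume()].
#' @export
make_ellipsoid_roi <- function(kind = c("nodule", "nonnodule"),
                               spacing = c(1, 1, 1), seed = 1) {
  kind <- match.arg(kind)
  withr::with_seed(as.integer(seed), {
    if (kind == "nodule") {
      R <- stats::runif(1, 4.6, 5.3)
      q <- stats::runif(3, 0.9, 1.12)     # pairwise ratios stay in [0.8, 1.25]
      ax <- R * q                          # semi-axes, all <= 5.94
      half <- c(ceiling(ax[1:2]) + 1L, ceiling(ax[3]))
      dims <- 2L * half + 1L               # in-plane 11..15, layers 9..13
      ctr <- half + 1L
      gx <- (seq_len(dims[1]) - ctr[1])
      gy <- (seq_len(dims[2]) - ctr[2])
      gz <- (seq_len(dims[3]) - ctr[3])
      q2 <- outer(outer(gx^2 / ax[1]^2, gy^2 / ax[2]^2, "+"),
                  gz^2 / ax[3]^2, "+")
      eps <- array(stats::runif(length(q2), -0.06, 0.06), dim(q2))
      mask <- q2 <= (1 + eps)^2
    } else {
      L <- stats::runif(1, 16, 36)         # capsule axis length
      rs <- stats::runif(1, 2, min(4, L / 6))  # long/short >= 3 by rs <= L/6
      phi <- stats::runif(1, 0, 2 * pi)
      uz_max <- max(0, min(0.45, (6 - rs) / (L / 2)))
      uz <- stats::runif(1, 0.5 * uz_max, uz_max)  # tilt out of plane
      w <- sqrt(1 - uz^2)
      u <- c(cos(phi) * w, sin(phi) * w, uz)
      half <- ceiling(abs(u) * L / 2 + rs)
      half[1:2] <- pmax(half[1:2] + 1L, 5L)  # in-plane extent 10..50 voxels
      dims <- 2L * half + 1L                 # layers stay within 5..13
      ctr <- half + 1L
      gx <- seq_len(dims[1]) - ctr[1]
      gy <- seq_len(dims[2]) - ctr[2]
      gz <- seq_len(dims[3]) - ctr[3]
      pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      t0 <- pmin(pmax(pts %*% u, -L / 2), L / 2)
      d2 <- rowSums((pts - t0 %*% t(u))^2)
      eps <- stats::runif(length(d2), -0.05, 0.05)
      mask <- array(d2 <= (rs * (1 + eps))^2, dims)
    }
    roi_volume(mask, spacing, sprintf("%s_%d", kind, as.integer(seed)))
  })
}

#' Generate a full imbalanced cohort of toy ROI volumes
#'
#' Produces 150 nodule and 908 non-nodule masks (the reference cohort shape)
#' via [make_ellipsoid_roi()], each with its own derived seed.
#'
#' @param seed integer master seed.
#' @param n_nodule,n_nonnodule cohort sizes.
#' @param spacing voxel spacing passed through to the mask generator.
#' @return list with `volumes` (list of [roi_volume()]) and `labels`
#'   (`+1` for nodules, `-1` for non-nodules).
#' @export
make_paperlike_cohort <- function(seed = 1, n_nodule = 150,
                                  n_nonnodule = 908, spacing = c(1, 1, 1)) {
  seeds <- derive_seeds(seed, n_nodule + n_nonnodule)
  vols <- c(
    lapply(seq_len(n_nodule),
           function(i) make_ellipsoid_roi("nodule", spacing, seeds[i])),
    lapply(seq_len(n_nonnodule),
           function(i) make_ellipsoid_roi("nonnodule", spacing,
                                          seeds[n_nodule + i])))
  for (i in seq_along(vols)) vols[[i]]$id <- sprintf("roi_%04d", i)
  list(volumes = vols, labels = c(rep(1, n_nodule), rep(-1, n_nonnodule)))
}
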