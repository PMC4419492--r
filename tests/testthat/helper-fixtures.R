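# Shared fixture builders: all geometry is generated in code at test time.

# Binary matrix of an axis-aligned ellipse (pixel centers inside).
raster_ellipse <- function(a, b, pad = 3) {
  n1 <- 2 * (ceiling(a) + pad) + 1
  n2 <- 2 * (ceiling(b) + pad) + 1
  c1 <- (n1 + 1) / 2
  c2 <- (n2 + 1) / 2
  outer(seq_len(n1), seq_len(n2),
        function(i, j) ((i - c1) / a)^2 + ((j - c2) / b)^2 <= 1)
}

raster_disc <- function(r, pad = 3) raster_ellipse(r, r, pad)

# roi_volume of an axis-aligned solid ellipsoid with semi-axes `ax` (voxels)
# and given spacing.
raster_ellipsoid <- function(ax, spacing = c(1, 1, 1), pad = 2, id = "ell") {
  g <- lapply(ax, function(a) seq(-(ceiling(a) + pad), ceiling(a) + pad))
  q <- outer(outer(g[[1]]^2 / ax[1]^2, g[[2]]^2 / ax[2]^2, "+"),
             g[[3]]^2 / ax[3]^2, "+")
  roi_volume(array(q <= 1, dim(q)), spacing, id)
}

# Small labeled dataset with both classes.
tiny_dataset <- function(n_min = 5, n_maj = 10, dim = 3, seed = 1) {
  withr::with_seed(seed, {
    labeled_dataset(
      rbind(matrix(rnorm(n_min * dim), n_min),
            matrix(rnorm(n_maj * dim, mean = 4), n_maj)),
      c(rep(1, n_min), rep(-1, n_maj)))
  })
}
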