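test_that("class geometry matches a brute-force loop", {
  # symmetric pair: center midway, radius 1
  ds <- labeled_dataset(rbind(c(0, 0), c(2, 0), c(5, 5)), c(1, 1, -1))
  g <- compute_class_geometry(ds)
  expect_equal(unname(g$center_min), c(1, 0))
  expect_equal(g$r_ave_min, 1)
  expect_equal(g$r_ave_maj, 0)  # one-sample class

  withr::with_seed(3, {
    ds <- labeled_dataset(matrix(rnorm(200 * 5), 200),
                          rep(c(1, -1), each = 100))
  })
  g <- compute_class_geometry(ds)
  for (lab in c(1, -1)) {
    x <- ds$features[ds$labels == lab, ]
    center <- numeric(5)
    for (i in seq_len(nrow(x))) center <- center + x[i, ]
    center <- center / nrow(x)
    r <- 0
    for (i in seq_len(nrow(x))) r <- r + sqrt(sum((x[i, ] - center)^2))
    r <- r / nrow(x)
    if (lab == 1) {
      expect_equal(unname(g$center_min), unname(center), tolerance = 1e-12)
      expect_equal(g$r_ave_min, r, tolerance = 1e-12)
    } else {
      expect_equal(unname(g$center_maj), unname(center), tolerance = 1e-12)
      expect_equal(g$r_ave_maj, r, tolerance = 1e-12)
    }
  }
  expect_error(
    compute_class_geometry(labeled_dataset(matrix(1, 2, 2), c(1, 1))),
    class = "rusmote_empty_class")
})

test_that("boundary-noise detection flags only intruding majority samples", {
  # well-separated clusters: nothing satisfies the noise condition
  ds <- make_gaussian_imbalanced(gaussian_spec(50, 200, separation = 10,
                                               seed = 1))
  expect_length(detect_boundary_noise(ds), 0)

  # hand-built 2D configuration: 19 majority points on the unit circle around
  # (10, 0), one majority point inside the minority cloud at the origin
  theta <- seq(0, 2 * pi, length.out = 20)[1:19]
  maj <- rbind(cbind(10 + cos(theta), sin(theta)), c(0.1, 0))
  minr <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))  # r_ave_min = 1
  ds <- labeled_dataset(rbind(minr, maj), c(rep(1, 4), rep(-1, 20)))
  flagged <- detect_boundary_noise(ds)
  expect_identical(flagged, 24L)  # the planted intruder, dataset row 24

  # the 5% cap: at most ceiling(0.05 * n_maj) indices, all majority rows
  ds <- make_gaussian_imbalanced(gaussian_spec(40, 100, separation = 0.5,
                                               seed = 2))
  flagged <- detect_boundary_noise(ds)
  expect_lte(length(flagged), ceiling(0.05 * 100))
  expect_true(all(ds$labels[flagged] == -1))
})

test_that("random undersampling halves counts exactly and keeps the distribution", {
  withr::with_seed(11, x <- matrix(rnorm(454 * 8), 454))
  expect_equal(nrow(random_undersample(x, 1)), 227)
  expect_identical(random_undersample(x, 0), x)
  for (m in c(7, 100, 333)) {
    for (n in 0:3) {
      expect_equal(nrow(random_undersample(x[seq_len(m), , drop = FALSE], n)),
                   ceiling(m / 2^n))
    }
  }

  # dyadic decimation preserves the empirical distribution: two-sample KS
  # per feature against the original, 10^4 draws from a bimodal mixture
  withr::with_seed(12, {
    mix <- matrix(c(rnorm(6000), rnorm(4000, 4),
                    rnorm(6000, 0, 2), rnorm(4000, -3)), ncol = 2)
  })
  kept <- random_undersample(mix, 1)
  for (j in 1:2) {
    p <- suppressWarnings(ks.test(kept[, j], mix[, j]))$p.value
    expect_gt(p, 0.01)
  }
  # mean and variance of a deeper decimation stay within 3 standard errors
  kept2 <- random_undersample(mix, 2)
  se_mean <- apply(mix, 2, sd) / sqrt(nrow(kept2))
  expect_true(all(abs(colMeans(kept2) - colMeans(mix)) < 3 * se_mean))
  ratio <- apply(kept2, 2, var) / apply(mix, 2, var)
  expect_true(all(abs(ratio - 1) < 3 * sqrt(2 / nrow(kept2))))
})

test_that("SMOTE produces the documented counts and exact interpolants", {
  withr::with_seed(5, minority <- matrix(rnorm(75 * 8), 75))
  expect_equal(nrow(smote_oversample(minority, 5, 5, seed = 1)$samples), 375)
  expect_equal(nrow(smote_oversample(minority, 3, 3, seed = 1)$samples), 225)
  noop <- smote_oversample(minority, 3, 1, seed = 1)
  expect_identical(noop$samples, minority)
  expect_equal(nrow(noop$provenance), 0)

  # provenance replay: every synthetic row reconstructs exactly from its
  # recorded base, neighbor and delta, with delta in [0, 1]
  withr::with_seed(6, minority <- matrix(rnorm(30 * 4), 30))
  out <- smote_oversample(minority, 4, 6, seed = 9)
  synth <- out$samples[-(1:30), , drop = FALSE]
  pv <- out$provenance
  expect_equal(nrow(pv), 5 * 30)
  expect_true(all(pv$delta >= 0 & pv$delta <= 1))
  rebuilt <- minority[pv$base, ] +
    pv$delta * (minority[pv$neighbor, ] - minority[pv$base, ])
  expect_lt(max(abs(synth - rebuilt)), 1e-10)
  # neighbors are genuine K-nearest minority neighbors, self excluded
  expect_true(all(pv$neighbor != pv$base))

  expect_error(smote_oversample(minority[1, , drop = FALSE], 3, 2, seed = 1),
               class = "rusmote_too_few_minority")
  expect_warning(smote_oversample(minority[1:3, ], 5, 2, seed = 1),
                 class = "rusmote_k_adjusted")
})

test_that("parameter selection reproduces the reference settings", {
  cases <- list(list(ratio = 6, ru = 2, k = 3, n = 3),
                list(ratio = 10, ru = 2, k = 5, n = 5),
                list(ratio = 20, ru = 4, k = 5, n = 5))
  for (cs in cases) {
    p <- select_balance_parameters(cs$ratio * 75, 75)
    expect_equal(2^p$ru_rounds, cs$ru)
    expect_equal(p$k_neighbors, cs$k)
    expect_equal(p$amplification, cs$n)
  }
  expect_error(select_balance_parameters(100, 1),
               class = "rusmote_too_few_minority")
})

test_that("auto-balanced datasets end up within a factor 2 of parity", {
  shapes <- list(c(75, 454), c(45, 454), c(25, 454), c(75, 150), c(75, 300))
  for (i in seq_along(shapes)) {
    ds <- make_gaussian_imbalanced(gaussian_spec(shapes[[i]][1],
                                                 shapes[[i]][2], seed = i))
    cnt <- dataset_counts(balance(ds, "auto", seed = i))
    ratio <- cnt[["minority"]] / cnt[["majority"]]
    expect_gte(ratio, 0.5)
    expect_lte(ratio, 2)
  }
  # the reference ratios end up within 15% of parity
  for (shape in list(c(75, 450), c(45, 450), c(25, 500))) {
    ds <- make_gaussian_imbalanced(gaussian_spec(shape[1], shape[2],
                                                 separation = 8, seed = 3))
    cnt <- dataset_counts(balance(ds, "auto", seed = 3))
    expect_lte(abs(cnt[["minority"]] - cnt[["majority"]]) / max(cnt), 0.15)
  }
})

test_that("balance composes its sub-operations and is bit-for-bit deterministic", {
  ds <- make_gaussian_imbalanced(gaussian_spec(75, 454, separation = 10,
                                               seed = 8))
  params <- resample_params(1, 3, 3)
  out <- balance(ds, params, seed = 21)
  cnt <- dataset_counts(out)
  expect_equal(cnt[["minority"]], 225)
  expect_equal(cnt[["majority"]], 227)

  out2 <- balance(ds, params, seed = 21)
  expect_identical(out$features, out2$features)
  expect_identical(out$labels, out2$labels)
  expect_identical(out$sample_ids, out2$sample_ids)
  expect_identical(attr(out, "provenance"), attr(out2, "provenance"))

  # identity configuration leaves an already-balanced dataset untouched
  bal <- tiny_dataset(10, 10)
  noop <- balance(bal, resample_params(0, 3, 1), seed = 1)
  expect_identical(noop$features, bal$features)
  expect_identical(noop$labels, bal$labels)
})

test_that("balanced counts match independently composed sub-operations", {
  withr::with_seed(99, seeds <- sample.int(1e6, 50))
  for (s in seeds) {
    withr::with_seed(s, {
      n_min <- sample(5:40, 1)
      n_maj <- sample(50:200, 1)
      sep <- runif(1, 1, 6)
      ru <- sample(0:2, 1)
      amp <- sample(1:4, 1)
    })
    ds <- make_gaussian_imbalanced(gaussian_spec(n_min, n_maj,
                                                 separation = sep, seed = s))
    out <- balance(ds, resample_params(ru, 3, amp), seed = s)
    cnt <- dataset_counts(out)
    n_noise <- length(attr(out, "noise_removed"))
    expect_equal(cnt[["minority"]], amp * n_min)
    expect_equal(cnt[["majority"]], ceiling((n_maj - n_noise) / 2^ru))
    expect_lte(n_noise, ceiling(0.05 * n_maj))
  }
})
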