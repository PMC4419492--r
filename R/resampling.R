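# The combined balancer: boundary-noise removal on the majority class, dyadic
# random undersampling, SMOTE oversampling of the minority class, and the
# deterministic rule that picks the resampling parameters from the class
# ratio.

#' Resampling parameters
#'
#' @param ru_rounds nonnegative integer `n`; the undersampling rate is
#'   `RU = 2^n` (each round halves the majority class).
#' @param k_neighbors SMOTE neighborhood size `K` (>= 1); clipped to
#'   `n_min - 1` at balance time if necessary.
#' @param amplification integer `N` (>= 1); the minority class ends with
#'   `N * n_min` samples, i.e. `N - 1` synthetics per original.
#' @return an object of class `resample_params`.
#' @export
resample_params <- function(ru_rounds, k_neighbors, amplification) {
  ru_rounds <- as.integer(ru_rounds)
  k_neighbors <- as.integer(k_neighbors)
  amplification <- as.integer(amplification)
  if (is.na(ru_rounds) || ru_rounds < 0) {
    abort_rusmote("ru_rounds must be a nonnegative integer",
                  "rusmote_bad_params")
  }
  if (is.na(k_neighbors) || k_neighbors < 1) {
    abort_rusmote("k_neighbors must be >= 1", "rusmote_bad_params")
  }
  if (is.na(amplification) || amplification < 1) {
    abort_rusmote("amplification must be >= 1", "rusmote_bad_params")
  }
  structure(list(ru_rounds = ru_rounds, k_neighbors = k_neighbors,
                 amplification = amplification),
            class = "resample_params")
}

#' @export
print.resample_params <- function(x, ...) {
  cat(sprintf("<resample_params> RU = 2^%d = %d, K = %d, N = %d\n",
              x$ru_rounds, 2^x$ru_rounds, x$k_neighbors, x$amplification))
  invisible(x)
}

#' Per-class centers and average radii
#'
#' Computes, for each class, the arithmetic mean of its feature rows and the
#' mean Euclidean distance of its members to that center. These define the
#' geometry used by the boundary-noise rule.
#'
#' @param dataset a [labeled_dataset()] with at least one sample per class.
#' @return an object of class `class_geometry`: list with `center_min`,
#'   `center_maj`, `r_ave_min`, `r_ave_maj`, `n_min`, `n_maj`.
#' @export
compute_class_geometry <- function(dataset) {
  validate_labeled_dataset(dataset)
  min_idx <- which(dataset$labels == 1)
  maj_idx <- which(dataset$labels == -1)
  if (length(min_idx) == 0 || length(maj_idx) == 0) {
    abort_rusmote("both classes must be present", "rusmote_empty_class")
  }
  geom_one <- function(x) {
    center <- colMeans(x)
    d <- sqrt(rowSums(sweep(x, 2, center, "-")^2))
    list(center = center, r_ave = mean(d))
  }
  gmin <- geom_one(dataset$features[min_idx, , drop = FALSE])
  gmaj <- geom_one(dataset$features[maj_idx, , drop = FALSE])
  structure(list(center_min = gmin$center, center_maj = gmaj$center,
                 r_ave_min = gmin$r_ave, r_ave_maj = gmaj$r_ave,
                 n_min = length(min_idx), n_maj = length(maj_idx)),
            class = "class_geometry")
}

#' Detect boundary-noise samples in the majority class
#'
#' A majority sample is flagged as boundary noise when it is (a) among the top
#' 5% of majority samples by distance to the majority center (the "boundary
#' set", size `ceiling(0.05 * n_maj)`, ties broken by original row index) and
#' (b) closer to the minority center than the minority class's average radius.
#' Such samples sit inside the minority cloud and drag the separating
#' hyperplane into it; they are removed before undersampling.
#'
#' @param dataset a [labeled_dataset()].
#' @param geometry optional [compute_class_geometry()] result for `dataset`;
#'   computed when missing.
#' @return integer vector of dataset row indices (majority rows only),
#'   ascending.
#' @export
detect_boundary_noise <- function(dataset, geometry = NULL) {
  if (is.null(geometry)) geometry <- compute_class_geometry(dataset)
  maj_idx <- which(dataset$labels == -1)
  xmaj <- dataset$features[maj_idx, , drop = FALSE]
  d_maj <- sqrt(rowSums(sweep(xmaj, 2, geometry$center_maj, "-")^2))
  n_boundary <- ceiling(0.05 * length(maj_idx))
  boundary <- order(-d_maj, seq_along(d_maj))[seq_len(n_boundary)]
  d_maj_min <- sqrt(rowSums(
    sweep(xmaj[boundary, , drop = FALSE], 2, geometry$center_min, "-")^2))
  sort(maj_idx[boundary[d_maj_min < geometry$r_ave_min]])
}

# Indices (into 1:nrow(samples)) kept by ru_rounds halving passes: rows are
# ranked by distance to their own mean (ties by row index) and every 2^n-th
# rank starting at the first survives. Iterated halving of a sorted sequence
# is exactly this stride.
ru_keep_indices <- function(samples, ru_rounds) {
  m <- nrow(samples)
  if (ru_rounds == 0 || m == 0) return(seq_len(m))
  center <- colMeans(samples)
  d <- sqrt(rowSums(sweep(samples, 2, center, "-")^2))
  ord <- order(d, seq_len(m))
  sort(ord[seq(1, m, by = 2^ru_rounds)])
}

#' Random undersampling by repeated halving
#'
#' Emulates dyadic decimation of an ordered sequence: samples are ordered by
#' distance to their own center (ties by original index) and each halving pass
#' keeps one sample from every adjacent pair, so the retained set preserves
#' the radial distribution of the original. The output size is exactly
#' `ceiling(m / 2^ru_rounds)`.
#'
#' @param samples numeric matrix, rows = samples.
#' @param ru_rounds nonnegative integer number of halving passes.
#' @param seed unused; the decimation is deterministic. Kept so all resampling
#'   operations share a signature.
#' @return matrix of retained rows, in original row order.
#' @export
random_undersample <- function(samples, ru_rounds, seed = NULL) {
  samples <- as.matrix(samples)
  ru_rounds <- as.integer(ru_rounds)
  if (is.na(ru_rounds) || ru_rounds < 0) {
    abort_rusmote("ru_rounds must be a nonnegative integer",
                  "rusmote_bad_params")
  }
  samples[ru_keep_indices(samples, ru_rounds), , drop = FALSE]
}

# Shared SMOTE core. `search` (defaults to standardized `minority`) defines
# the metric space for the K-nearest-neighbor lookup; interpolation always
# happens on the original rows, which gives the identical synthetic point
# because z-scoring is affine.
smote_core <- function(minority, k_neighbors, amplification, seed, search) {
  n <- nrow(minority)
  if (n < 2) {
    abort_rusmote("SMOTE needs at least 2 minority samples",
                  "rusmote_too_few_minority")
  }
  k <- as.integer(k_neighbors)
  if (k > n - 1) {
    warn_rusmote(sprintf("k_neighbors = %d exceeds n_min - 1 = %d; using %d",
                         k, n - 1, n - 1), "rusmote_k_adjusted")
    k <- n - 1L
  }
  n_synth <- (amplification - 1L) * n
  if (n_synth == 0) {
    return(list(samples = minority,
                provenance = data.frame(base = integer(), neighbor = integer(),
                                        delta = numeric()),
                k_used = k))
  }
  dmat <- as.matrix(stats::dist(search))
  diag(dmat) <- Inf
  nb <- t(apply(dmat, 1, function(row) order(row, seq_along(row))[seq_len(k)]))
  nb <- matrix(nb, nrow = n)  # k = 1 drops the dim otherwise
  base <- rep(seq_len(n), each = amplification - 1L)
  draws <- withr::with_seed(as.integer(seed), {
    list(pick = sample.int(k, n_synth, replace = TRUE),
         delta = stats::runif(n_synth))
  })
  neighbor <- nb[cbind(base, draws$pick)]
  synth <- minority[base, , drop = FALSE] +
    draws$delta * (minority[neighbor, , drop = FALSE] -
                     minority[base, , drop = FALSE])
  list(samples = rbind(minority, synth),
       provenance = data.frame(base = base, neighbor = neighbor,
                               delta = draws$delta),
       k_used = k)
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic sample is a point on the segment between a minority sample
#' `x_i` and one of its `K` nearest minority neighbors `x_i^(t)` (Euclidean,
#' self excluded): `x_s = x_i + delta * (x_i^(t) - x_i)` with `delta` uniform
#' on `[0, 1]`. Every original sample contributes `amplification - 1`
#' synthetics, each with an independently drawn neighbor and `delta`, so the
#' minority class grows to `amplification * n_min` rows.
#'
#' @param minority numeric matrix of minority-class rows (`n_min >= 2`).
#' @param k_neighbors neighborhood size `K`; values above `n_min - 1` are
#'   lowered with a warning.
#' @param amplification integer `N >= 1`; `N = 1` returns the originals only.
#' @param seed integer seed for the neighbor and `delta` draws.
#' @param standardize z-score the features for the neighbor metric (the
#'   interpolation itself is always on the original scale).
#' @return list with `samples` (original rows followed by synthetics),
#'   `provenance` (data frame `base`, `neighbor`, `delta`, one row per
#'   synthetic) and `k_used`.
#' @export
smote_oversample <- function(minority, k_neighbors, amplification, seed,
                             standardize = TRUE) {
  minority <- as.matrix(minority)
  search <- if (standardize) {
    apply_standardizer(minority, fit_standardizer(minority))
  } else {
    minority
  }
  smote_core(minority, k_neighbors, as.integer(amplification), seed, search)
}

#' Choose resampling parameters from the class ratio
#'
#' Given `N_ratio = n_maj / n_min`, picks the number of halving rounds and the
#' SMOTE amplification so that the post-balance class sizes
#' `n_maj / 2^ru_rounds` and `N * n_min` are as close as possible, under the
#' constraints `RU >= 2` and a neighborhood size in 3..6, without one side
#' over-adjusting. Concretely the rule enumerates `ru_rounds` in 1..8 and `N`
#' in 1..6 and minimizes `|log2(N_ratio) - ru_rounds - log2(N)|`, breaking
#' ties by the smaller `|2^ru_rounds - N|` (keep the two adjustments
#' comparable), then by fewer rounds, then smaller `N`. The neighborhood is
#' `K = min(max(N, 3), 6)`. This reproduces the reference settings
#' `N_ratio = 6 -> RU 2, K 3`; `10 -> RU 2, K 5`; `20 -> RU 4, K 5`.
#'
#' @param n_maj,n_min class sizes, `n_maj >= n_min >= 2`.
#' @return a [resample_params()].
#' @export
select_balance_parameters <- function(n_maj, n_min) {
  if (n_min < 2) {
    abort_rusmote("need at least 2 minority samples",
                  "rusmote_too_few_minority")
  }
  if (n_maj < n_min) {
    abort_rusmote("n_maj must be >= n_min", "rusmote_bad_params")
  }
  n_ratio <- n_maj / n_min
  grid <- expand.grid(ru = 1:8, n = 1:6)
  grid$mismatch <- abs(log2(n_ratio) - grid$ru - log2(grid$n))
  grid$lopsided <- abs(2^grid$ru - grid$n)
  best <- grid[order(grid$mismatch, grid$lopsided, grid$ru, grid$n), ][1, ]
  resample_params(best$ru, min(max(best$n, 3L), 6L), best$n)
}

#' Balance a dataset with the combined RU-SMOTE scheme
#'
#' Pipeline: (1) compute class geometry, (2) remove boundary-noise majority
#' samples ([detect_boundary_noise()]), (3) undersample the remaining majority
#' by `ru_rounds` halving passes, (4) SMOTE-oversample the minority with
#' amplification `N`. With `standardize = TRUE` (default) all distance
#' computations run on z-scored features (fit on this dataset, i.e. the
#' training fold); the returned features are on the original scale. The output
#' has `N * n_min` minority rows and
#' `ceiling((n_maj - #noise) / 2^ru_rounds)` majority rows.
#'
#' @param dataset a [labeled_dataset()] with both classes present.
#' @param params a [resample_params()], or `"auto"` to derive them from the
#'   class ratio via [select_balance_parameters()].
#' @param seed integer seed (expanded into sub-streams for the undersampling
#'   and SMOTE steps).
#' @param standardize use z-scored features for all distance computations.
#' @return a `labeled_dataset` whose synthetic rows have ids
#'   `syn_<base id>_<j>`; attributes `params` (the parameters used),
#'   `noise_removed` (row indices of `dataset` removed as boundary noise) and
#'   `provenance` (SMOTE provenance with ids resolved) record what was done.
#' @export
balance <- function(dataset, params = "auto", seed = 1, standardize = TRUE) {
  validate_labeled_dataset(dataset)
  cnt <- dataset_counts(dataset)
  if (cnt[["minority"]] == 0 || cnt[["majority"]] == 0) {
    abort_rusmote("both classes must be present", "rusmote_empty_class")
  }
  if (identical(params, "auto")) {
    params <- select_balance_parameters(cnt[["majority"]], cnt[["minority"]])
  }
  if (!inherits(params, "resample_params")) {
    abort_rusmote("params must be \"auto\" or a resample_params object",
                  "rusmote_bad_params")
  }
  seeds <- derive_seeds(seed, 2)

  z <- if (standardize) {
    apply_standardizer(dataset$features, fit_standardizer(dataset$features))
  } else {
    dataset$features
  }
  zds <- labeled_dataset(z, dataset$labels, dataset$feature_names,
                         dataset$sample_ids)
  noise <- detect_boundary_noise(zds)

  maj_idx <- setdiff(which(dataset$labels == -1), noise)
  keep_local <- ru_keep_indices(z[maj_idx, , drop = FALSE], params$ru_rounds)
  maj_keep <- maj_idx[keep_local]

  min_idx <- which(dataset$labels == 1)
  sm <- smote_core(dataset$features[min_idx, , drop = FALSE],
                   params$k_neighbors, params$amplification, seeds[2],
                   search = z[min_idx, , drop = FALSE])

  keep <- sort(c(min_idx, maj_keep))
  out_feat <- rbind(dataset$features[keep, , drop = FALSE],
                    sm$samples[-seq_along(min_idx), , drop = FALSE])
  n_synth <- nrow(sm$provenance)
  base_ids <- dataset$sample_ids[min_idx][sm$provenance$base]
  synth_ids <- if (n_synth > 0) {
    paste0("syn_", base_ids,
           "_", rep(seq_len(params$amplification - 1L), length(min_idx)))
  } else {
    character()
  }
  out <- labeled_dataset(out_feat,
                         c(dataset$labels[keep], rep(1, n_synth)),
                         dataset$feature_names,
                         c(dataset$sample_ids[keep], synth_ids))
  prov <- sm$provenance
  if (n_synth > 0) {
    prov$base_id <- base_ids
    prov$neighbor_id <- dataset$sample_ids[min_idx][sm$provenance$neighbor]
  }
  attr(out, "params") <- params
  attr(out, "noise_removed") <- noise
  attr(out, "provenance") <- prov
  out
}
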