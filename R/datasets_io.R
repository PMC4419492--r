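# Core data containers and file I/O: labeled feature tables (CSV), binary ROI
# voxel masks (NIfTI), and experiment configuration (YAML).

#' Construct a labeled dataset
#'
#' The basic container for classification data: a numeric feature matrix with
#' one row per sample plus a binary label per row. By convention the nodule
#' (minority) class is `+1` and the non-nodule (majority) class is `-1`.
#'
#' @param features numeric matrix, rows = samples, columns = named features.
#' @param labels vector of `+1`/`-1`, one per row.
#' @param feature_names optional character vector overriding
#'   `colnames(features)`.
#' @param sample_ids optional character vector of per-row identifiers;
#'   generated as `s0001, s0002, ...` when missing.
#' @return an object of class `labeled_dataset`: a list with elements
#'   `features`, `labels`, `feature_names`, `sample_ids`.
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c(1, -1), 5))
#' dataset_counts(ds)
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL,
                            sample_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  rownames(features) <- NULL
  labels <- as.numeric(labels)
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- paste0("f", seq_len(ncol(features)))
    }
  }
  colnames(features) <- feature_names
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(nrow(features)))
  }
  ds <- structure(
    list(features = features, labels = labels,
         feature_names = feature_names, sample_ids = as.character(sample_ids)),
    class = "labeled_dataset"
  )
  validate_labeled_dataset(ds)
  ds
}

validate_labeled_dataset <- function(ds) {
  n <- nrow(ds$features)
  if (length(ds$labels) != n || length(ds$sample_ids) != n) {
    abort_rusmote("features, labels and sample_ids must have matching lengths",
                  "rusmote_shape_mismatch")
  }
  if (n > 0 && !all(ds$labels %in% c(-1, 1))) {
    abort_rusmote("labels must be +1 or -1", "rusmote_bad_label")
  }
  if (n > 0 && !all(is.finite(ds$features))) {
    abort_rusmote("feature values must be finite", "rusmote_nonfinite_feature")
  }
  invisible(ds)
}

#' Number of samples per class
#'
#' @param dataset a [labeled_dataset()].
#' @return named integer vector with elements `minority` (+1) and
#'   `majority` (-1).
#' @export
dataset_counts <- function(dataset) {
  c(minority = sum(dataset$labels == 1), majority = sum(dataset$labels == -1))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cnt <- dataset_counts(x)
  cat(sprintf(
    "<labeled_dataset> %d samples (%d minority / %d majority), %d features\n",
    nrow(x$features), cnt[["minority"]], cnt[["majority"]], ncol(x$features)))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

# Row subset preserving all parallel fields.
subset_dataset <- function(ds, idx) {
  labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  ds$feature_names, ds$sample_ids[idx])
}

# Map raw label codes to {+1, -1}. Accepts 1/-1, 1/0 and nodule/nonnodule.
map_labels <- function(raw) {
  raw <- trimws(tolower(as.character(raw)))
  out <- rep(NA_real_, length(raw))
  out[raw %in% c("1", "+1", "nodule")] <- 1
  out[raw %in% c("-1", "0", "nonnodule", "non-nodule")] <- -1
  if (anyNA(out)) {
    abort_rusmote(
      sprintf("unrecognized label value(s): %s",
              paste(unique(raw[is.na(out)]), collapse = ", ")),
      "rusmote_bad_label")
  }
  out
}

#' Read a feature table from CSV
#'
#' Expects a header row with a `label` column, an optional `id` column and one
#' or more numeric feature columns. Labels may be coded `1`/`-1`, `1`/`0`
#' (0 mapped to -1) or `nodule`/`nonnodule`; they are always returned as
#' `+1`/`-1` with `+1` the nodule/minority class. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return a [labeled_dataset()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort_rusmote(sprintf("empty or missing feature table: %s", path),
                  "rusmote_empty_table")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% names(df)) {
    abort_rusmote("feature table has no 'label' column",
                  "rusmote_missing_label")
  }
  if (nrow(df) == 0) {
    abort_rusmote("feature table has a header but no rows",
                  "rusmote_empty_table")
  }
  labels <- map_labels(df$label)
  ids <- if ("id" %in% names(df)) as.character(df$id) else NULL
  feat_cols <- setdiff(names(df), c("id", "label"))
  if (length(feat_cols) == 0) {
    abort_rusmote("feature table has no feature columns", "rusmote_empty_table")
  }
  feats <- df[feat_cols]
  bad <- !vapply(feats, is.numeric, logical(1))
  if (any(bad)) {
    abort_rusmote(
      sprintf("non-numeric feature column(s): %s",
              paste(feat_cols[bad], collapse = ", ")),
      "rusmote_nonnumeric_feature")
  }
  labeled_dataset(as.matrix(feats), labels, feat_cols, ids)
}

#' Write a feature table to CSV
#'
#' Columns are `id,label,<features...>`; numeric values are written with 17
#' significant digits so a write/read round trip is lossless at double
#' precision.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(dataset, path) {
  validate_labeled_dataset(dataset)
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_rusmote(
                    sprintf("cannot write to %s", path), "rusmote_unwritable"))
  on.exit(close(con))
  writeLines(paste(c("id", "label", dataset$feature_names), collapse = ","),
             con)
  n <- nrow(dataset$features)
  if (n > 0) {
    num <- apply(dataset$features, 2, function(col) sprintf("%.17g", col))
    num <- matrix(num, nrow = n)
    rows <- apply(cbind(dataset$sample_ids,
                        sprintf("%d", as.integer(dataset$labels)), num),
                  1, paste, collapse = ",")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Construct an ROI volume
#'
#' A binary 3D voxel mask with physical voxel spacing. Arrays are indexed in
#' the native NIfTI order `[x, y, z]` (column-major, x fastest) and spacing is
#' `(dx, dy, dz)` in mm/voxel in the same order.
#'
#' @param mask 3D array; values are binarized with a 0.5 threshold.
#' @param spacing numeric length-3, strictly positive, mm per voxel.
#' @param id opaque identifier.
#' @return an object of class `roi_volume` with elements `mask` (logical 3D
#'   array), `spacing`, `id`.
#' @export
roi_volume <- function(mask, spacing = c(1, 1, 1), id = "roi") {
  if (length(dim(mask)) != 3) {
    abort_rusmote("mask must be a 3D array", "rusmote_not_3d")
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_rusmote("spacing must be 3 strictly positive numbers",
                  "rusmote_bad_spacing")
  }
  structure(list(mask = array(mask > 0.5, dim(mask)),
                 spacing = as.numeric(spacing), id = as.character(id)),
            class = "roi_volume")
}

#' @export
print.roi_volume <- function(x, ...) {
  cat(sprintf("<roi_volume> '%s' %s voxels @ (%s) mm, %d foreground\n",
              x$id, paste(dim(x$mask), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' Read a binary ROI volume from a NIfTI file
#'
#' Voxel spacing is taken from the file header; intensities are binarized at
#' 0.5. An all-background mask is accepted here and only rejected when feature
#' extraction is attempted.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return an [roi_volume()].
#' @export
read_roi_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    abort_rusmote(sprintf("expected a 3D image, got %d dimension(s)",
                          length(d)), "rusmote_not_3d")
  }
  roi_volume(array(as.numeric(img), d), RNifti::pixdim(img),
             sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write an ROI volume to a NIfTI file
#'
#' @param roi an [roi_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_roi_volume <- function(roi, path) {
  img <- RNifti::asNifti(array(as.double(roi$mask), dim(roi$mask)))
  RNifti::pixdim(img) <- roi$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Experiment configuration
#'
#' Bundles the resampling, classifier and cross-validation settings used by
#' [run_comparison()] and the command-line tool. The defaults are the reference
#' protocol: RBF kernel with `C = 10`, SMOTE-SVM at `N = 5, K = 5`, the
#' combined balancer at `RU = 2, N = 3, K = 3`, and five repeated stratified
#' half splits.
#'
#' @param resample `"auto"` or a [resample_params()] object used by the
#'   combined balancer.
#' @param svm list with `kernel` (`"rbf"` or `"linear"`), `C`, and optional
#'   `gamma`.
#' @param smote list with `amplification` and `k_neighbors` for the SMOTE-only
#'   classifier arm.
#' @param cv_repeats positive integer `m`, the number of repeated half splits.
#' @param seed integer; all randomness flows from this value.
#' @param standardize logical; z-score features (fit on the training fold
#'   only) before distance computations and SVM training.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(resample = "auto",
                              svm = list(kernel = "rbf", C = 10),
                              smote = list(amplification = 5, k_neighbors = 5),
                              cv_repeats = 5,
                              seed = 1,
                              standardize = TRUE) {
  if (!identical(resample, "auto") && !inherits(resample, "resample_params")) {
    abort_rusmote("resample must be \"auto\" or a resample_params object",
                  "rusmote_bad_config")
  }
  cv_repeats <- as.integer(cv_repeats)
  if (is.na(cv_repeats) || cv_repeats < 1) {
    abort_rusmote("cv_repeats must be a positive integer", "rusmote_bad_config")
  }
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    abort_rusmote("seed must be set explicitly", "rusmote_bad_config")
  }
  svm <- utils::modifyList(list(kernel = "rbf", C = 10, gamma = NULL), svm)
  smote <- utils::modifyList(list(amplification = 5, k_neighbors = 5), smote)
  structure(list(resample = resample, svm = svm, smote = smote,
                 cv_repeats = cv_repeats, seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; a `resample`
#' mapping with `ru_rounds`, `k_neighbors` and `amplification` keys is turned
#' into a [resample_params()] object.
#'
#' @param path path to a YAML file.
#' @return an `experiment_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("svm", "smote", "cv_repeats", "seed", "standardize")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$resample)) {
    args$resample <- if (identical(raw$resample, "auto")) "auto" else
      resample_params(raw$resample$ru_rounds, raw$resample$k_neighbors,
                      raw$resample$amplification)
  }
  do.call(experiment_config, args)
}
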