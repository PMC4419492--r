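# Experiment harness: repeated stratified half-split cross-validation
# comparing four classifiers on identical test halves — plain C-SVM,
# biased SVM, SMOTE-SVM and the combined RU-SMOTE-SVM.

CLASSIFIER_NAMES <- c("svm", "biased_svm", "smote_svm", "rusmote_svm")

#' Stratified half split
#'
#' Each class is split as evenly as possible into a training and a test half
#' (odd counts give the extra sample to the training half). The two halves
#' are disjoint and together contain every sample exactly once.
#'
#' @param dataset a [labeled_dataset()] with at least 2 samples per class.
#' @param seed integer seed for the per-class permutations.
#' @return list with `train` and `test` datasets.
#' @export
split_half <- function(dataset, seed = 1) {
  validate_labeled_dataset(dataset)
  cnt <- dataset_counts(dataset)
  if (any(cnt < 2)) {
    abort_rusmote("each class needs at least 2 samples to split",
                  "rusmote_too_few_samples")
  }
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(c(1, -1), function(lab) {
      idx <- which(dataset$labels == lab)
      perm <- sample(idx)
      perm[seq_len(ceiling(length(idx) / 2))]
    }))
  })
  train_idx <- sort(train_idx)
  list(train = subset_dataset(dataset, train_idx),
       test = subset_dataset(dataset, setdiff(seq_along(dataset$labels),
                                              train_idx)))
}

# Train the four-classifier roster on `train` and evaluate every one on the
# same `test`. Returns a data frame: one row per classifier with confusion
# counts and all metrics.
compare_on_split <- function(train, test, config, seed) {
  seeds <- derive_seeds(seed, 2)
  kern <- kernel_spec(config$svm$kernel, config$svm$gamma)
  C <- config$svm$C
  std <- config$standardize
  cnt <- dataset_counts(train)

  smoted <- {
    min_idx <- which(train$labels == 1)
    sm <- smote_oversample(train$features[min_idx, , drop = FALSE],
                           config$smote$k_neighbors,
                           config$smote$amplification, seeds[1],
                           standardize = std)
    n_syn <- nrow(sm$provenance)
    labeled_dataset(
      rbind(train$features, sm$samples[-seq_along(min_idx), , drop = FALSE]),
      c(train$labels, rep(1, n_syn)),
      train$feature_names,
      c(train$sample_ids, sprintf("syn_%04d", seq_len(n_syn))))
  }
  models <- list(
    svm = train_csvm(train, C, kern, std),
    biased_svm = train_biased_svm(
      train, C,
      biased_penalty_from_ratio(C, cnt[["majority"]] / cnt[["minority"]]),
      kern, std),
    smote_svm = train_csvm(smoted, C, kern, std),
    rusmote_svm = train_csvm(balance(train, config$resample, seeds[2], std),
                             C, kern, std))

  rows <- lapply(CLASSIFIER_NAMES, function(nm) {
    cm <- confusion(test$labels, predict(models[[nm]], test$features))
    rep <- suppressWarnings(evaluate(cm))
    data.frame(classifier = nm, TP = cm$TP, FN = cm$FN, FP = cm$FP,
               TN = cm$TN, as.data.frame(unclass(rep)))
  })
  do.call(rbind, rows)
}

#' Run the four-classifier comparison under repeated half-split CV
#'
#' For each of `m = config$cv_repeats` repeats: draw a fresh stratified half
#' split, train the four classifiers — plain C-SVM and biased SVM on the raw
#' training half, C-SVM on the SMOTE-balanced half, and C-SVM on the combined
#' RU-SMOTE-balanced half — and evaluate all four on the identical test half.
#'
#' @param dataset a [labeled_dataset()].
#' @param config an [experiment_config()].
#' @return an object of class `experiment_result`: list with `per_repeat`
#'   (data frame, one row per classifier per repeat), `aggregate` (mean of
#'   each metric per classifier), `mean_counts` (mean confusion counts) and
#'   `metrics_of_mean_counts` (metrics recomputed from the rounded mean
#'   counts, the other reading of "average results").
#' @export
run_comparison <- function(dataset, config = experiment_config()) {
  seeds <- derive_seeds(config$seed, 2 * config$cv_repeats)
  per_repeat <- do.call(rbind, lapply(seq_len(config$cv_repeats), function(r) {
    halves <- split_half(dataset, seeds[2 * r - 1])
    out <- compare_on_split(halves$train, halves$test, config, seeds[2 * r])
    cbind(repeat_ = r, out)
  }))
  metric_cols <- setdiff(names(per_repeat),
                         c("repeat_", "classifier", "TP", "FN", "FP", "TN"))
  agg <- stats::aggregate(per_repeat[metric_cols],
                          list(classifier = per_repeat$classifier), mean)
  agg <- agg[match(CLASSIFIER_NAMES, agg$classifier), ]
  mean_counts <- stats::aggregate(per_repeat[c("TP", "FN", "FP", "TN")],
                                  list(classifier = per_repeat$classifier),
                                  mean)
  mean_counts <- mean_counts[match(CLASSIFIER_NAMES, mean_counts$classifier), ]
  momc <- do.call(rbind, lapply(seq_len(nrow(mean_counts)), function(i) {
    cm <- confusion_matrix(round_half_up(mean_counts$TP[i]),
                           round_half_up(mean_counts$FN[i]),
                           round_half_up(mean_counts$FP[i]),
                           round_half_up(mean_counts$TN[i]))
    data.frame(classifier = mean_counts$classifier[i],
               as.data.frame(unclass(suppressWarnings(evaluate(cm)))))
  }))
  structure(list(per_repeat = per_repeat, aggregate = agg,
                 mean_counts = mean_counts, metrics_of_mean_counts = momc,
                 config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, digits = 4, ...) {
  cat(sprintf("<experiment_result> m = %d repeats\n", x$config$cv_repeats))
  cat("mean confusion counts:\n")
  print(cbind(x$mean_counts[1],
              round(x$mean_counts[-1])), row.names = FALSE)
  cat("mean metrics across repeats:\n")
  agg <- x$aggregate
  agg[-1] <- lapply(agg[-1], round, digits)
  print(agg[c("classifier", "accuracy", "acc_plus", "acc_minus",
              "g_mean", "f_measure")], row.names = FALSE)
  invisible(x)
}

#' Accuracy sweep over training-set imbalance ratios
#'
#' Rebuilds the robustness experiment: several training datasets with
#' different majority/minority ratios are evaluated against one fixed test
#' set. Each spec is repeated `config$cv_repeats` times with fresh generator
#' seeds; the table reports the mean accuracy per classifier per spec.
#'
#' @param dataset_specs list of [gaussian_spec()] objects describing the
#'   training sets.
#' @param config an [experiment_config()].
#' @param test_spec a [gaussian_spec()] for the fixed test set; defaults to
#'   the reference test shape (75 vs 454) with the same distributional
#'   parameters as the first training spec.
#' @return data frame: one row per spec with `n_min`, `n_maj`, `n_ratio` and
#'   one mean-accuracy column per classifier.
#' @export
ratio_sweep <- function(dataset_specs, config = experiment_config(),
                        test_spec = NULL) {
  if (!length(dataset_specs)) {
    abort_rusmote("dataset_specs must be a nonempty list", "rusmote_bad_spec")
  }
  seeds <- derive_seeds(config$seed,
                        1 + 2 * length(dataset_specs) * config$cv_repeats)
  if (is.null(test_spec)) {
    s1 <- dataset_specs[[1]]
    test_spec <- gaussian_spec(75, 454, s1$dim, s1$separation,
                               s1$minority_scale, s1$majority_scale,
                               0, seeds[1])
  }
  test <- make_gaussian_imbalanced(test_spec)
  rows <- lapply(seq_along(dataset_specs), function(i) {
    spec <- dataset_specs[[i]]
    acc <- sapply(seq_len(config$cv_repeats), function(r) {
      j <- 2 * ((i - 1) * config$cv_repeats + r - 1)
      train <- make_gaussian_imbalanced(
        gaussian_spec(spec$n_min, spec$n_maj, spec$dim, spec$separation,
                      spec$minority_scale, spec$majority_scale,
                      spec$noise_fraction, seeds[j + 2]))
      res <- compare_on_split(train, test, config, seeds[j + 3])
      stats::setNames(res$accuracy, res$classifier)
    })
    acc <- if (is.matrix(acc)) rowMeans(acc) else acc
    data.frame(n_min = spec$n_min, n_maj = spec$n_maj,
               n_ratio = spec$n_maj / spec$n_min,
               as.list(acc))
  })
  do.call(rbind, rows)
}
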