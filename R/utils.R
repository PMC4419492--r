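# Internal helpers: classed errors, seed substreams, standardization.

abort_rusmote <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "rusmote_error"), call = call))
}

warn_rusmote <- function(message, class) {
  warning(warningCondition(message, class = c(class, "rusmote_warning")))
}

#' Derive independent sub-seeds from one master seed
#'
#' Every stochastic operation in the package takes an explicit seed; compound
#' operations expand theirs into sub-seeds so that, e.g., changing the SMOTE
#' amplification does not perturb the undersampling draw.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Fit z-score constants on a matrix; zero-variance columns get scale 1 so they
# pass through unchanged instead of producing NaN.
fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
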