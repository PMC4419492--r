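---
title: "Methods: imbalance-aware nodule ROI classification with rusmote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware nodule ROI classification with rusmote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rusmote)
```

## The problem

Candidate regions of interest (ROIs) from chest CT are overwhelmingly
non-nodules: a realistic candidate set has on the order of six non-nodules per
true nodule, and the cost of the two error types is asymmetric — a missed
nodule delays diagnosis, while a false positive merely adds one case to the
radiologist's review queue. A soft-margin SVM trained on such data drifts
toward the majority class: the margin term dominates, the few minority samples
that should pin down the positive-side support hyperplane are missing, and the
decision boundary "pushes" into the minority region. Overall accuracy stays
high while minority recall collapses, which is exactly the failure mode that
matters clinically.

`rusmote` addresses this at the data level (a combined balancer) and at the
classifier level (per-class penalties), and evaluates everything with
imbalance-aware metrics.

## The combined balancer

Let $x_{maj}, x_{min}$ denote majority and minority feature vectors,
$n_{maj}, n_{min}$ the class sizes. Both class centers are arithmetic means,
and each class's *average radius* is the mean Euclidean distance of its
members to their own center. `balance()` applies four steps, in this order:

1. **Geometry.** Compute centers and average radii
   (`compute_class_geometry()`).
2. **Boundary-noise removal.** Rank majority samples by distance to the
   majority center; the top 5% ($\lceil 0.05\,n_{maj}\rceil$, ties broken by
   row index) form the boundary set. A boundary sample closer to the minority
   center than the minority average radius sits inside the minority cloud and
   is deleted (`detect_boundary_noise()`). Only majority samples are ever
   removed: the asymmetric cost argument above means minority samples are
   never discarded.
3. **Dyadic undersampling.** The remaining majority samples are decimated
   like a signal: ordered, then one of every two adjacent samples is kept,
   $n$ times, so the undersampling rate is $RU = 2^n$ and the retained count
   is exactly $\lceil m / 2^n \rceil$. "Adjacent" is undefined for an
   unordered point set, so the package orders by distance to the class center
   (ties by original index): alternate ranks of the radial order preserve the
   radial distribution, and the operation becomes fully deterministic. The
   distribution-preservation claim is tested with two-sample
   Kolmogorov–Smirnov checks at $10^4$ draws.
4. **SMOTE oversampling.** Every minority sample $x_i$ contributes $N - 1$
   synthetics $x_s = x_i + \delta\,(x_i^{(t)} - x_i)$, where $x_i^{(t)}$ is
   drawn uniformly from the $K$ Euclidean-nearest minority neighbors (self
   excluded, with replacement across the $N-1$ draws) and
   $\delta \sim U[0,1]$; the minority class grows to $N\,n_{min}$. Each
   synthetic's $(i, t, \delta)$ triple is recorded as provenance so tests can
   replay the interpolation exactly; every synthetic lies on a segment
   between minority points and hence in the minority convex hull.

The published balanced-count table is reproduced by construction: 454
majority samples with no detected noise at $RU = 2$ yield
$\lceil 454/2\rceil = 227$; 75 minority samples at $N = 3$ yield 225 (and 375
at $N = 5$).

### Parameter selection

Given $N_{ratio} = n_{maj}/n_{min}$, the balancer should meet in the middle:
$n_{maj}/2^{ru}$ and $N\,n_{min}$ as close as possible without one side
over-adjusting, under $RU \ge 2$ and a neighborhood size in $3..6$.
`select_balance_parameters()` enumerates $ru \in 1..8$, $N \in 1..6$ and
minimizes $|\log_2 N_{ratio} - ru - \log_2 N|$, breaking ties by the smaller
$|2^{ru} - N|$ (keep the two adjustments comparable), then fewer rounds, then
smaller $N$; the SMOTE neighborhood is $K = \min(\max(N, 3), 6)$. This
reproduces the three reference settings ($N_{ratio} = 6 \to RU\,2, K\,3$;
$10 \to RU\,2, K\,5$; $20 \to RU\,4, K\,5$). A simpler closed form we
considered first, $ru = \max(1, \mathrm{round}(\log_2\sqrt{N_{ratio}}))$,
fails at $N_{ratio} = 10$ (it rounds to two halving rounds); the enumeration
is the rule precisely because each printed setting is its unique minimizer.
Allowing $N$ down to 1 (while keeping $K \ge 3$) lets mildly imbalanced
inputs ($N_{ratio} = 2$) balance by undersampling alone instead of being
forced to triple the minority class; the post-balance ratio stays within
$[1/2, 2]$ for every $N_{ratio} \le 20$.

### Standardization

The eight shape features span orders of magnitude (a volume in mm³ against a
unit-interval circularity), and every distance above — class radii, the noise
rule, SMOTE neighborhoods, the RBF kernel — is scale-sensitive. By default all
distance computations and SVM training run on z-scored features, with the
constants fitted on the training fold only and re-applied at prediction time;
sample counts and all reported metrics are scale-invariant, so
standardization affects which neighbors are chosen but never the accounting.
SMOTE interpolation is affine, so interpolating original-scale rows with
neighbors found in standardized space gives the same synthetic point as
interpolating standardized rows and back-transforming.

## Classifiers

`train_csvm()` solves the usual dual soft-margin problem with box constraint
$0 \le \alpha_i \le C$ and decision function
$f(x) = \mathrm{sign}\left(\sum_i \alpha_i y_i K(x, x_i) + b\right)$;
`train_biased_svm()` replaces the single box constraint with $C_+$ for
minority and $C_-$ for majority coefficients, making minority errors more
expensive. The quadratic program itself is delegated to libsvm (through
e1071) — per-class boxes are expressed exactly as class weights on the cost —
while the package owns the kernel specification, standardization, penalty
rule and decision function, and exposes $\alpha$, $b$ and the support set so
tests audit dual feasibility ($\sum_i \alpha_i y_i = 0$, class-wise boxes)
directly. With $C_+ = C_-$ the biased model is the plain C-SVM; the test
suite asserts this reduction numerically.

Defaults and their reasons:

* `C = 10`, RBF kernel: the reference experimental setting.
* `C_minus = max(1, round(C_plus / round(N_ratio)))` (rounding half away from
  zero): scales the majority penalty down by the imbalance, e.g. $C_+ = 10$
  at ratio $454/75 \approx 6$ gives $C_- = 2$.
* RBF width $\gamma = 1/(d\,\bar v)$ with $\bar v$ the mean per-feature
  variance of the (standardized) training matrix — the scale-free choice; on
  z-scored features it reduces to $1/d$. The reference protocol never states
  $\gamma$, so this default is a package decision, configurable via
  `kernel_spec()`.
* Solver tolerance $10^{-4}$. Ties in the decision function
  ($f(x) = 0$) map to $+1$: when undecided, flag the nodule.

## Shape features

Eight descriptors per ROI, four computed on the largest-area axial slice and
four on the volume. Dimensionless features are clamped to $[0, 1]$ where
their definition bounds them; discretization can otherwise push a ratio
marginally past 1.

* **circularity** — largest inscribed radius (distance-transform maximum)
  over circumscribed radius (max centroid-to-boundary distance); 1 for a
  disc.
* **elongation** — min over max centroid-to-boundary distance.
* **compactness** — $4\pi A / P^2$. The perimeter $P$ uses the 4-direction
  Crofton estimator (weighted counts of $2\times 2$ pixel configurations):
  naive staircase lengths overestimate a digital circle's perimeter by
  $\sim 5\%$ and pixel-edge (crack) lengths by $27\%$, which would push a
  disc's compactness down to 0.62; the Crofton estimate keeps it at 0.97.
  The estimator assumes near-isotropic in-plane pixels (true of CT) and uses
  $\sqrt{d_x d_y}$ as its scale.
* **moment** — the rotation/translation/scale-invariant normalized second
  moment $\eta_{20} + \eta_{02}$; $1/(2\pi)$ for a disc.
* **volume** — foreground voxels × voxel volume.
* **surface_area** — exposed voxel faces (6-connectivity) × face area. This
  voxel-face estimate systematically exceeds the smooth surface (a voxelized
  sphere reports $\approx 1.5\times$ its smooth area), so…
* **sphericity** — $\pi^{1/3}(6V)^{2/3}/A$ — is a *relative* sphericity:
  $\approx 0.65$ for a voxel sphere, lower for elongated shapes. Rankings,
  which are what the classifier uses, are preserved; tests assert the
  monotone response to stretching rather than absolute values.
* **centroid_offset** — mean in-plane distance between per-slice centroids
  and the projected volume centroid, normalized by the volume-equivalent
  radius $(3V/4\pi)^{1/3}$; near 0 for compact blobs, large for tilted
  vessel-like tubes.

Degenerate single-pixel slices define all ratios as 1 and the moment as 0.
Multi-component slices keep the largest component (with a message). Masks are
stored in native NIfTI `[x, y, z]` index order with spacing $(d_x, d_y, d_z)$
in mm, read from the file header and never guessed.

## Synthetic data: what it emulates, and what it does not

Two generators make the whole pipeline testable without any image download:

* `make_gaussian_imbalanced()` draws two isotropic Gaussian clusters in
  feature space with a configurable center separation (units of within-class
  SD). Default separation 3: close enough that a plain SVM at ratio ~6
  visibly loses minority recall (mirroring the published gap), far enough to
  be learnable. Planted boundary noise (`noise_fraction`) replaces
  `round(noise_fraction * n_maj)` majority rows with points drawn uniformly
  inside the minority empirical average radius *and* beyond the 99th
  percentile of majority center distances. The second clause is deliberately
  stricter than the 95% cutoff the detector uses: in 8 dimensions a planted
  point merely beyond the 95th percentile would often be outranked by the
  genuine majority tail and fall outside the top-5% boundary set, making
  recovery a coin flip of the generator rather than a property of the
  detector. With the stricter bound, recovery is essentially exact.
* `make_ellipsoid_roi()` / `make_paperlike_cohort()` build toy voxel masks:
  nodules as near-spherical ellipsoids (pairwise axis ratios in
  $[0.8, 1.25]$) with mild surface jitter, non-nodules as elongated tilted
  capsules (long/short $\ge 3$), within the reference dimension ranges
  (10–50 voxels in plane, 5–13 layers), at the reference cohort size
  (150 vs 908).

What the toy cohort does *not* show: real candidate ROIs are not cleanly
ellipsoidal, and the two shape families here are separable in feature space —
on the toy cohort every classifier, balanced or not, reaches perfect test
metrics, so cohort-level comparisons only assert orderings (never strict
gaps). The Gaussian generator is the harder testbed where the imbalance
pathology actually appears. One published claim does not transfer at all:
the robustness result that the combined balancer's *accuracy* varies least
across training ratios. On smooth Gaussian clusters a plain SVM's accuracy is
already nearly constant in the training ratio (accuracy is majority-dominated
and the majority is always learned), while the balancer trades majority
accuracy for minority recall by a ratio-dependent amount — so on synthetic
data the balancer's accuracy variance is typically *larger*. `ratio_sweep()`
implements and reports the full protocol, but the package does not assert the
variance ordering on data that cannot express it.

## Experiment harness

`split_half()` makes a stratified half/half split (odd counts give the extra
sample to training). `run_comparison()` repeats `m` times (default 5): each
repeat trains four classifiers — plain C-SVM and biased SVM on the raw
training half, C-SVM after SMOTE-only balancing ($N = K = 5$), and C-SVM
after the combined balancer (default auto parameters, which reproduce
$RU = 2, N = K = 3$ at ratio 6) — and evaluates all four on the identical
test half. The reference protocol describes one fixed train/test assignment
repeated; that literal reading is the default (each repeat is a fresh
stratified split used once as train, once as test).

"Average results" is ambiguous between averaging metrics and computing
metrics of averaged counts; the result object reports both
(`aggregate` and `metrics_of_mean_counts`), with the metric mean as the
headline number.

Metrics come from the confusion matrix with the minority as positive class:
overall accuracy, TPR/FPR, per-class accuracies, their geometric mean
(G-mean), precision, recall, and F-measure. Zero denominators yield `NA`
with a classed warning — never a silent 0. Printed reports round to 4
decimals; everything internal is full double precision.

## Determinism and problem sizes

Every stochastic operation takes an explicit seed and touches no global RNG
state (`withr::with_seed`); compound operations expand their seed into
sub-streams so that changing one stage's parameters does not perturb
another's draws. `balance()` and `run_comparison()` are bit-for-bit
reproducible given (data, parameters, seed).

The test suite runs its Monte-Carlo properties at deliberately modest sizes
chosen to make the statistics stable: 20 seeds for directional classifier
comparisons, $10^4$–$2\times 10^4$ draws for distribution-preservation
checks, exhaustive enumeration of confusion matrices to total 30, and one
full 1058-volume cohort for the end-to-end ordering check. The complete
suite finishes in well under a minute.

## Known limitations

* The 2D Crofton perimeter assumes isotropic in-plane pixels; strongly
  anisotropic in-plane spacing would bias compactness.
* Absolute sphericity values are voxel-surface-relative (see above); compare
  only within the pipeline.
* The balancer and classifiers are strictly two-class.
* No probability calibration, ROC/FROC analysis, or hyperparameter search;
  `C`, $\gamma$ and the resampling parameters are either the reference
  settings or explicit arguments.
* NIfTI is the only supported volume format; DICOM ingestion and lung
  segmentation are out of scope — the package starts from candidate ROI
  masks or precomputed feature tables.
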