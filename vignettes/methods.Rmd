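---
title: "Distance-based evaluation of neurorehabilitation from functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based evaluation of neurorehabilitation from functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rehabdist)
```

## The problem

Clinical rating scales for motor recovery (after spinal cord injury,
stroke, and similar conditions) are ordinal, rater-dependent, and coarse.
Resting-state fMRI offers a complementary, physiology-based readout: if a
patient's whole-brain functional organization is measurably different from
that of healthy controls, then the *degree* of that difference is a
candidate severity index, and its change over repeated scans is a candidate
recovery index.

`rehabdist` implements this idea as a concrete pipeline:

1. summarize each scan as a region-by-region **functional connectivity
   (FC) network**;
2. find the network edges that **discriminate patients from controls**;
3. fit a **linear decision boundary** between the two groups in the space
   of those edges;
4. score every scan — including follow-up scans of the same patient — by
   its **signed Euclidean distance to that boundary**. Motion toward the
   healthy side of the boundary is read as functional recovery.

## 1. Connectivity networks

For one scan, let $x_i(t)$ be the mean time course of region $i$ of a
$k$-region parcellation ($t = 1, \dots, T$). The network is the $k \times
k$ matrix of Pearson correlations

$$ R_{ij} = \operatorname{corr}(x_i, x_j), $$

symmetric with unit diagonal. Because the matrix is symmetric, a scan is
represented by its upper triangle, vectorized in lexicographic order
($i < j$), giving $E = k(k-1)/2$ edge features. `pearson_connectivity()`
builds the matrix from a $T \times k$ time-series matrix;
`extract_roi_timeseries()` produces that matrix from a 4D NIfTI image plus
an integer-labeled atlas (with nearest-neighbour label resampling when the
grids differ); `vectorize_edges()`/`devectorize_edges()` convert between
matrix and edge-vector forms. An optional Fisher $z$ transform
(`fisher_z()`) is provided for users who prefer variance-stabilized edges,
but the core pipeline operates on raw correlations, which are naturally
bounded and directly interpretable.

## 2. Discriminative edge selection

With $n_c$ control and $n_p$ patient first-session scans, each of the $E$
edges gets a two-sample $t$-test (patient minus control orientation;
pooled-variance by default, Welch optionally). Edges with $p < \alpha$
(default $\alpha = 0.05$, deliberately uncorrected) form the significant
set used as the feature space. `ttest_filter()` implements this; edges
with zero pooled variance carry no information and are skipped with a
warning rather than producing undefined statistics.

The uncorrected threshold is a *screening* device, not an inferential
claim about individual edges: the goal is a feature space in which the two
groups separate, and validity is then established at the whole-model level
(cross-validation and permutation, below), not edge by edge.

## 3. The linear decision boundary

Patients are labeled $+1$ and controls $-1$. In the selected-edge space,
the package fits the standard soft-margin linear SVM

$$ \min_{w, b, \xi} \; \tfrac12 \lVert w \rVert^2 + C \sum_i \xi_i
   \quad \text{s.t.} \quad y_i (w^\top v_i + b) \ge 1 - \xi_i, \;
   \xi_i \ge 0, $$

with $C = 1$ by default (`train_linear_svm()`, backed by libsvm via
**e1071**; features are *not* rescaled, since correlations already share a
common scale). The package's test suite independently verifies the
returned hyperplane against a generic interior-point quadratic-programming
solve of the dual.

Any session vector $v$ — training or follow-up — is then scored by its
signed distance to the boundary,

$$ d(v) = \frac{w^\top v + b}{\lVert w \rVert}, $$

(`signed_distance()`): positive on the patient side, negative on the
healthy side, in units of the edge space. A decision value of exactly zero
is classified as control. The clinical reading is that a patient whose
follow-up sessions drift from positive toward negative $d$ is moving, in
FC terms, toward the healthy group.

## 4. Validation protocol

`run_pipeline()` (and the corresponding CLI subcommands) assembles the
full protocol:

* **Leave-one-out cross-validation** (`loocv_classify()`): accuracy,
  precision, sensitivity, specificity from held-out first sessions.
* **Label-permutation test** (`permutation_test()`): the LOOCV accuracy is
  re-computed under randomly permuted group labels; the $p$-value uses the
  positively biased estimator $p = (1 + \#\{\text{perm} \ge
  \text{obs}\})/(n_{\text{perm}} + 1)$, which can never return 0.
* **2-means clustering check** (`kmeans_validation()`): an unsupervised
  sanity check that the two groups form separable clusters in the selected
  edge space, scored against the best of the two cluster-to-class
  matchings over 50 seeded restarts.
* **Intra-group paired tests** (`intra_group_tests()`): paired $t$,
  Wilcoxon signed-rank (reported as the *smaller* of the two signed-rank
  sums, the convention used in clinical tables), and Shapiro–Wilk
  normality checks on session-1 versus session-2 distances and scores.
* **Normalized trajectories** (`distance_trajectories()`): per subject,
  distances are $z$-scored and sign-flipped, $d^* = -(d - \bar d)/s_d$,
  and clinical scores $z$-scored, $s^* = (s - \bar s)/s_s$ (sample SD), so
  that both increase with recovery on a common scale and can be compared
  or correlated directly.

### Two feature-selection modes, and why both exist

`selection_mode = "paper"` (default) fits the edge filter once on *all*
labeled first sessions and reuses it inside every LOOCV fold. This matches
common practice in the applied literature, but it leaks the held-out label
into feature selection. The leakage is not cosmetic: with $n = 40$
subjects and 3321 candidate edges, a cohort with *no group signal at all*
still yields paper-mode LOOCV accuracy near 1.0, because screening
thousands of noise edges on the full sample always finds some that
separate it. `selection_mode = "nested"` refits the filter inside each
fold, restoring an honest estimate (≈ 0.5 on null cohorts). The package
ships both, documents the difference, and the acceptance tests assert the
gap directly.

The same phenomenon dictates the permutation-test default for paper-mode
analyses. If the filter is refit on every permuted labeling
(`refit_filter = TRUE`), the permutation null inherits the selection
optimism — null accuracies sit at 1.0 and the test has no power. Holding
the observed significant set fixed across permutations
(`refit_filter = FALSE`) tests the sharper question "does *this* edge set
separate *these* labels better than permuted ones?", which is the variant
used for the headline significance claim. With nested selection the refit
variant is fully valid and remains the default behavior.

### Second-session generalization

`second_session_test()` applies the model fitted on *first* sessions to
patients' second sessions. Under recovery, second-session accuracy (the
fraction still classified as patients) should *fall*: misclassification
toward the control side is here the clinically desirable outcome.

## 5. The synthetic cohort generator

`simulate_cohort()` provides seeded cohorts with known ground truth for
testing and power analysis. It emulates the statistical *shape* of a
rehabilitation study rather than fMRI physics:

* **Edges.** Each edge has a latent Gaussian mean drawn from
  $N(0.15, 0.25^2)$ (weakly positive on average, as resting-state
  correlations are); a session's edge value is the latent mean plus
  $N(0, 0.15^2)$ scan noise, passed through $\tanh$ to keep values in
  $(-1, 1)$ with correlation-like saturation.
* **Group effect.** A random fraction $f$ of edges (default 0.07)
  receives a signed offset of $\delta$ latent SDs (default $\delta = 1.5$)
  in patients — some edges hyper-, some hypo-connected, as observed
  empirically.
* **Recovery.** Session $s$ of a patient scales the planted offset by
  $(1 - \lambda_s)$, with drift schedule $\lambda = (0, 0.5)$ for the
  standard two sessions and a longer schedule for a subset of patients
  followed over extra sessions. $\lambda = 1$ is full normalization.
* **Clinical scores.** A motor score rises linearly with $\lambda$ plus
  noise, giving the trajectory comparison something to correlate with.

Defaults (22 controls, 18 patients, $k = 82$ regions, 5 long-format
patients) mirror a realistic single-center cohort size — small enough that
the selection-leakage phenomenon above is visible, large enough that the
paired session-1 versus session-2 tests have power.

What the generator does **not** model: spatial autocorrelation between
edges sharing a region, physiological/motion confounds, site effects, or
heavy-tailed edge noise. Conclusions about those require real data.

## 6. Numerical conventions

* Edge order is row-major lexicographic over the upper triangle, 1-based.
* The $t$ filter is patient-minus-control; pooled variance by default.
* Decision value exactly 0 predicts control ($-1$).
* An empty significant set is refused for model fitting (there is nothing
  to learn on); in permutation folds a majority-vote fallback keeps the
  null distribution defined.
* Trajectory normalization uses the sample SD ($n - 1$).
* Wilcoxon statistics are the smaller signed-rank sum; exact $p$-values
  for $n \le 25$ without ties, normal approximation otherwise. All-zero
  paired differences are an error, not a degenerate statistic.
* All stochastic steps (simulation, permutation, $k$-means restarts) are
  explicitly seeded; `run_pipeline()` is bit-reproducible given its
  config.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
cfg <- run_config(
  simulate = list(n_controls = 22, n_patients = 18, k = 82),
  n_perm = 1000, seed = 7, out_dir = "run1")
report <- run_pipeline(cfg)
report$loocv$accuracy
report$permutation$p
report$distance_summary
```

The report collects LOOCV metrics, the permutation $p$, the clustering
check, per-group distance summaries, paired intra-group statistics, and
normalized trajectories, and writes each artifact (model, predictions,
distance records, trajectories) as plain JSON/TSV files in `out_dir`.

## Limitations

The distance $d$ is defined relative to one fitted hyperplane, so
distances are comparable *within* a model, not across retrained models
or sites. With cohorts of this size the paper-mode accuracy is an
optimistic estimate by construction; the nested mode and the permutation
machinery are provided precisely so users can quantify that optimism on
their own data before reading the distances clinically.
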