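---
title: "Multiclass discriminative analysis of resting-state connectomes"
author: "idaconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiclass discriminative analysis of resting-state connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idaconn)
```

## The analysis in one paragraph

`idaconn` classifies subjects — for example major-depression patients,
schizophrenia patients, and healthy controls — from whole-brain resting-state
functional connectivity, and then asks *which connections carried the
decision*. Each subject contributes a vector of Pearson correlations between
the mean BOLD time series of every pair of regions in a 116-region
parcellation (6670 edges). Intrinsic discriminant analysis (IDA) reduces this
high-dimensional edge space to a few supervised components, one-against-rest
linear support vector machines classify subjects in the embedding under
leave-one-out cross-validation (LOOCV), and the SVM weight vectors are mapped
back to edge space to rank connections by discriminative power. Combining the
two patient-versus-rest classifiers separates *convergent* alterations
(shared by both disorders) from *divergent* ones (telling the disorders
apart).

## Connectivity features

For each subject the pipeline takes a regions × volumes matrix of mean
regional BOLD signals (or extracts one from a registered 4-D volume plus an
integer label image), then:

1. discards the first 5 volumes (magnetic saturation; applied when at least
   20 volumes are present, and configurable);
2. band-pass filters each regional series with a Chebyshev Type I filter,
   0.01–0.08 Hz, order 4, 0.5 dB passband ripple, applied forward–backward
   for zero phase. The family is standard for resting-state work; the order
   and ripple are deliberate defaults exposed as arguments, and the filter's
   analytic frequency response (`idaconn:::bandpass_response`) doubles as an
   independent oracle in the test suite. Rows are demeaned before filtering:
   DC lies outside any passband, and removing it up front avoids the long
   low-frequency edge transient of the recursive filter;
3. regresses each series on an intercept, the whole-brain mean course
   (optional — global-signal regression is scientifically contested, so it is
   a toggle), and six motion parameters, keeping OLS residuals;
4. correlates every region pair and stores the upper triangle along a fixed
   row-major edge enumeration (`edge_index_map()`), giving the
   p(p−1)/2-dimensional feature vector — 6670 edges for p = 116.

Filtering precedes nuisance regression by default; the order is a switch
(`filter_first`) because the two conventions coexist in practice.
Correlations are used raw, without a Fisher z-transform.

## Intrinsic discriminant analysis

Write each training sample (an edge vector) as the sum of three parts:

* a **common** component — the global mean over all training samples;
* a **class-common** component — the sample's class mean minus the global
  mean;
* an **individual** component — the sample minus its class mean.

`intrinsic_decompose()` returns this three-way split, which reconstructs the
sample exactly. Collect the class-common deviations (weighted by √n_i, so
their outer product is the usual between-class scatter S_cc) and the
individual deviations (outer product: within-class scatter S_ind). IDA seeks
directions w maximizing class-common variation relative to individual
variation, obtained from the generalized eigenproblem

    S_cc w = λ (S_ind + ε I) w.

With far fewer subjects than edges S_ind is singular, so a small
perturbation ε regularizes it. The top-d eigenvectors form the
transformation matrix W; in edge space its columns are the
*intrinsicconnectomes*, patterns over connections whose combinations can
represent any connectivity profile.

### Numerical choices

* **Span solver.** Every eigenvector with nonzero eigenvalue lies in the
  span of the centered training data, so the problem is projected onto an
  orthonormal basis of that span (rank ≤ N − 1) and solved there as a
  symmetric whitened eigenproblem. No P × P matrix is ever formed; fitting
  6670-edge data with 89 subjects takes well under a second. On problems
  small enough to form the dense scatters, the test suite checks the span
  solver against a dense generalized eigensolver.
* **ε default**: `1e-4 × mean(diag(S_ind))`, falling back to `1e-8` when the
  individual scatter vanishes. Tying ε to the scatter scale makes the
  conditioning scale-free; ε is exposed everywhere.
* **Signs and scale.** Eigenvector sign is fixed by making the
  largest-magnitude component positive, and columns are unit-normalized, so
  back-projection is reproducible.
* **Ties and zero eigenvalues.** With c classes, S_cc has rank at most
  c − 1; requesting d beyond that fills the remaining columns with a
  deterministic basis of the (eigenvalue ≈ 0) complement. A tie between
  genuinely nonzero eigenvalues at the cut keeps the first computed basis
  and warns; the identically-zero tail does not warn, since there the tie is
  structural.
* **Admissible dimensions.** d must satisfy 1 ≤ d ≤ N − 1 (the scatter
  rank bound); `max_embedding_dimension()` reports the ceiling — 88 for an
  89-subject dataset, one lower inside a leave-one-out fold.

## Classification protocol

One linear SVM per class is trained with that class positive and all others
negative (`train_ovr()`, regularization C = 1 by default — the embeddings
are low-dimensional, so the standard default is appropriate; hinge loss is
unweighted since fold-level imbalance is mild). Prediction takes the class
with the highest real-valued decision output, breaking exact ties toward the
lowest class index.

LOOCV refits *everything* — means, eigenvectors, SVMs — on each fold's N − 1
training subjects; the held-out subject influences nothing but its own
prediction. The test suite audits this by corrupting a held-out subject's
features and verifying the fold's fitted weights do not move.

`grid_search_dimension()` scans an integer grid of embedding dimensions,
selecting the best LOOCV accuracy (smallest d on ties). Each fold's
reduction is fitted once at the grid ceiling and truncated to each d, which
is exact because leading components do not depend on how many trailing ones
are kept. Selecting d by the same LOOCV that reports accuracy reproduces the
reference protocol faithfully but is optimistically biased; an unbiased
estimate would nest the selection inside an outer loop, which users can do
by calling `loocv()` on held-out splits of their own design. A PCA reducer
(`pca_reducer()`, leading principal axes of the mean-centered data) provides
the unsupervised baseline under the identical protocol.

## Discriminative connections

For each one-against-rest classifier the per-fold embedding-space weight
vectors are averaged (plain arithmetic mean, no per-fold normalization) and
back-projected to edge space as W·w̄, so decision values are identical
whether computed in embedding or edge space. Two back-projection variants
exist because the averaging order is genuinely ambiguous: the default
back-projects the averaged weights through the transformation refitted on
all N subjects; the alternative (`backprojection = "per_fold"`) back-projects
each fold's weights through that fold's own transformation and averages in
edge space. The planted-structure tests run both.

The **consensus set** of a classifier is the top 5% of edges by absolute
back-projected weight — `floor(0.05 × 6670) = 333` edges at full scale.
Magnitude, not sign, drives the ranking (a negative weight is equally
discriminative for a linear decision); the floor and the ascending-edge-id
tie-break are deliberate determinism choices. **Region weights** count each
region's incidence in the consensus set and always sum to twice the set
size.

**Convergent vs divergent.** An edge can enter both patient classifiers'
consensus sets for two reasons: both disorders shift the connection the same
way, or the connection separates the disorders so strongly that each
one-versus-rest classifier uses it with opposite sign. The convergent set
therefore defaults to the *sign-consistent* intersection of the two
consensus sets; without the sign requirement (available as a switch),
disorder-specific edges leak into the convergent set and are then wrongly
excluded from the divergent one. The divergent set takes the top fraction of
the difference profile |w_A − w_B|, excluding convergent edges and exact
zeros; a rank-discordance alternative (`divergent_rule = "rank_sum"`) is
provided since the narrative construction admits either reading.

## The synthetic cohort

No clinical scans ship with the package, so `sim_config()` /
`simulate_subjects()` generate a cohort with controlled group structure. The
defaults are the reference study conditions: three groups of 19 (mdd),
38 (hc), and 32 (scz) subjects, 116 regions, 180 volumes at TR = 2 s (a
6-minute session — `session_volumes(6, 2)`).

Each class has a target correlation matrix: a base matrix (uniform 0.1
off-diagonal by default — weak background coupling of the order seen in
parcellated data) plus class-specific additive perturbations on chosen
edges. If a perturbation breaks positive definiteness, eigenvalues are
clipped at 1e-6 and the matrix renormalized to unit diagonal — a simple,
deterministic repair whose (small) deviation from nominal targets the tests
account for. Subject time series are the Cholesky factor of the class matrix
applied to AR(1) Gaussian noise (coefficient 0.3, a typical BOLD
autocorrelation at TR = 2 s; unit marginal variance), plus a shared Gaussian
global time course (SD 0.5) added to every region — giving the
global-signal regression step a real target — and a 6-row motion table
(SD 0.1) used as nuisance regressors. A master seed expands into per-subject
substreams by stable hashing of the subject index, so cohorts are bit-stable
and reproducible under subsetting.

The **reference planted-effect design** used by the end-to-end checks places
30 perturbed edges at delta = 0.4: ten edges elevated in *both* patient
groups (the convergent structure), ten only in mdd, and ten only in scz.
This mirrors the shared-plus-specific alteration structure the analysis is
meant to detect, and it is the regime where supervision pays: an
unsupervised PCA front end spends its leading components on the dominant
shared patient-versus-control variance, while IDA uses the labels to keep
the disorder-separating directions as well.

What the generator does *not* emulate: voxel-level spatial structure,
hemodynamic response dynamics, scanner drift and artifacts, heterogeneous
within-group effect sizes, site effects, or realistic motion (motion columns
are white noise, present only so the regression step has the right shape).
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted covariance structure at realistic sample sizes —
not clinical performance. The reference clinical accuracies cannot be
reproduced without the original scans, and nothing in the package attempts
to.

## Problem sizes in the tests

Unit tests run on deliberately small problems (tens of features, tens of
subjects) with brute-force oracles: explicit scatter loops, dense
eigensolvers, 1-degree angular grids, normal-equation solves, per-voxel
averaging loops. The end-to-end checks run at the reference scale — 89
subjects × 6670 edges — with the dimension grid scanned over [2, 20]; the
permutation-null check uses a balanced 45-subject, 30-region cohort. These
sizes were chosen so the whole suite completes in a few minutes while the
full-scale path (span solver, LOOCV, grid search, back-projection) is
exercised end to end.

## Known limitations

* The grid-search accuracy is an optimistic estimate by construction
  (dimension selected on the same LOOCV); treat it as a protocol
  reproduction, not an unbiased generalization estimate.
* Components beyond c − 1 carry no first-order class-mean information; with
  three classes the informative embedding is essentially two-dimensional,
  and accuracy curves over d are correspondingly flat.
* Edge selection by top fraction is a ranking, not an inference; no
  per-edge significance statement is made, mirroring the reference
  protocol.
* The intrinsic decomposition is the mean-based three-component model;
  kernelized or online variants are out of scope.
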