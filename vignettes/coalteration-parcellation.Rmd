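---
title: "Co-alteration networks and profile parcellation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-alteration networks and profile parcellation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaltnet)
```

`coaltnet` estimates which brain regions tend to be *co-altered* across
coordinate-based voxel-based-morphometry experiments and parcellates a
region of interest (ROI) by the whole-brain co-alteration profile of its
nodes. This vignette documents the model, every tunable parameter, the
synthetic data the tests rely on, and the numerical and design decisions a
maintainer would want to know about.

## The observation model

The unit of observation is an *experiment*: a set of alteration peaks in
MNI millimetres plus a clinical sample size. Peak coordinates are noisy —
template registration differs between labs, and smaller samples localize
less reliably — so each focus is modeled as an isotropic 3D Gaussian,
$p(d) \propto e^{-d^2/2\sigma^2}$, with $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$
and a sample-size-dependent width

$$\mathrm{FWHM}(n) = \sqrt{\mathrm{FWHM}_{\mathrm{template}}^2 +
\mathrm{FWHM}_{\mathrm{subject}}^2 / n}.$$

`kernel_spec()` exposes the three kernel parameters:

* `fwhm_template_mm` (default **5.7 mm**) — the irreducible between-lab
  uncertainty; the n → ∞ limit of the kernel width.
* `fwhm_subject_mm` (default **11.6 mm**) — per-subject uncertainty, shrunk
  by √n. The defaults are the conventional ALE uncertainty constants; both
  are configurable because published pipelines vary.
* `truncation_sigmas` (default **3.5**) — the kernel's support radius in
  units of σ. Truncation is what makes the downstream "altered = non-zero
  MA value" test meaningful: beyond 3.5σ a node is deterministically
  unaltered. At 3.5σ the truncated and untruncated kernels differ by less
  than 10⁻³ at every voxel (asserted in the tests), while the support stays
  a few voxels wide on a 2 mm grid.

The printed Gaussian is a density; on a discrete grid we renormalize the
truncated kernel to unit sum, reading weight w(v) as the probability that
the "true" alteration lies in voxel v. This keeps every modeled-alteration
(MA) value in [0, 1] on any grid and makes the union formula
$\mathrm{ALE}(v) = 1 - \prod_e (1 - \mathrm{MA}_e(v))$ probabilistically
coherent. Within one experiment, overlapping foci combine by voxel-wise
*maximum*, not sum, so a cluster of nearby peaks reported by a single study
cannot inflate its own map.

Foci are snapped to their containing voxel before kernel placement; a voxel
"contains" the millimetre points that round to its index. World coordinates
are RAS millimetres; user-facing voxel indices are **1-based** (the R
convention), while stored affines keep the NIfTI 0-based convention — the
conversion lives entirely inside `mm_to_voxel()` / `voxel_to_mm()`.

## Nodes, alteration states and Patel's κ

Network nodes are local maxima of the ALE map (`detect_peaks()`):
26-connected, at least `min_value` (default 10⁻³, just above the truncation
floor), optionally masked, merged below `min_distance_mm` (default 10 mm)
keeping the higher peak. Determinism is the binding requirement, so every
ambiguity has a fixed rule: flat plateaus collapse to their
lexicographically smallest voxel, value ties merge toward the smaller
voxel index, and ids are assigned in descending ALE order. The node count
is sensitive to both parameters; neither is a reproduction target.

Node A is *altered* in experiment e iff e's MA map is non-zero at A's
voxel, i.e. A lies within the truncated support of one of e's foci. The
joint frequencies over N experiments,
$\theta_1 = P(a{=}1,b{=}1), \theta_2 = P(a{=}1,b{=}0),
\theta_3 = P(a{=}0,b{=}1), \theta_4 = P(a{=}0,b{=}0)$, are plug-in counts/N
(a conjugate add-α option exists for degenerate vectors, default off —
presented probabilities are raw frequencies). Patel's κ compares θ₁ with
its independence expectation E = (θ₁+θ₂)(θ₁+θ₃), normalized by how far θ₁
can move given the margins:

$$\kappa = \frac{\theta_1 - E}{D\,(\max(\theta_1) - E) +
(1-D)\,(E - \min(\theta_1))}$$

with $\max(\theta_1) = \min(\theta_1+\theta_2, \theta_1+\theta_3)$ and
$\min(\theta_1) = \max(0, 2\theta_1+\theta_2+\theta_3-1)$. The weight D
interpolates linearly from 0 at $\theta_1 = \min(\theta_1)$ through ½ at
independence to 1 at $\theta_1 = \max(\theta_1)$:
$D = \tfrac12 + (\theta_1-E)/(2(\max(\theta_1)-E))$ above independence and
$D = \tfrac12 + (\theta_1-E)/(2(E-\min(\theta_1)))$ below. This is the
construction that pins κ to −1 and +1 exactly at the attainable bounds of
θ₁; writing the lower branch with the opposite sign (a form that appears in
parts of the literature) sends D to 1 as θ₁ falls, and the index then
escapes [−1, 1] by an order of magnitude on ordinary inputs — the package's
tests check the bound on 10⁵ random θ quadruples against an independently
transcribed oracle. Floating-point noise on near-degenerate quadruples is
clamped to [−1, 1].

Degenerate nodes (altered in none or all experiments) have undefined κ;
they are excluded from pairing and listed in the network diagnostics rather
than silently zeroed. Edges are kept when κ > 0 — strictly, so exact
independence never creates an edge. An optional one-sided permutation test
(`kappa_permutation_null()`) permutes one node's state vector and reports
$p = (1 + \#\{\kappa^* \ge \kappa\})/(1 + n_{\mathrm{perm}})$. Because the
margins are fixed under permutation, κ* is a monotone function of the
discrete joint count, and the ≥ tie rule makes the p-value valid but
conservative when N is small; at the package's standard study size (150
experiments) the discreteness is fine enough that empirical rejection at
α = 0.05 sits inside the 95% binomial interval (checked in the acceptance
tests at N = 150, 200 pairs, 999 permutations).

## Parcellation, MDS and decomposition

Nodes whose voxel falls inside the ROI mask (a voxel-membership test, not a
distance test) are *root nodes*. The first-neighbor subnetwork keeps
exactly the edges with ≥ 1 root endpoint; the profile matrix has one row
per root, one column per subnetwork node, κ where an edge exists and 0
elsewhere. Structural zeros are kept as zeros — the matrix is clustered
exactly as built.

Row distance is **1 − r** (Pearson). Not (1 − r)/2 and not 1 − |r|:
anticorrelated profiles are maximally dissimilar. A constant row
(a root with no edges) has undefined correlations; they are set to 0
(distance 1) with a warning. Linkage is WPGMA by default — after merging u
and v, d(uv, w) = (d(u,w) + d(v,w))/2 — with UPGMA and complete as
alternatives; all three are reducible, so merge heights are monotone. Ties
break to the lexicographically smallest pair of cluster indices (creation
order), which makes the merge tree a pure function of the input. The
implementation is hand-written for exactly that reason; `stats::hclust`
(method `mcquitty`) is used as an independent cross-check on tie-free
matrices in the tests, together with a second oracle that recomputes every
inter-cluster distance from the original matrix. Cutting at cardinality c
undoes the last c − 1 merges and labels clusters by their smallest leaf id.
`drop_root_edges()` zeroes the root columns to repeat the clustering
without local (within-ROI) co-alteration; `local_subnetwork()` isolates
root–root edges above a κ threshold (default 0.5, a display convention for
the strongest local coupling).

The voxel-wise parcel map assigns each ROI voxel the label of its
Euclidean-nearest root, computed in millimetres so anisotropic grids are
safe; exact ties go to the smallest root id.

`torgerson_pcoa()` double-centres the squared distances
(B = −½ J D⁽²⁾ J) and takes the top-k eigenpairs; since 1 − r distances
need not be Euclidean, axes with non-positive eigenvalues are zero-filled
with a warning reporting the negative-mass fraction (truncation, not
imaginary scaling — the standard principal-coordinates practice). The
optional SMACOF refinement (`stress_refine()`) is off the default path so
every reported embedding is closed-form reproducible.

`decompose_cluster()` takes the edges joining a chosen cluster's roots to
nodes outside the cluster, thresholds them at percentiles of that edge
set's κ distribution (linear interpolation between order statistics — R's
default quantile type 7), and counts surviving distinct neighbors by their
atlas label. Nodes outside all seven networks are counted in the
denominator and reported as "unassigned", so percentages always sum to 100;
a stricter denominator is a one-line post-filter on the returned table.

## The synthetic generator

Real inputs come from proprietary coordinate databases, so
`make_ground_truth()` / `sample_experiments()` emulate the essential
structure of such a pool:

* region centres inside a box-shaped ROI, grouped into spatial parcels,
  plus extra-ROI "partner" centres, each parcel + partners forming one
  *coupling group*;
* per experiment, each group activates with `p_group_active` (default
  0.35) and each region independently with `p_background` (default 0.05);
  active regions emit one focus jittered by an isotropic Gaussian
  (`jitter_sigma_mm`, default 3 mm);
* sample sizes uniform on 10–30 subjects; experiments without an ROI focus
  are rejected and resampled, mirroring an ROI-conditioned database query
  rather than post-hoc filtering (the rejection itself induces the mild
  negative between-group dependence such a query creates);
* in well-separated mode, centres are ≥ 2 × truncation radius apart, so
  each planted region maps to exactly one ALE peak.

Default problem sizes — 3 parcels × 4 ROI regions + 2 partners each, 150
experiments on the 2 mm MNI grid — are the package's standard study
conditions: large enough that planted couplings dominate sampling noise,
small enough that the full pipeline runs in seconds. What the generator
does *not* emulate: disease-specific topographies, correlated jitter,
multiple foci per region per study (a multiplicity option exists to
exercise the within-experiment maximum rule), heterogeneous study quality,
or publication bias. Passing tests therefore demonstrate that the
*machinery* recovers planted structure under honest noise, not that any
particular empirical parcellation is correct.

`make_map_fixtures()` stands in for seed-based functional connectivity
maps: per parcel a smooth random template (sums of random Gaussian blobs,
standardized, optionally orthogonalized so noiseless between-parcel
correlation is exactly 0), per root that template plus iid voxel noise.

## Numerical choices and degenerate inputs

* Kernel support radii are floored to whole voxels; a σ so small that the
  support is one voxel yields the degenerate kernel {centre: 1}.
* `ale_map()` streams the union product so per-experiment volumes are
  never all resident; `alteration_states()` evaluates MA values directly
  at node voxels (exactly equal to the full-map route, asserted in tests).
* All-zero ALE maps return an empty node table, not an error; an
  all-outside-ROI node set errors, because no root nodes means no
  parcellation target.
* `run_pipeline()` writes every tabular artifact as CSV plus NIfTI volumes
  and Newick dendrograms; per-experiment MA volumes are written only under
  `write_ma_maps = TRUE` since they dominate disk at realistic study sizes
  while the ALE map carries the downstream information. Identical config
  and seed give byte-identical tabular outputs; the manifest records the
  seed, parameters and a config fingerprint.
* All randomness flows from explicit integer seeds; derived sub-seeds are
  small offsets of the master seed and stay within 32-bit range.

## Known limitations

* Edges are undirected: the method cannot say whether alteration
  originates in the ROI and propagates outward or vice versa.
* κ is estimated by plug-in frequencies; at small N the estimates are
  coarse and the permutation p-values conservative (see above).
* Peak-detection parameters materially affect the node count; downstream
  conclusions should be checked across reasonable settings.
* The nearest-root voxel assignment yields Voronoi-like parcels; it cannot
  produce disconnected or interdigitated parcels even if the underlying
  profiles would support them.
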