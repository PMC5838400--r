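---
title: "Measuring subject-level deviation from cohort-common resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subject-level deviation from cohort-common resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Group spatial ICA treats a cohort of resting fMRI scans as sharing a set of
C spatial sources: after masking, each subject's T x K data matrix is
reduced by PCA along time, the reductions are concatenated across subjects,
and a second PCA plus ICA unmixing yields the cohort-common component maps
S_agg (C x K), each a resting-state network (RSN). Dual regression then
recovers subject-specific time courses A_i (least-squares fit of the
subject's data onto the group maps) and subject maps S_i (fit of the data
onto A_i). Because group-level components are the spatial patterns conserved
across the cohort, the distance between a subject's map and the group map is
a per-subject, per-network scalar — a summary feature with the same
subject-by-variable shape as genotype data, which is what makes it usable in
imaging-genetics association.

Three deviation metrics are implemented for a subject map x against the
reference r over the K masked voxels:

* Euclidean distance `sqrt(sum((x - r)^2))` — larger is more deviant;
* Pearson correlation — smaller is more deviant;
* Kullback-Leibler divergence between intensity histograms of x and r,
  binned on shared equal-width edges spanning the pooled range, with a
  pseudocount added to every bin (natural-log units).

The same metrics apply to functional network connectivity (FNC): each
subject's component time courses are detrended, motion-corrected (when
realignment parameters are available), despiked, band-pass filtered at
0.01–0.08 Hz, and correlated pairwise; the Fisher r-to-z transformed matrix
is vectorized to its D = J(J-1)/2 distinct connections and compared with the
cohort mean matrix. Weighted global efficiency — the inverse harmonic mean
of shortest-path lengths on the graph with weights |r| and lengths 1/|r| —
summarises how integrated each subject's connectivity graph is.

On maps standardized to zero mean and unit population variance over the
mask (the package default), the Euclidean and Pearson features obey the
exact identity `rho_ED = sqrt(2K(1 - rho_PC))`, so the two features are
deterministically anti-correlated; the package keeps both because their
group-level statistics are not identical once covariates enter.

## Parameters that matter

* `n_components` (default 75): the ICA model order. Desk-scale simulated
  studies in this package use 8, matched to the generator's 8 planted
  networks.
* `kl_bins` (default 100) and `pseudocount` (default 1): the KL histogram
  resolution and smoothing. The pseudocount is required because the
  divergence is undefined when a reference bin is empty; edges are shared
  between the two inputs so that the divergence compares shapes, not
  supports. Both are configurable because neither choice has a canonical
  value.
* `bandpass` (default 0.01–0.08 Hz): the resting-state frequency band; it
  must lie strictly below the Nyquist frequency 1/(2 TR).
* Despiking (11-point moving median, 3 robust SD = 3 x 1.4826 MAD): all
  three constants are configurable; they implement "replace samples that
  deviate implausibly from their local level".
* `algorithm`: Infomax (natural-gradient, logistic score) is the default
  unmixing, matching common practice for spatial fMRI sources, with
  symmetric FastICA (tanh contrast) as the alternative. Both are seeded and
  deterministic.

## Numerical choices

* **ICA convergence.** The unmixing iterates until the relative natural
  gradient norm |G|/|W| falls below 1e-6, with an adaptive learning rate
  (gentle growth while the gradient norm falls, a hard cut on a rise,
  capped at 0.3). The separating directions settle within tens of
  iterations but the source scale adapts slowly, so the iteration cap is
  2000; non-convergence is a hard error, never a silent pass-through.
* **Sign convention.** Each group map is flipped to positive skewness, so
  activation blobs are positive regardless of the arbitrary ICA sign.
* **Map standardization.** ICA scale is arbitrary and the Euclidean metric
  is scale-sensitive, so subject and group maps are standardized (zero
  mean, unit population variance over the mask) before any metric;
  `standardize = FALSE` disables this.
* **Dual regression conditioning.** Both regression steps verify the
  reciprocal condition number of their normal matrices (threshold 1e-12)
  and fail loudly on rank deficiency.
* **Efficiency conventions.** Connection length is 1/weight; absent
  connections (r = 0) have infinite length; unreachable pairs contribute
  zero efficiency. Shortest paths are computed by Dijkstra's algorithm via
  igraph; tests verify agreement with an exhaustive path-enumeration oracle
  to 1e-10.
* **Degenerate inputs.** Constant volumes (empty masks), empty mask
  intersections, constant time courses, |r| = 1 connections under Fisher z,
  monomorphic SNPs and collinear designs are all explicit errors or
  warnings naming the offending subject, component or SNP.

## What the synthetic cohorts emulate

The generator (`simulate_cohort()`) produces everything the pipeline
consumes — 4D NIfTI volumes, motion tables, covariates, genotypes, SNP
weights, a manifest — from a single seed, with the ground truth retained so
that every downstream stage has a recoverable target:

* **Networks**: C_true smooth Gaussian blobs (main bump plus half-amplitude
  satellite) inside a spherical "brain" support, with centers placed by
  farthest-point sampling and the final maps symmetrically orthogonalized.
  Spatial ICA assumes near-independent sources and real RSNs are largely
  non-overlapping parcellations, so the generator plants sources that
  satisfy the model it is meant to validate.
* **Subject spatial deviation**: subject map j is
  `standardize(G_j + delta_i * E_ij)` with E a smoothed unit-variance field
  orthogonalized against the group-map span — the deviation moves each
  network into novel territory rather than into the other networks, which
  keeps the spatial (`delta`) and temporal (`gamma`) ground truths
  separable downstream. `delta_i` is log-normal around 0.4 (heterogeneity
  SD 0.3), multiplied by 1.5 for patients, plus a small additive effect
  (0.05 per allele) of one causal SNP.
* **Connectivity deviation**: time courses are drawn with correlation
  `(1 - gamma_i) * Sigma + gamma_i * R_i`, where Sigma is a modular
  two-block pattern (within 0.65, between 0.2, emulating functional
  domains) and R_i is the subject's aberrant state. `gamma_i` is log-normal
  around 0.35 (SD 0.8, capped at 0.9), 1.5x in patients.
* **Measurement**: volumes are `A_i S_i` plus a baseline offset of 100
  inside the brain support (so the mean-activation masking rule does real
  work) and white noise at a signal-to-noise variance ratio of 10.
* **Genetics**: Binomial(2, MAF) dosages with MAF uniform on 0.05–0.5, and
  odds-ratio weights (log-normal around 1; 1.2 for the causal SNP) for PRS
  scoring.

### Two geometries of connectivity deviation

A single random deviation structure cannot exhibit both properties the
framework is validated against, so the generator offers two:

* `"diffuse"` (default): R_i perturbs every connection with symmetric
  Fisher-z noise (SD 0.75). The deviation has no cohort-common direction,
  so the cohort-mean FNC sits at the true pattern and the distance to it is
  monotone in `gamma_i` — the regime for validating that the FNC
  variability feature recovers the planted deviation magnitude. Had the
  deviation a common direction, the mean reference itself would shift with
  the average deviation and the distance would become V-shaped in
  `gamma_i`.
* `"dysconnectivity"`: R_i knocks a random ~30% of connections down to
  50–100% of their strength — deviation as loss of (mostly within-module)
  connection strength. In this clinical regime, more deviation entails a
  weaker graph and hence lower global efficiency, which is the direction
  the framework is expected to reproduce; the price is that the common
  weakening direction makes `gamma` recovery from the mean reference less
  precise.

Positive definiteness of every correlation target is enforced by
eigenvalue-clipping projection rescaled to unit diagonal.

### Study sizes and scan lengths

Validation studies use the desk-scale cohort of 30 controls and 30 patients
on a 15^3 grid (about 1300 masked voxels) with 8 networks. A 0.01–0.08 Hz
band-limited process observed for T volumes at TR 2 s carries roughly
`2 * 0.07 * T * 2` effective samples per connection — about 34 at T = 120 —
so each Fisher-z connection is estimated with an SD near 0.17. The spatial
studies (map recovery, `delta` recovery, diagnosis differences) are
comfortably powered at T = 120 and use it. The connectivity-side studies
measure second-order quantities and use longer scans, chosen a priori from
the effective-sample argument: `gamma` recovery uses T = 300 (about 84
effective samples) and the deviation-versus-efficiency study uses T = 600
in the dysconnectivity regime. This is an information limit of short scans,
not an implementation property: it persists when the pipeline is bypassed
and the true (unestimated) time courses are used.

### What passing these studies does not show

The generator's networks are compact, orthogonalized blobs; its noise is
white; its time courses are Gaussian; sites carry no real effect; genotypes
are in linkage equilibrium. Real resting fMRI violates all of these —
spatially structured physiological noise, scanner effects confounded with
site, hemodynamic autocorrelation, LD structure. Passing recovery studies
on these cohorts demonstrates that the implementation measures what it
claims to measure under its own model assumptions, not that the features
are clinically valid biomarkers.

## Design choices made where the design was open

* **"Activation" for masking** is the voxel's temporal mean, the only
  time-collapsed scalar available before decomposition; the subject rule
  keeps voxels strictly above the grand mean, and the group mask is the
  intersection. Each subject is masked on its own intensity scale (the rule
  is invariant to positive affine rescaling), so no cross-scanner
  normalization is assumed.
* **Back-reconstruction** is dual (spatial-temporal) regression: fully
  specified, deterministic, and sign-consistent with the group maps.
* **"Normalized FNC (z-score)"** is read as the Fisher r-to-z transform per
  connection, the standard FNC z-score convention.
* **KL details**: natural log; shared equal-width edges over the pooled
  range; pseudocount 1. All are conventions rather than consequences of the
  definition, and all are configurable.
* **FNC vectorization** uses the strict upper triangle (D = J(J-1)/2
  distinct connections; 1225 for J = 50); the unit diagonal carries no
  information.
* **Efficiency** is computed on raw |correlation| weights (before Fisher
  z), with the 1/w length mapping of the weighted-graph convention.
* **Per-SNP regressions** include the same age/sex/site covariates as the
  diagnosis model, for consistency across analyses; `covariates = NULL`
  gives the unadjusted scan. Site is dummy-coded with the lexicographically
  first site as reference.
* **PRS weights** are natural-log odds ratios (additive scoring on 0–2
  dosages, fractional dosages allowed); no p-value thresholding is applied
  beyond the user-supplied SNP set.
* **Percent variance explained** is the squared partial correlation,
  `100 t^2 / (t^2 + residual df)`.
* **Balanced reference**: when group sizes differ, `mean_fnc()` can
  subsample the larger group (seeded) so both groups contribute equally to
  the reference pattern.

## Known limitations

* The mean FNC is a pragmatic, not an ideal, reference for "typical"
  connectivity; when deviations share a direction the mean itself is
  displaced (see the two deviation geometries above).
* KL divergence compares intensity histograms and therefore discards all
  spatial arrangement; it is the least sensitive of the three metrics.
* Model-order selection, ICASSO-style stability analysis and artifact
  component labelling are out of scope; the kept-component set for FNC is
  user input.
* Scans shorter than ~100 volumes leave very few effective samples in the
  0.01–0.08 Hz band; FNC-side quantities estimated from them are noisy, and
  the efficiency relationship in particular should not be interpreted at
  such lengths.
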