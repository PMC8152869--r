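---
title: "Individualized thalamic parcellation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized thalamic parcellation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. No empirical claim is made here that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The segmentation model

Each thalamic voxel carries a fiber orientation distribution (FOD)
represented in a real, even-order spherical-harmonic (SH) basis. At
`lmax = 6` this is 28 coefficients per voxel; antipodal symmetry of fiber
orientations makes odd orders unnecessary. The basis convention is
MRtrix-style ordering (l ascending, m from −l to l; m < 0 mapped to the
sine harmonics, m > 0 to the cosine harmonics, each scaled by √2), so
coefficient volumes interchange predictably with FOD files produced by
constrained spherical deconvolution tools.

Voxels are clustered by k-means under the hybrid metric

$$D = \alpha X + (1-\alpha)\,\beta\, Y,$$

with $X$ the Euclidean distance between SH coefficient vectors and $Y$ the
Euclidean distance between voxel coordinates. Defaults are the study
configuration: $k = 7$ nuclei per hemisphere, $\alpha = 0.5$, $\beta = 85$.
Distances are *unsquared* in both terms, exactly as the metric is written;
the centroid update is nevertheless the arithmetic mean — the standard
k-means heuristic, which is not the exact minimizer of summed unsquared
distances. Two consequences follow and are handled explicitly:

* **Monotonicity.** Because the mean update is a heuristic for this
  objective, a rare update step could increase the summed assigned
  distance. The implementation checks the objective every iteration and
  stops at the previous (better) partition if an update would increase it,
  so the recorded objective trace is non-increasing by construction.
* **Local optima.** The initialization is deterministic — hierarchical
  (Ward) agglomeration of the spatial coordinates only, cut at $k$ — which
  can seed two centroids inside one true nucleus and none inside another.
  Lloyd iterations cannot escape that basin: once two centroids share a
  nucleus their FOD coordinates coincide and only the (stable) spatial
  split distinguishes them. `kmeans_segment()` therefore applies a
  deterministic merge–split refinement after convergence: trial moves merge
  the two closest centroids under the hybrid metric and split the cluster
  with the largest within-cluster cost at its spatial median, and a move is
  kept only if the re-converged objective is lower. On small instances the
  refined objective matches multi-restart search (this is asserted in the
  test suite).

Other conventions: voxel coordinates are 0-based indices of the template
grid (world coordinates appear only at NIfTI I/O); empty clusters are
re-seeded with the voxel farthest from its assigned centroid; assignment
ties break to the lowest centroid index, making the whole fit
deterministic. Ward linkage was chosen for the spatial initialization
because it yields compact, contiguous seed regions; no particular linkage
is canonical for this step.

`kmeans_segment()` returns a classed S3 object in the classic R modelling
idiom, with `print`, `summary`, `fitted`, `coef`, `predict` and `plot`
methods.

## 2. Fixels and their metrics

The FOD is realized as a spherical function by sampling on a
subdivided-icosahedron tessellation (three subdivisions, 1280 face-centroid
directions, spherical-triangle-area quadrature weights that sum to $4\pi$
exactly). Working on the full sphere keeps the quadrature exact for the
constant harmonic; antipodal lobe pairs are merged into one fixel, so a
single-fiber FOD yields one fixel whose FD integrates both half-lobes.

Fixel extraction: negative amplitudes (ringing) are clipped to zero; peaks
are local maxima on the mesh above 0.1 of the per-voxel maximum (the only
amplitude threshold the study prints, and configurable); peaks closer than
15° under the antipodal metric are merged — the mesh spacing at 1280
directions is ≈ 6°, and a band-limited lobe apex falling between samples
otherwise splits into two discrete maxima ≈ 10° apart. Every positive
sample joins its nearest peak, and FD is the quadrature integral of the
amplitude over the lobe. An FOD with no distinct peak yields a single
"peakless" fixel along +z carrying the full integral rather than silently
dropping density. Band-limited sharp lobes (Watson concentration ≈ 20 at
lmax = 6) can carry a ringing sidelobe a few percent of the main peak that
survives the 0.1 threshold as a small third fixel; this is a property of
the band limit, not of the extraction.

FC is the cross-sectional area change of the plane perpendicular to the
fixel direction under the local warp Jacobian, $FC = |\det J| / \lVert J
d\rVert$, and FDC = FD · FC. Regional means weight every fixel equally (the
simplest convention consistent with "averaged within each subfield");
cross-subject fixel matching, when needed, takes the nearest template fixel
within 45°.

## 3. Deformation fields and shape statistics

Deformation fields are displacement volumes on the template grid for the
warp that pushes template space into subject space, so that
$\log \det J > 0$ marks expansion of the subject relative to the template —
the sign convention under which "expansion of the dorsal posterior nucleus"
reads naturally. Jacobians use central finite differences in the interior
and one-sided differences at borders, scaled by voxel size; a non-positive
determinant inside the analysis mask raises a folding error. Per-nucleus
shape statistics are the arithmetic means of the log-Jacobian over each
nucleus. The covariate-adjusted one-sample test mean-centers the covariates
so the intercept estimates the covariate-adjusted mean; with no covariates
it reduces exactly to the classical one-sample t-test. FDR correction uses
Benjamini–Hochberg at q = 0.05 across nuclei.

The pipeline also reports a warp-integrated nucleus volume ratio (the mean
of $e^{\log\det J}$ over the nucleus). The count-based volume ratio of two
parcellations is available too (`volume_ratio_change()`), but at
desk-scale grids a planted ~20 % continuum volume change moves nucleus
boundaries by only ~0.2 voxel — every voxel center sits at least half a
voxel from a block boundary, so nearest-neighbor label counts quantize the
change away. The warp-integrated ratio is the standard tensor-based
morphometry resolution of exactly this problem and is what the CRS-R
volume correlation uses.

## 4. Statistics

* **NMI** is computed in the over-entropies form on the voxel contingency
  table with $0 \log 0 = 0$; it is base-invariant and equals the familiar
  $2\,MI/(H_A + H_B)$. The degenerate both-single-cluster case is defined
  as 1 with a `degenerate` attribute.
* **Consensus partitions** accumulate the co-association matrix (fraction
  of subjects placing a voxel pair in the same nucleus) and cut
  average-linkage agglomeration of $1 - $ co-association at $k$ — any
  method invariant to per-subject label permutation would do; this is the
  standard evidence-accumulation realization.
* **The NMI group test** reallocates subjects to two groups of the original
  sizes and recomputes consensus NMI (1000 draws by default); significance
  is declared outside the empirical 2.5–97.5 percentile interval, and a
  two-sided add-one p-value around the null mean is reported as well. The
  percentile rule is conservative under ties (the null is discrete when
  subject partitions are near-identical), so calibration is asserted on the
  p-value rule. A structural caveat worth knowing: for a *binary* group
  difference, any reallocation that re-concentrates the minority subject
  type reproduces the observed consensus pair, so the null distribution
  contains the observed NMI with non-trivial probability at n ≈ 10+10, and
  strict percentile detection of such differences is inherently limited.
  The package's power test therefore asserts the directional property
  (observed at or below the null median).
* **Two-group metric tests** residualize each column on the covariates over
  the pooled sample and permute group labels of the residuals
  (a Freedman–Lane-style simplification), statistic = difference of group
  means, two-sided add-one p-values, BH-FDR within each metric family (one
  family per metric per region type, matching how such results are
  presented per figure). For the DOC-versus-HC tests the DOC-duration
  covariate, which is undefined for controls, is imputed at the patient
  mean: coding it 0 for controls makes it a near-perfect group indicator,
  and pooled residualization would then absorb ≈ 80 % of any true group
  effect. Within-patient analyses use the raw durations.
* **Partial correlation** is the Pearson correlation of residuals after
  regression on the covariates, with $t$-based p-values on
  $n - n_{cov} - 2$ degrees of freedom.

## 5. Classification

Features are the 7 metrics (FD, FC, FDC, FA, MD, AD, RD) of every nucleus
region under the chosen parcellation; volume is excluded because
population-level parcellations give all subjects identical nucleus volumes.
Per cross-validation fold, features are z-scored on the training rows only;
the L1 penalty of the logistic model is selected by inner leave-one-out
deviance on the training rows (with ~7 training subjects an inner k-fold is
dominated by fold luck); folds are stratified so both classes appear in
every training set. Accuracy is recorded per fold across 20 repeats of
3-fold cross-validation. The no-leakage property — held-out rows never
influence standardization or fitting — is asserted directly in the tests.
PCA for visualization standardizes columns, so its spectrum is invariant to
column permutation and sign flips (the orthogonal maps that commute with
per-column standardization), not to general rotations.

## 6. What the synthetic cohort emulates

`make_cohort()` generates the study design: 10 healthy controls, 5 MCS and
5 VS patients on a common template grid (default 20×24×16 voxels, thalamus
block 12×14×10 = 1680 voxels, seven contiguous box-shaped nuclei — the
octants of the block with two face-adjacent octants merged). Each nucleus
has a dominant fiber orientation (pairwise ≥ 35° apart) rendered as a
Watson-like SH lobe (concentration 20), a per-nucleus baseline fiber
density (relative amplitudes 0.7–1.3: real nuclei differ in baseline
density, and this is precisely what makes mis-aggregation under a
population atlas costly), and i.i.d. coefficient noise.

A latent severity score drives the planted pathology: 0 for controls,
moderate for MCS (0.1–0.5), high for VS (0.6–1.0). Severity scales

* expansion of the dorsal-posterior stand-in (nucleus 6) and shrinkage of
  the anterior stand-in (nucleus 1), up to ±20 % at full severity, realized
  by a separable axis-aligned scaling warp whose analytic log-Jacobian is
  calibrated so the nucleus mean equals $\log \lambda$ exactly, with
  compensating compression in the complementary slabs of the block and a
  smoothstep taper to the identity outside it (so pathway tubes see almost
  no planted warp). A compactly supported radial bump cannot do this job:
  it conserves volume inside its own support, so it cannot put net
  expansion into a nucleus while remaining identity outside the thalamus.
  The volume redistribution means non-designated nuclei legitimately show
  small opposite-signed shape effects;
* FD reduction (30 % at full severity) in designated nuclei (2 and 6) and
  along all thalamo-cortical pathway tubes;
* increased radial diffusivity along pathways (MD/RD up, FA down);
* CRS-R totals decreasing with severity (≈ 16 − 12 s, clipped to 0–23,
  giving the observed 4–15 patient range, controls at ceiling), so CRS-R
  correlates negatively with the planted volume change and positively with
  FD.

Independent of group, every subject receives anatomical variability —
nucleus block midplanes shifted by ±1 voxel — and deformation noise: six
random compact warp bumps (amplitude s.d. 0.08) plus severity-independent
volume noise (s.d. 0.04) on the expansion factors. These three noise
sources are what make the study's comparative claims reproducible rather
than trivial: without anatomical variability an atlas is as good as an
individual parcellation; without volume noise the warp-derived FC reads
severity almost perfectly (r ≈ 0.98) under *any* labeling and
population-level features classify as well as individual ones.

Covariates: age and intracranial volume are drawn once and snake-assigned
between controls and patients so the groups are covariate-balanced,
emulating the matched design ("no significant difference in age"); in an
unbalanced draw, chance covariate–group correlation absorbs part of the
group effect during residualization at n = 20. DOC duration is 0 for
controls in the metadata (see §4 for how the statistics handle it).

Thalamo-cortical pathways are 35 disjoint 6-connected tubes (7 nuclei × 5
cortical targets, the targets standing for prefrontal, motor,
somatosensory, parietal-occipital and temporal cortices as grid faces),
routed by breadth-first search from a surface voxel of each nucleus through
the warp-free shell; the first voxel of each tube lies inside its nucleus.

**Generator parameters worth knowing.** The FOD amplitude scale (default
500 for a unit-baseline nucleus) is set high enough that the planted
partition is the *optimum* of the hybrid-metric objective for every ±1
midplane-shift geometry — at lower amplitudes the objective genuinely
prefers merging a small jittered nucleus and splitting the merged double
octant, and no optimizer can recover a partition the objective disfavors.
The coefficient noise (s.d. 0.26 of the mean c00) puts the within:between
nucleus coefficient-distance ratio at ≈ 1:3, the regime in which
segmentation recovery is exercised. Both were fixed from the generator's
own geometry before the acceptance checks were written.

**What passing tests do and do not show.** The phantoms establish that the
implementation recovers what was planted under controlled conditions:
box-shaped nuclei, band-limited single-fiber FODs, analytic warps, Gaussian
coefficient noise. Real thalami have curved boundaries, crossing fibers,
registration error, and pathology that is not a single latent severity
scale; passing these tests says the machinery is correct, not that the
study's clinical effect sizes would replicate. One known divergence is
deliberate: planting a volume change mechanically elevates FC in the
deformed nuclei and, through the tube mouths inside the block, slightly
along pathways, so the real study's "FC not significantly different"
pattern is only partially reproduced; the asserted pattern is FD/FDC
reduction in designated regions with increased diffusivities along
pathways.

## 7. Problem sizes and runtime choices

The full tessellation (1280 directions) is the default for fixel metrics;
pipeline-level tests run the basis at one subdivision less (320 directions),
which changes lobe integrals by well under the effect sizes studied. The
end-to-end recovery checks run 20 seeded cohorts at the default grid with
999 metric permutations and the full 20×3-fold cross-validation; module
calibration tests use 200 replicates at 99–199 permutations. The package
defaults remain the study values (2000 and 1000 permutations).

## 8. Known limitations

* The block-partition phantom supports k ≤ 8 contiguous nuclei; the
  two-lobe-per-voxel case (crossing fibers inside the thalamus) is not
  generated, though the fixel extractor handles it.
* The hybrid-metric k-means treats β as a global constant; no per-dataset
  calibration of β or k is attempted (the study fixes both).
* Consensus clustering is one standard realization (co-association +
  average linkage); any permutation-invariant alternative satisfying the
  same invariants could be substituted.
* Hungarian label matching is exhaustive for k ≤ 8 and greedy above, with a
  warning.
* The CLI is a thin wrapper; orchestration beyond one cohort directory
  (parallelism, clusters) is out of scope.
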