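# thalparc

Individual-level parcellation of the thalamus from fiber orientation
distributions (FODs), with the downstream analyses that turn per-subject
parcellations into group-level neuroscience: consensus partitions,
partition-similarity testing, nucleus shape statistics, fixel- and
tensor-based microstructural statistics, and clinical-group classification.
Because high-field diffusion MRI cohorts of disorders-of-consciousness (DOC)
patients are not publicly shareable, the package ships a seeded
synthetic-cohort generator that plants the group effects this kind of study
looks for, so the entire pipeline is testable end to end without any
download.

## The science

**Segmentation.** Within a thalamus mask, each voxel carries a FOD expressed
in a real, even-order spherical-harmonic basis (lmax = 6, i.e. 28
coefficients). Voxels are clustered by k-means (k = 7 nuclei per hemisphere)
under the hybrid metric

    D = alpha * X + (1 - alpha) * beta * Y

where `X` is the Euclidean distance between FOD coefficient vectors, `Y` the
Euclidean distance between voxel coordinates, `alpha = 0.5` weights the two
features equally, and `beta = 85` brings the spatial term onto the scale of
the FOD term. Centroids are initialized deterministically from hierarchical
(Ward) clustering of the spatial coordinates alone, and a deterministic
merge–split refinement guards against mis-seeded local optima.

**Partition comparison.** Group-level consensus partitions are built by
co-association (evidence-accumulation) clustering, and compared with
normalized mutual information,

    NMI(A, B) = -2 ΣΣ N_ij log(N_ij N / (N_i N_j))
                ------------------------------------------
                Σ N_i log(N_i / N) + Σ N_j log(N_j / N)

with significance from a group-reallocation permutation test (subjects
randomly reassigned to two groups of the original sizes, 1000 times).

**Shape.** Voxelwise log-Jacobian determinants of the template-to-subject
deformation field (`log det J > 0` = expansion) are averaged per nucleus and
tested against zero with a covariate-adjusted one-sample t-test (age,
intracranial volume, DOC duration), FDR-corrected across nuclei.

**Microstructure.** Fixels (FOD lobes) are extracted per voxel; apparent
fiber density (FD) is the integral of the FOD over the lobe,
fiber-bundle cross-section `FC = |det J| / ||J d||` for fixel direction `d`,
and FDC = FD * FC. Tensor metrics FA/MD/AD/RD come from the eigenvalues.
All metrics are averaged per nucleus and per thalamo-cortical pathway and
compared between groups with covariate-adjusted permutation tests (2000
permutations, Benjamini–Hochberg FDR at q = 0.05), plus partial correlations
with the CRS-R behavioral score.

**Classification.** L1-penalized logistic regression over the 7 metrics of
all nuclei (volume excluded), evaluated by stratified 3-fold
cross-validation repeated 20 times, comparing feature sets from
individual-level, population-level (consensus), and whole-thalamus
parcellations.

## A worked example

```r
library(thalparc)

phantom <- make_phantom(phantom_config(seed = 1))
phantom
#> FOD phantom: grid 20x24x16, 1680 thalamus voxels, 7 nuclei, lmax 6

fit <- kmeans_segment(phantom$fod, phantom$mask, clustering_config())
fit
#> Thalamic parcellation (individual): 1680 voxels, 7 nuclei
#>   k-means: 3 iterations, objective 3.741e+05, converged

matched <- match_labels(fit, phantom$parcellation)
mean(dice_scores(matched, phantom$parcellation))
#> [1] 1
```

The fitted object supports `print`, `summary`, `fitted` (the label volume),
`coef` (centroids), `predict` (label new voxels) and `plot` (axial slice).

A full cohort analysis:

```r
cohort <- make_cohort(n_hc = 10, n_mcs = 5, n_vs = 5,
                      phantom = phantom_config(tessellation_level = 2, seed = 1),
                      effects = effect_config(), seed = 101)
report <- run_pipeline(cohort, pipeline_config(seed = 1),
                       reference = cohort$template$parcellation)
report
#> Individualized thalamic parcellation report
#>   consensus NMI (HC vs DOC): 0.763 (p = 0.77)
#>   nuclei with significant shape change: 1, 3, 6, 7
#>   FD columns significant after FDR: 38
#>   doc_vs_hc accuracy: individual 82%, population 70%, whole 56%
#>   mcs_vs_vs accuracy: individual 80%, population 83%, whole 58%
```

The report recovers the planted structure: nucleus 6 (the dorsal-posterior
stand-in) expands (`mean_logj_doc = +0.106`, q < 0.05), nucleus 1 (the
anterior stand-in) shrinks (`-0.080`, q < 0.05), FD is significantly reduced
in the designated nuclei and pathways, and CRS-R correlates negatively with
the nucleus-6 volume change and positively with its FD (`report$correlations`).
Nuclei 3 and 7 show the compensating compression/expansion that volume
redistribution inside the thalamus block implies. `write_cohort()` /
`write_report()` serialize everything as NIfTI + TSV + JSON;
`inst/cli/thalparc` exposes `simulate`, `segment`, `nmi` and `run-all`
subcommands for shell use.

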