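# tmespectra

Spatial and spectral-graph analysis of imaging-mass-cytometry (IMC) tumor
microenvironments in R.

IMC measures ~30–40 metal-tagged antibodies simultaneously at 1 µm
resolution over tissue sections, producing multichannel count images in
which malignant epithelial (cytokeratin+, CK+) tumor nests sit in stroma
populated by CD4+/CD8+ T cells, CD68+ macrophages (TAMs) and CD20+ B
cells. `tmespectra` is for researchers comparing two patient groups on
such data — the motivating design is non-small cell lung cancer in people
with and without HIV — and implements the complete comparative pipeline:

* **Segmentation** — nuclear detection on the DNA channels (Gaussian
  smoothing, Otsu threshold, 4-connected labeling) and fixed-radius
  Voronoi expansion to cell objects (default radius 3 px; overlapping
  cells split at the perpendicular bisector, i.e. the median distance
  between their nuclei), then per-cell mean marker quantification.
* **Phenotyping** — ordered positivity/negativity gating
  (CK−CD68−CD20−CD3+CD4+CD8− → CD4 T, and so on), PhenoGraph-style
  clustering (arcsinh + z-score, exact kNN, Jaccard shared-neighbor
  weights, Louvain), and per-group statistics: cluster proportions, fold
  changes FC = p₁/p₂, two-sided Fisher exact tests with Holm adjustment,
  pooled Wilcoxon marker tests, and a random-intercept model
  `intensity ~ group + (1 | case)` for between-patient variability.
* **Spatial statistics** — per-cell minimum Euclidean distances between
  cell types within each ROI; two-group Wilcoxon comparison with effect
  size **r = Z/√N**; kNN spatial graphs and permutation-based
  neighborhood-enrichment z-scores.
* **Spectral-graph patch classifier** (segmentation-free) — per case, 14
  patches of 35 µm side centered on the highest CK signal; a
  Gaussian-kernel graph over the patches; for every marker a
  personalized-PageRank steady-state distribution (SSD)
  `s = αPᵀs + (1−α)t` with teleport `t` ∝ the marker's patch expression
  (α = 0.85); the markers × patches SSD representation matrix; a
  diffusion-map embedding with Nyström out-of-sample extension;
  leave-one-case-out RBF-SVM classification with per-case majority vote;
  and marker ranking by the L1 distance between group-averaged sorted
  SSDs.
* **Synthetic cohort generator** — two-group cohorts of rendered
  multichannel images with ground truth (tumor nests as disk unions,
  stromal immune cells at configurable exclusion distances, lognormal
  per-cell means with Poisson rendering), so every stage is testable
  without access to patient data.

## Worked example

```r
library(tmespectra)

cfg <- simulation_config(n_cases_per_group = 2, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> <synthetic_cohort> 4 cases (2+2), 4 ROIs, 720 truth cells

## segment and gate one ROI
img <- cohort$images[["PWH_01_r1"]]
img
#> <multichannel_image> PWH_01/r1 256x256 px, 27 channels, 1 um/px
cells <- gate_populations(segment_roi(img), panel = cfg$panel)
attr(cells, "gate_counts")
#> pop
#>     B  CD4T  CD8T   TAM tumor
#>    15    29    30    25    75
```

The gate recovers the simulated composition (15 B, 30 CD4 T, 30 CD8 T,
25 TAM, 80 tumor cells per ROI: 174 of the 180 cells are segmented and
assigned a population here; the missing ones are close tumor-cell pairs
merged during expansion).

```r
## immune-to-tumor spatial exclusion
dd <- min_distance_distributions(cohort$truth, "CD8T", "tumor")
grp <- cohort$manifest$group[match(dd$case_id, cohort$manifest$case_id)]
compare_distances(dd$distance_um[grp == "PWH"], dd$distance_um[grp == "PWOH"])
#> <distance_comparison> n = 60 + 60, U = 2963.5, Z = 6.107, r = 0.557, p = 1.02e-09
```

The default configuration places immune cells 15 µm farther from the
nest boundary in the HIV-like group; the positive effect size
(r = 0.56) reports that PWH-group CD8-to-tumor minimum distances are
stochastically larger.

```r
## spectral patch representation and marker ranking
patches <- lapply(cohort$images, select_patches)
rep <- build_representation_matrix(patches, cohort$manifest)
rep
#> <representation_matrix> 27 markers x 56 patches (4 cases)
head(rank_markers(rep), 3)
#>       marker l1_distance rank
#> CD68    CD68   0.1304697    1
#> FOXP3  FOXP3   0.1229229    2
#> VISTA  VISTA   0.1221696    3
```

(Two cases per group is far too few for a stable ranking — at this size
the L1 distances are dominated by sampling noise; the validation suite
uses 10–20 cases per group, where a planted marker ranks first in ≥ 90%
of replicate cohorts.) Classification of a full cohort is one call:

```r
res <- loocv_classify(rep)      # leave-one-case-out RBF-SVM
res$case_accuracy; res$confusion
```

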