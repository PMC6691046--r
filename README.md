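# cytofuse

Multi-tube mass cytometry merging, clustering and phenotyping in R.

Mass cytometry (CyTOF) measures roughly 40 protein markers per cell. To
phenotype a complex disease at higher resolution, aliquots of one blood
sample can be stained with several antibody panels that share a common
**backbone** of markers; the per-tube profiles are then fused into a
single high-dimensional profile by matching cells across tubes in backbone
space. cytofuse is aimed at computational immunologists who want that
whole workflow — merging, clustering, categorical phenotyping and group
statistics — as tested, scriptable R functions, exercised end-to-end on a
synthetic multi-panel cohort with known ground truth.

## The method

**Backbone matching.** Cells `a` (in tube A) and `b` (in tube B) are
compared by the Euclidean distance over the backbone markers `B`:

    d(a, b) = sqrt( Σ_{m ∈ B} (a_m − b_m)² )

computed on arcsinh-transformed intensities (`asinh(x / 5)`). A pair is
merged iff it is

* **acceptable** — `d(a, b) ≤ T` (threshold `T = 3` by default), and
* **non-ambiguous** — `a` and `b` are *mutual* nearest neighbors among the
  still-unmatched cells.

Matched cells are removed and the search repeats on the remainder until no
round adds a pair. The merged cell takes the arithmetic mean of the two
contributors on the backbone and each contributor's values on its
panel-specific markers; a three-tube merge applies the same step
sequentially. Accounting obeys `excluded = Σ inputs − k × merged` for a
`k`-profile merge, and `merged ≤ min(inputs)`.

**Downstream.** Per sample: uniform pre-downsampling, local-density
estimation and density-dependent downsampling to 5%, pooled agglomerative
clustering (Euclidean, Ward) into `k` clusters, and full upsampling of
every cell to its nearest cluster median. Cluster phenotypes are
quantized into five uniform categories (negative / low / medium / high /
bright) over each marker's 5th–95th percentile range, with clusters under
50 cells left unassigned, and annotated by editable lineage-marker rules.
Clusters whose abundance fold-change between conditions exceeds 4 are
flagged as enrichment-trend clusters, and per-population marker MSIs
(mean signal intensities) are compared between groups with an exact (or
Monte-Carlo) two-sample permutation test.

## Worked example

Simulate one individual measured by three panels (35/32/33 markers, 14
shared), split with tube-to-tube backbone noise, and merge back:

```r
library(cytofuse)
spec  <- make_hiv_cohort_preset(seed = 1, n_events = 1000)
gen   <- generate_individual(spec, "HEA-1", seed = 2)
tubes <- split_panels(gen$profile, spec$panels,
                      backbone_noise_sd = 0.05, seed = 3)
bb    <- backbone_spec(spec$panels[[1]]$backbone, threshold = 3)
res   <- merge_panelset(tubes, bb, order = c("#A", "#B", "#C"))
res$merged
#> <cyto_profile> HEA-1 / #A+#B+#C: 1000 events x 72 markers (arcsinh units)
merge_report(res)
#>    profile n_cells n_excluded
#> 1       #A    1000         NA
#> 2       #B    1000         NA
#> 3       #C    1000         NA
#> 4 #A+#B+#C    1000          0
matching_accuracy(res, tubes)
#> [1] 1
```

All 1000 cells are re-paired correctly (the report's last row shows the
merged count and the excluded-cell identity), and the merged profile
carries the full 72-marker phenotype. Group comparisons use exact
permutation tests; with complete separation of two groups of three, the
smallest attainable two-sided p-value is 2 of the 20 relabelings:

```r
permutation_test(c(10, 11, 12), c(0, 1, 2))
#> permutation test: observed = 10, p = 0.1 (exhaustive, 20 relabelings)
```

## Analysis workflow

The numbered drivers under `analysis/` replay the full study design on
the synthetic cohort and write their tables under `results/`:

1. `01_simulate_cohort.R` — 3 healthy + 3 treated-HIV individuals, 5,000
   cells each, three panels, ground truth on disk.
2. `02_merge_panels.R` — per-individual backbone merging, accounting
   report, pairing accuracy against ground truth.
3. `03_cluster_phenotype.R` — density-dependent downsampling, pooled
   clustering (k = 100 at this scale), categorical heatmap, population
   annotation.
4. `04_differential_abundance.R` — enrichment-trend clusters and monocyte
   MSI permutation tests; at this cohort's effect sizes every shifted
   activation marker (CD11a, CD11b, CD32, CD38, CD64, CD83, CD86, TLR2)
   reaches the exhaustive minimum p of 0.1 with positive direction.

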