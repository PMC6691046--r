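---
title: "Merging multi-tube mass cytometry profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging multi-tube mass cytometry profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cytofuse implements a multi-tube mass cytometry workflow: aliquots of one
sample are stained with several antibody panels sharing a backbone of
common markers, the per-tube event matrices are fused into one
high-dimensional profile by matching cells in backbone space, and the
fused profiles feed a clustering / categorical-phenotyping / group-testing
pipeline. This vignette records the model as implemented, the parameters
that matter, and the design decisions taken where the procedure left room.

## The matching model and its assumptions

All analysis operates on arcsinh-transformed intensities,
`asinh(x / cofactor)` with cofactor 5 (the standard CyTOF choice; the
cofactor divides raw ion counts before the variance-stabilizing asinh).
`cyto_profile` objects track a `transformed` flag and refuse a second
transform, because every downstream distance is meaningful only in
arcsinh units applied exactly once. Matching distances are computed on
transformed values; the workflow transforms first and merges second, so
no other convention is representable.

Two cells from different tubes are merged iff they are **acceptable**
(backbone Euclidean distance at or below the threshold, default 3
arcsinh units) and **non-ambiguous** (each is the other's nearest
still-unmatched neighbor). The matcher repeats rounds on the residual
unmatched cells until a round adds no pair: a cell whose nearest neighbor
was claimed by a better partner competes again against what remains. This
iterative-residual reading maximizes yield while keeping the mutual-NN
stringency; the per-round pair set is computed simultaneously from the
same unmatched sets, which makes the result symmetric in the two inputs.
Equidistant neighbors are resolved toward the lowest row index so results
are deterministic; the contract is exact nearest neighbors, not
approximate.

A merged cell averages the two contributors on the backbone and copies
each contributor's panel-specific values. For three or more tubes the
merge is sequential in a stated order (default `#A`, `#B`, `#C`), and the
intermediate profile's backbone holds the running average — the only
representation consistent with the two-profile contract. Whether one
should instead carry both backbone copies into the next round is a
genuine open point; averaging was chosen and is documented here. The
accounting identity `excluded = Σ inputs − k × merged` holds by
construction and is asserted for every merge.

## Clustering stage

The cluster stage is a parameter-matched density-normalized workflow, not
a re-implementation of any specific published package's internals: per
sample, a uniform pre-downsample (default 67,000 cells), local-density
estimation, density-dependent downsampling to a 5% target, pooled
agglomerative clustering (Euclidean distance, Ward criterion) cut at `k`
clusters, and full upsampling of every cell to the nearest cluster
median. Defaults follow the high-resolution run (`k = 500`);
validation-style and desk-scale runs use `k = 100`. Pooling cells from
all individuals before clustering (rather than per-sample clustering with
meta-clustering) is the declared choice: it is what makes cluster ids
comparable across individuals.

Density of an event is the number of events within radius `r`, where `r`
is 5 times the median nearest-neighbor distance of a seeded subsample of
at most 2,000 events — a pragmatic kernel in the density-downsampling
tradition; both the multiplier and the outlier/target percentiles
(defaults 1 and 5) are exposed. Downsampling removes events below the
outlier percentile, always keeps events below the target density `TD`,
keeps denser events with probability `TD / density`, and applies a final
uniform thinning when the expected yield still exceeds the requested
fraction. The property that matters — rare populations survive at a
higher proportion than under uniform thinning — is asserted by
simulation in the test suite.

## Categorical phenotyping

Cluster phenotypes are the unweighted mean of per-individual medians
(individuals with no cells in a cluster do not contribute), quantized
into five uniform categories over each marker's 5th–95th percentile range
computed on the pooled cells of all individuals. Pooled (rather than
per-individual) percentiles keep categories comparable across clusters.
Values at or below the low bound map to category 1, at or above the high
bound to 5, and interior bin edges belong to the upper bin; a degenerate
range maps values at the constant to 1 and above it to 5. Clusters with
fewer than 50 cells in the whole dataset are unassigned — too few cells
to defend a median. Row and column dendrograms (complete linkage,
Euclidean) are computed on the categorical matrix, not on the raw
mean-of-medians; the choice is ours and recorded here. Annotation rules
are shipped as editable category predicates (e.g. CD66 high → PMN;
CD3 high with CD19/CD66 negative → T cell) evaluated in priority order;
they are declared heuristics standing in for manual annotation.

One consequence of categorical coarseness worth knowing: a marker that
sits near the top of its 5th–95th range in *both* conditions (CD64 on
monocytes in the preset, for instance) can saturate at category 5 on both
sides, so a real upward shift is sometimes invisible in categories even
when the MSI permutation test detects it. That is a property of
quantization, not a failure of the test.

## Group statistics

Cluster abundances are normalized to per-individual proportions before
being summed within condition; the fold-change between condition sums
uses a pseudocount of one cell at the smallest individual total so
empty-in-one-condition clusters stay finite. Clusters above four-fold in
either direction are enrichment-trend clusters; swapping condition labels
inverts the classification exactly. The two-sample permutation test uses
the two-sided statistic `|mean(x) − mean(y)|`, enumerating all
`choose(n1+n2, n1)` relabelings when that count is at most
`max_permutations` (default 10,000 — 3v3 and 6v6 designs are always
exhaustive) and Monte-Carlo sampling with the add-one convention
otherwise. Exhaustive p-values are computed with a relative tolerance of
1e-12 on the statistic comparison so the identity relabeling always
counts. Direction is reported alongside the two-sided p. Note the
granularity floor: a 3v3 exhaustive test cannot produce p below 2/20 =
0.1, and can never reject at α = 0.05 — which is why the type-I
calibration in the acceptance suite uses a 6v6 design (924 relabelings).
No multiple-testing correction is applied; tests are reported unadjusted.

## The synthetic cohort generator

The generator exists to give every stage a ground truth, not to model
CyTOF physics. Each population is a diagonal multivariate normal in
arcsinh space (independent markers; correlation structure is out of
scope), with per-condition abundance weights and optional per-condition
mean shifts. Generation happens directly in arcsinh units — committing to
a raw ion-count model would add assumptions the downstream stages never
use. Tube-to-tube variation is i.i.d. Gaussian noise added to the
backbone columns of each panel copy (default sd 0.05 arcsinh units), and
each tube's rows are shuffled independently; event ids follow the shuffle
for scoring only and are never visible to the matcher.

The preset cohort (`make_hiv_cohort_preset`) encodes a two-condition
whole-blood design: three healthy and three treated-HIV individuals,
eight leukocyte populations (CD4/CD8 T cells, B cells, NK cells,
monocytes, PMNs, mDCs, pDCs) with a granulocyte-dominated mixture, three
panels of 35/32/33 markers sharing the 14-marker backbone (CD1c, CD3,
CD11c, CD14, CD16, CD19, CD32, CD64, CD66, CD86, CD123, CD141,
Granzyme B, HLADR), and upward HIV-condition shifts of 1–2 arcsinh units
on activation and adhesion markers (CD11a, CD11b, CD32, CD38, CD64,
CD83, CD86, TLR2, and relatives) concentrated on monocytes and PMNs with
related lymphocyte and dendritic shifts. Population means, abundances and
shifts were fixed once when the preset was written, at values a cytometry
analyst would call plausible for strongly separated leukocyte lineages.

What the generator does **not** emulate: marker correlations within a
population, spillover, doublets, acquisition drift, eosinophil
background, or heavy-tailed expression. Passing tests on this cohort
demonstrate that the algorithms invert the generative process they were
given — perfect pairing at zero noise, high accuracy at realistic noise,
directional disease signals propagating to the heatmap and tests — not
that any instrument dataset would merge with the same fidelity.

## Problem sizes and numerical notes

Desk-scale runs use 5,000 events per individual (the analysis scripts and
the recovery checks), `k = 100` for the six-individual cohort and
`k = 50` for reduced runs; these sizes were chosen so the whole workflow,
test suite and acceptance script run comfortably on a laptop while
leaving every population with hundreds of cells per individual. The
published six-donor accounting table operates on printed counts and does
not depend on simulation scale.

Distance computations use an exact per-pair accumulation for small
problems (preserving bit-exact zeros for duplicate rows and hence
deterministic tie-breaks against brute-force oracles) and the expanded
square form via BLAS, clamped at zero, for large ones. Population
standard deviations may be exactly zero (the degenerate point
distribution), which the sampler handles naturally. File formats: TSV is
the primary, fully round-tripping format; the FCS 3.0/3.1 reader/writer
covers single-dataset list-mode files with float32/float64 storage and
plain (non-escaped) TEXT segments, which is sufficient for typical
instrument exports and for self-consistent pipeline output.

## Known limitations

* The merge quality degrades gracefully but silently as backbone noise
  approaches the inter-cell spacing; no diagnostic flags ambiguous
  regimes beyond the excluded-cell counts.
* Annotation rules are heuristics; clusters mixing lineages (possible at
  coarse `k`) take the first matching label.
* The clustering stage's agreement with any particular published
  implementation is at the level of its user-facing parameters, not its
  internals; MST layouts and t-SNE embeddings are out of scope.
* Permutation tests at 3v3 have a hard p-value floor of 0.1; designs of
  that size can rank markers but not clear conventional significance.
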