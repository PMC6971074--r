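---
title: "Methods: single-cell immune phenotyping of multiplexed IF images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell immune phenotyping of multiplexed IF images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxifcell)
```

# The problem

Cyclic multiplexed immunofluorescence stains one FFPE tissue section with
many antibody rounds (four markers plus a DAPI counterstain per round),
producing a stack of several dozen channels for the same cells. From such
stacks, `mxifcell` quantifies the immune infiltrate of a tumour at
single-cell resolution: which cell types are present, in what
proportions, in which functional state, and how they are arranged in
space. The package was built around the immune landscape of uterine
leiomyosarcoma — a tumour whose infiltrate is dominated by heterogeneous
macrophage populations with a smaller, phenotypically stereotyped T-cell
component — but every stage is generic.

The pipeline has six stages, each an exported function family:

1. **Image preparation** — rigid registration of rounds on DAPI,
   autofluorescence subtraction.
2. **Dual-mask segmentation** — a DAPI *nuclear* mask and a combined
   leukocyte-lineage *targeted* mask.
3. **Quantification** — per-cell mean marker intensity, centroid, area.
4. **Phenoclustering** — kNN/Jaccard graph + Louvain communities.
5. **Classification** — rule-based nine cell-type calls per cluster,
   per-case T-cell exhaustion state.
6. **Spatial statistics** — permutation test of pairwise
   enrichment/avoidance at two ranges; cohort summaries.

Because no raw images of the original cohort are publicly available, the
package ships a first-class synthetic-tissue generator
(`tissue_spec()`, `generate_cell_table()`, `render_image()`) whose output
carries exact ground truth; all quantitative claims about the pipeline
are demonstrated on that generator plus the shipped 21-case clinical
table.

# Registration and background

Rounds are aligned by integer-pixel translation estimated from the FFT
cross-correlation of mean-centred DAPI images (`register_rounds()`).
Translation-only is deliberate: each round re-images the *same* physical
section, so rotation and scale are fixed by the scanner; the estimator
recovers any shift up to a quarter of the field exactly on clean images
and within one pixel at noise up to ~20% of signal. A round whose DAPI
channel has zero variance is refused (`degenerate-image` error) rather
than silently aligned.

Autofluorescence is modelled as a single blank reference channel scaled
by a global factor (default 1): every non-DAPI channel becomes
`max(0, channel - scale * AF)` and the reference channel is dropped
(`subtract_autofluorescence()`). Subtraction is pixelwise monotone in the
scale and can never create negative intensities.

# The two masks

`make_nuclear_mask()` smooths DAPI with a Gaussian
(`smoothing_sigma_um = 1`), thresholds (Otsu by default), and labels
8-connected components, dropping objects under `min_area_um2 = 12` —
roughly half the area of a small lymphocyte nucleus.

`make_targeted_mask()` instead segments cells from combined leukocyte
lineage channels (by default whichever of CD43, CD45, CD68, CD163 the
panel contains). Each channel is rescaled to [0, 1] by its 99.9th
percentile and the channels are combined by pixelwise max, so a cell
bright in any single lineage channel survives combination regardless of
the others. After thresholding and labelling, `exclude_fragments()`
removes objects below the area cut or below `min_solidity = 0.5`
(pixel area over convex-hull area) — a digital stand-in for manually
excluding thin dendritic cytoplasm fragments, which are high-perimeter,
low-solidity shapes, while intact cells are near-solid disks.

The point of the second mask is macrophages: their reduced chromatin DAPI
staining leaves too little contrast for a DAPI threshold, so a nuclear
mask systematically under-counts them while lineage channels see them
plainly. `compare_mask_yield()` quantifies this as the nuclear/targeted
object-count ratio; on synthetic tissue with 30% dim-DAPI macrophages the
ratio comes out at about 0.7, and it is below 1 whenever any dim-DAPI
phenotype is present.

Two numerical caveats discovered while validating on ground truth, both
now fixed behaviour:

* Gaussian smoothing uses **replicate** boundary handling. FFT-based
  filtering with circular boundaries wraps one image edge onto the
  opposite one, which can bridge two cells that sit on opposite borders
  into a single labelled object.
* Percentile rescaling assumes each lineage channel actually contains a
  stained population. A channel with *no* positive cells gets its noise
  amplified to full scale; choose `lineage_markers` to match the panel's
  stained populations.

There is no watershed splitting: two cells whose borders approach within
about two smoothing sigmas (~2 µm at defaults) can merge into one label.
This is a documented resolution limit, not a tuned parameter; the
synthetic tissues used for exact-count validation therefore keep a 4 µm
border gap.

# Quantification

`quantify()` takes the mean intensity of every channel over each label's
pixels (mean, not median, matching the common single-cell imaging
convention), the unweighted centroid, and the pixel-count area, converted
to micrometres through the panel's pixel size. Coordinates are 0-based,
y-down; physical position is `index * pixel_size_um`. The table satisfies
an exact conservation property — summed (area x mean) over cells equals
the masked channel total — which the test suite checks to 1e-6.

# Normalization and clustering

`normalize_expression()` clips each marker above its 99th percentile
(one extreme pixel-bleed artefact should not set the scale), optionally
arcsinh-transforms (`cofactor = 5`, the usual fluorescence choice), and
z-scores. Constant columns normalize to zero with a warning rather than
NaN.

`cluster_phenograph()` builds the exact Euclidean kNN graph
(`k = 30`, the usual Phenograph operating point), reweights each edge by
the Jaccard overlap of the two neighbourhoods (edges between chance
neighbours of different modes get near-zero weight), and runs Louvain
modularity with a fixed RNG seed, so results are reproducible to the
bit.

The one genuinely open choice here is the Louvain **resolution**. At the
conventional resolution 1, modularity optimisation on a kNN graph
fragments even a single compact, isolated Gaussian mode into several
sub-communities — on ground-truthed mixtures this cost ~0.2 of ARI with
every split being a within-type division. Because distinct expression
modes are (almost) disconnected in the kNN graph, lowering the
resolution cannot merge them; it only stops the shattering. The default
`resolution = 0.1` was selected by validating against generator ground
truth: a two-blob construction and the default nine-phenotype mixture
both recover the exact partition (ARI about 1.0) across seeds at sizes
from 400 to 10000 cells. Users clustering data with genuinely continuous
substructure may prefer a higher value.

# Cluster profiling and the rule engine

`profile_clusters()` reduces each phenocluster to its mean normalized
expression and its fraction of positive cells per marker (positivity
cut: 0.5 normalized units by default, per-marker overridable). That
table is the numeric form of the usual phenocluster heatmap.

`classify_cluster()` applies declarative rules: a rule matches when every
required-positive marker is positive in **at least one third** of the
cluster's cells and every required-negative marker in less than one
third. The one-third criterion is fixed — it is the quantified reading of
"expressed at high levels in a third or more of the cells" that defines
marker positivity for a phenogroup — while the per-cell positivity
threshold is a configurable knob. Among matching rules the highest
priority wins; equal top priorities raise an explicit tie error, never a
silent choice; no match returns `"Unassigned"` (how tumour and stromal
clusters fall out of the infiltrate analysis).

The default rule table (`inst/extdata/cell_type_rules.yaml`) encodes the
nine infiltrate types: CD4 and CD8 T cells, NK (CD45+ CD3−
GranzymeB+ Granulysin+), B, TAM (CD16+ CD68+ CD163+), CD16− histiocytes,
phagocytes (CD68+ CD163− CD16−), LYZ+ VISTA+ inflammatory monocytes, and
an undefined monocyte/macrophage fallback. Two reconstructions are worth
flagging: "CD163 and/or CD68, CD16−" is split across the Histiocyte and
Phagocyte rules (their union covers the and/or), and the "spotty
presence" definition of the undefined class is not expressible as fixed
positive/negative requirements, so that class is the lowest-priority
CD45+ non-lymphoid fallback. Rules are data, not code; replace the YAML
to change the classification.

# T-cell exhaustion state

`classify_tcell_state()` operationalizes the per-case call. Lymphocyte
density (CD4 T + CD8 T + NK per mm²) below 60 — the published cut
separating "deserted" tumours — gives `Deserted`. Otherwise the fractions
of PD1+ and TCF7+ CD8 T cells (positivity as above) decide:
PD1 ≥ 0.33 with TCF7 < 0.33 is acute exhaustion, TCF7 ≥ 0.33 with
PD1 < 0.33 is chronic exhaustion (TCF7 marking the resident-memory,
reactivatable state), and both high is mixed. Two edge cells complete the
partition: a dense case with *neither* fraction above threshold shows no
exhaustion phenotype and is called `Deserted`, as is a dense case with no
CD8 T cells at all (with a warning). The 0.33 thresholds deliberately
reuse the only quantified fraction criterion in the classification
scheme; both are arguments. Note the original "deserted" labels also
reflected qualitative review; this implementation is strictly numeric.

# Neighbourhood analysis

`interaction_test()` asks, for every ordered phenotype pair (A, B),
whether B cells are enriched or depleted around A cells relative to
chance, separately at a submicroscopic range (within 100 µm) and a
microscopic annulus (100–250 µm). The statistic is the mean number of
B-neighbours per A-cell by centroid distance; the null shuffles type
labels over the fixed positions (tissue architecture is held constant,
only labels are exchangeable); p-values use the add-one permutation
formula, so the smallest attainable p is `1/(n_permutations + 1)` and
the test is conservative (super-uniform under the null — calibration at
nominal 0.05 runs near 0.03–0.04). Significance flags use strict
`p < alpha`. No multiple-testing correction is applied by default, since
each pair is usually read as its own hypothesis; `adjust = "BH"` applies
Benjamini–Hochberg within each range.

# The synthetic-tissue generator

`default_phenotypes()` defines nine immune phenotypes plus an optional
marker-negative tumour phenotype (default 35% of cells). The tumour
fraction is not decoration: in real sections most segmented cells are
tumour, which keeps pan-leukocyte channels like CD45 bimodal; a
synthetic tissue of *only* immune cells would make CD45 near-constant
and z-scoring would erase it. Immune abundances (TAM 25%, histiocytes
15%, CD8 T 15%, CD4 T 10%, undefined mono/mac 10%, phagocytes 8%,
inflammatory monocytes 7%, NK 5%, B 5% of the immune compartment) echo a
macrophage-dominated sarcoma infiltrate. Expression is zero-truncated
Gaussian (exact inverse-CDF truncation, so marginal means are
analytically checkable); macrophage-lineage types carry
`dapi_intensity_factor` 0.35–0.8, reproducing the dim-DAPI phenomenon.
Both pan-leukocyte channels (CD43, CD45) are bright on every immune
phenotype: under the max-combination this makes a cell invisible to the
targeted mask only if *both* channels draw extreme low tails at once.

Cells are hard disks placed by rejection sampling under a configurable
spatial model: CSR (validated by Clark–Evans index ≈ 1), Thomas-style
parent/offspring clustering of one type, or hard-core avoidance between
two types. The renderer stamps each cell's sampled expression uniformly
on its disk, applies per-round rigid shifts, adds constant
autofluorescence plus truncated Gaussian pixel noise.

What the generator does **not** emulate: optics (no PSF, no chromatic
shift), staining-cycle degradation, cell-shape variation (disks only),
overlapping or touching cells, intra-cell texture, and spatially varying
autofluorescence. Passing tests on this generator therefore demonstrate
algorithmic correctness under the stated model — exact count recovery,
ARI ≈ 1, composition within 2 points — not performance on real tissue,
where segmentation error and marker bleed dominate.

# Problem sizes and reproducibility

The validation suite uses the sizes it reports: 500-cell fields for
segmentation (3 seeds), 5000 cells for clustering ARI (3 seeds), 10000
cells for end-to-end composition recovery, 200 CSR replicates of 500
cells for permutation-test calibration, and 20 replicates for power.
These were chosen as the smallest sizes at which the quantities of
interest are statistically stable. Every stochastic step takes an
explicit seed and is bit-reproducible given it.

# Known limitations

* No watershed splitting of touching cells; counts are exact only for
  separated cells (border gap ≳ 2 smoothing sigmas).
* Translation-only registration; no deformable or rotational component.
* The rule table is a reconstruction from published phenotype
  definitions, not a transcription of an original criteria table.
* The `Deserted` call is strictly numeric; the original cohort labels
  also included qualitative review.
* Semiquantitative clinical scores (MHC, B7H3, Axl, IDO, desmin) are
  carried verbatim as strings and never computed on.
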