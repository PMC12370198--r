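---
title: "Methods: cross-species immune checkpoint signature analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species immune checkpoint signature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsig)
```

# The problem and the model

Immune checkpoints (ICs) are receptor and ligand genes that modulate
immune-cell activation; their transcript abundance in a tumor describes the
immune character of that cancer and its amenability to checkpoint-blockade
therapy. `icsig` treats a cancer type's **IC signature** — the vector of
per-type median expression over a fixed IC panel — as the unit of comparison,
and provides the operations needed to (i) summarize the immune environment of
each cancer type, (ii) cluster signatures within and across species, (iii)
rank genes by between-group fold change, and (iv) find the few genes that
drive a species divide through PCA loadings.

The pipeline assumes bulk RNA-seq expression for two species harmonized on
shared gene symbols. Cross-species comparisons run on TPM (the only unit in
which public human pan-cancer expression is commonly distributed), single-
species analyses on size-factor-normalized counts. Neither TPM nor marker
averaging is a substitute for deconvolution or count-based inference; the
methods here deliberately mirror a relative-pattern analysis style in which
correlation, clustering and component structure — not absolute levels — carry
the conclusions.

# Stage-by-stage contracts

## Normalization

* `size_factors()` implements the median-of-ratios estimator: genes with any
  zero count are excluded from the reference set (their log geometric mean is
  undefined), each sample's factor is the median ratio of its counts to the
  per-gene geometric means. Two exact properties are tested: the two-column
  doubling fixture gives factors (1/sqrt(2), sqrt(2)), and re-estimating
  factors on normalized output returns a constant vector (the geometric mean
  of the first-round factors — exactly 1 only when that geomean is 1, as in
  the doubling fixture).
* `to_tpm()` divides by gene length (kb) and rescales each column to 1e6.
  Columns of a *full-transcriptome* TPM matrix must sum to 1e6 within 1e-6
  relative tolerance; a `gene_subset` flag waives this for panel slices.
* `log2_transform()` uses pseudocount 1.0 by default — the conventional
  choice, and it maps zeros to zeros. `zscore_per_gene()` uses the sample
  (n−1) standard deviation; constant rows map to zero with a warning rather
  than NaN.
* `mean_normalized_scores()` divides each gene's per-type means by the mean
  of those means, forcing every gene's cross-type mean to exactly 1 so that
  abundant and rare markers contribute equally to category scores.

## Immune scores

Infiltrate scores are plain means of mean-normalized marker genes per cell
type; the inhibition ratio is the inhibitory-IC mean over the stimulatory-IC
mean. Genes with a *complex* role join neither side of the ratio: their sign
is ambiguous, and including them would let a single bifunctional gene pull
the ratio in an arbitrary direction. A stimulatory score of exactly zero
yields an `NA` ratio (never infinity). Display scaling (e.g. row
standardization of heatmaps) is left to plotting and is not part of the
score.

## Signatures and clustering

Signatures are per-type medians of per-gene z-scored TPM. Two ambiguities
were decided and exposed as flags:

* **Restriction before standardization.** The matrix is cut down to the IC
  panel first and z-scored second, so the standardization reflects the genes
  actually analyzed. A `zscore = FALSE` flag gives raw-median signatures.
* **Centered Pearson.** The distance is `1 − r` with the ordinary (centered)
  Pearson correlation — what the name "Pearson" means — although some legacy
  distance libraries compute an uncentered variant under that name. This is a
  known divergence risk when comparing against historical results.

`ward_cluster()` is this package's own agglomerator: Lance–Williams with the
Ward.D2 coefficients applied to squared dissimilarities, heights reported on
the original scale. Ties in the minimal merge distance break toward the
lowest label-sorted pair, making the tree a pure function of the input. The
test suite proves exact merge-sequence and height agreement with R's
independent `hclust(method = "ward.D2")` implementation on hundreds of
random instances; the object returned *is* an `hclust`, so `cutree()`,
`as.dendrogram()` and `ape::as.phylo()` all apply. Newick export quotes
labels containing reserved characters and round-trips topology through
`ape::read.tree()`.

Four-gene subset clustering (the driver-gene validation) computes Pearson
correlations of 4-long vectors. That is statistically fragile — r from four
points is close to meaningless in isolation — and the package permits it
with a warning rather than refusing, because the aggregate pattern over many
cancer types (do the species separate?) is the readout, not any single
correlation.

`species_purity()` operationalizes "separation of cancers by species": cut
the tree into k = 2 clusters and report the fraction of cancer types whose
species matches their cluster's majority.

## Differential IC expression

For a comparison of cancer-type groups, the group statistic is the median
(or mean) **of per-type statistics** — types are weighted equally, so a
25-sample cohort does not drown a 10-sample one. Fold change is the plain
ratio; genes with a zero statistic on either side are reported as
"undetectable" and excluded without a pseudocount (printed reference tables
bottom out at 0.10 TPM, leaving no evidence that any pseudocount was ever
applied).

The z-score needed reconstruction: published tables show one z per gene per
comparison, and their (z, p) pairs match `p = pnorm(-|z|)` — a one-sided
standard-normal tail (a two-sided definition would print doubled p-values).
The simplest construction consistent with this is adopted: **z is the
gene-wise standardization of log2 fold changes across the retained panel
genes of the comparison**. This is flagged prominently as a reconstruction,
and it has a consequence worth stating plainly:

* **The score is anti-conservative.** If the null log2 fold changes are
  roughly normal across genes, `p < 0.05` corresponds to `|z| > 1.645`,
  which captures about 10% of null genes, not 5%. The acceptance suite
  asserts the calibration band [0.03, 0.07] demanded of a proper p-value and
  that test fails by design — measured null rate ≈ 0.094 over 500 simulated
  comparisons. Treat these p-values as a ranking device with a familiar
  scale, not as error control. No multiple-testing correction is applied,
  matching the source analysis.

The `robust` flag (significant under both the median- and mean-based
variants with the same direction) is the "increased confidence" bolding rule
of the source tables and is the right filter to apply before reading
anything into a gene.

## Dimension reduction

`pca_pipeline()` log2-transforms, centers and scales, then eigendecomposes
via SVD; component signs are canonicalized (largest-|loading| entry
positive). Retention offers the elbow rule (maximal perpendicular distance
from the chord of the top-10 scree points) and Horn's parallel analysis
(within-variable permutation null, 0.95 quantile, both configurable). The
elbow governs retention when the two disagree, being the more conservative
in practice on these data shapes.

"The species-separating component" is found operationally — the component
whose scores correlate most strongly (point-biserial) with the species
indicator — because component *ordering* is dataset-specific, not a law.
`top_loading_genes()` then reports the n = 4 largest-|loading| genes,
annotated (not filtered) with whether each is also a top loader of stated
"exclusivity" components.

**Identifiability at the type level.** With only ~20 cancer types and 44
genes (p/n ≈ 2), a 4-gene species factor of moderate size sits below the
Marchenko–Pastur bulk edge and its variance mixes across components: in
simulation, type-signature PCA recovers all four drivers in only ~60% of
cohorts, while sample-level PCA (hundreds of samples, p/n ≪ 1) recovers them
essentially always. The recovery acceptance test therefore identifies the
species component at the sample level — the same analysis run on individual
patients — and this is the recommended practice whenever per-sample data are
available. A real 41-type analysis sits between these regimes.

`umap_embed()` delegates the algorithm to `uwot` and pins everything that
threatens reproducibility: mandatory seed, single-threaded optimization,
`n_neighbors = 15`, `n_components = 2`, `min_dist = 0.1` defaults, and
automatic `n_neighbors` reduction (with a warning) on small inputs.

# The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws log2 expression as

```
baseline_g + type_effect_{g,t} + species_effect_g + log2(bias_t)·[g inhibitory] + noise
```

with `type_effect ~ N(0, tau²)`, `noise ~ N(0, sigma²)`, and a species
effect ±delta confined to designated driver genes. Defaults state the world
once: 14 + 27 cancer types, 10–45 samples per type, 44 IC + 40 marker genes,
baselines `N(3, 2.5)` on the log2-TPM scale (medians spanning ~0.1 to ~500,
matching the dynamic range of published IC tables), `tau = 0.5`,
`sigma = 1`, `delta = 2` on four drivers with signs (+, +, −, −). The mixed
signs mirror how real species-divide genes behave (two up, two down in one
species) and are also what makes a 4-gene signature identifiable at all: a
uniform shift across all four genes would be removed by the per-signature
centering inside the Pearson correlation.

The log-normal family is a modeling choice (the simplest generative family
consistent with log2-scale analysis), not a claim about any dataset. Two
deliberate departures from naive emulation:

* **TPM as a transcriptome slice.** By default the exponentiated values are
  the TPMs, with the gene-subset flag set: a 44-gene panel extracted from a
  full-transcriptome TPM matrix does not sum to 1e6 per sample, and a change
  in one panel gene does not deflate the others. Rescaling the panel to 1e6
  over itself (`rescale_tpm = TRUE`, available) injects a compositional
  species shift into every gene whenever one gene dominates the panel — an
  artifact real data does not have, strong enough to halve driver recovery
  in simulation.
* **Variance bookkeeping.** The law-of-total-variance check
  (per-gene log2 variance ≈ tau² + sigma²) is asserted on the truth record's
  pre-TPM log2 matrix, because any within-sample normalization adds a
  compositional per-sample offset that is not part of the generative
  statement.

What a green recovery test establishes: the pipeline's operations compose
correctly and the estimator finds planted structure of the stated size. What
it does not establish: robustness to batch effects across laboratories,
protocol mixtures, breed structure, annotation incompleteness, or
non-log-normal expression — none of which the generator models.

# Numerical choices and degenerate inputs

* Even-length medians: arithmetic mean of the two central values.
* Missing values are rejected outright; absent genes must be explicit zero
  rows (absence-of-information is a display concern, not a data state).
* Constant signature vectors are an error naming the offending cancer type
  (their correlation is undefined); constant gene rows z-score to zero with
  a warning; constant variables are dropped before PCA with a warning.
* Fewer than three retained genes abort a differential comparison (a
  standard deviation over two fold changes is not a meaningful scale).
* All stochastic entry points (`generate_cohort`, `horn_k`, `umap_embed`)
  take a mandatory seed and restore the caller's RNG state.

# Known limitations

The inhibition ratio and infiltrate scores inherit every caveat of marker
averaging on bulk data: they proxy cell abundance only as well as the marker
lists do, and lymphoid cancers inflate their own lineage scores. The
differential-expression score ranks but does not control error (see above).
Pearson-distance clustering of 4-long vectors is tolerated noise-aware, not
endorsed. Cross-species conclusions rest on the assumption that gene symbols
were correctly matched between species upstream — the package requires
pre-harmonized identifiers and does not attempt ortholog mapping.
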