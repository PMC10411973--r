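---
title: "Methods: composition and pseudo-bulk DE for scRNA-seq cohorts"
author: "gliastate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition and pseudo-bulk DE for scRNA-seq cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliastate)
```

# The analysis this package implements

The workflow targets droplet scRNA-seq cohorts in which several animals
per genotype group are profiled and the questions are (a) does a
genotype change the *composition* of the tissue — e.g. an expansion of
infiltrating T-cells — and (b) does it change *gene expression within a
cell type* — e.g. immediate-early-gene induction in microglia. Both
questions are answered per animal: cells are never treated as
independent replicates. The stages are per-cell QC, median-ratio
normalization, clustering and marker annotation, per-animal cellularity
statistics, pseudo-bulk aggregation, and moderated differential
expression, with a bulk RNA-seq signature layer (nRPKM, gene-set
scores, z-score matrices) sharing the same scoring conventions.

# QC and normalization

A cell is removed iff its total UMI count is strictly below 1000 or its
mitochondrial UMI fraction strictly exceeds 10%. Both comparisons are
strict by a literal reading of the rule, so a cell at exactly 1000 UMIs
or exactly 10% mitochondrial content survives; the boundary behavior is
pinned by tests. Mitochondrial genes are recognized by the
case-insensitive `mt-` symbol prefix (the mouse convention); the list
is overridable because annotation sources differ.

Normalization divides each gene's count in cell $c$ by
$f_c = n_c / \operatorname{median}_{c'}(n_{c'})$, where $n_c$ is the
cell's total. Every normalized column then sums to the median library
size. The median of an even number of cells is the mean of the central
pair — the conventional sample median. Factors are computed on
QC-surviving cells only, since filtering precedes normalization in the
workflow's order. Genes are never filtered at this stage; gene-level
filters belong to HVG selection and the DE expression filter.

# Clustering and annotation

Highly variable genes are ranked by the dispersion
(variance over mean) of $\log_2(\text{nUMI}+1)$, z-scored within 20
equal-count bins of mean expression so that expression level does not
dominate the ranking. The statistic is deterministic; ties break by
gene identifier. PCA runs on centered, unit-scaled log expression of
the selected genes, with each component's sign fixed so its
largest-magnitude loading is positive (removing the eigenvector sign
ambiguity). Clustering builds a k-nearest-neighbour graph in PC space,
weights edges by the Jaccard overlap of neighbourhoods (each cell's
neighbourhood includes itself), and maximizes modularity with Louvain
under a fixed seed.

Defaults are 3000 HVGs, 30 PCs, `k = 15`, resolution 1 — the
subclustering recipe extended to the top level, since only the
subclustering parameters are standard in this workflow; all are
exposed. Two practical caveats the tests make explicit: Louvain's
resolution limit means a neighbourhood size very small relative to a
population lets it split (we use `k = 25` when asking two 200-cell
blobs to come out as exactly two clusters, and `k = 8` when a ~30-cell
doublet population must form its own community); and subclustering
caps `n_hvg` and `n_pcs` at what the subset can support.

Cluster annotation scores each marker set in each cell as the mean of
$\log_2(\text{nUMI}+1)$ over the set's genes, averages within
clusters, and assigns the argmax set name, with exact ties broken
lexicographically and flagged. Doublet-cluster flagging compares a
cluster's best and second-best marker scores: the cluster is flagged
when the runner-up comes within a margin of the winner, the signature
of a cluster co-expressing two disjoint type programs. The default
margin is a quarter of the best score's excess over that set's
*minimum* across clusters. We use the minimum, not the median, as the
background reference: when a marker program is genuinely expressed in
half the clusters (one pure cluster plus one doublet cluster out of
three, say) the median sits at the expressed level and the excess
collapses to zero, so a median-referenced rule can never flag the very
case it exists for. Flagging is off by default and manual cluster
exclusion is always available, mirroring how doublet clusters are
identified by inspection in practice.

Reference mapping (for, e.g., deciding that an unknown immune cluster
is dendritic-like) Spearman-correlates a cluster's mean log profile
against each column of a type-by-gene compendium over shared genes
(at least 10 required); constant columns give an undefined correlation
and are reported as missing, never selected.

# Composition statistics

Cellularity tables count cells per (animal, cell type) and report
percentages of the animal's total, or of a parent lineage when
subtypes are analyzed; zero-count combinations are kept so every
animal enters every comparison. Group differences use the Welch
(unequal-variance) t-test on per-animal percentages — the default
t-test of the plotting convention the workflow follows, which does not
assume pooled variance. No correction is applied across cell types
because results are reported per comparison, as in the figures this
mirrors. Degenerate inputs follow fixed conventions: both groups
constant and equal gives $t = 0, p = 1$; constant but unequal is
reported as undefined rather than infinite. Boxplot summaries use
type-7 quartiles as hinges and whiskers at the most extreme data
values within $1.5 \times \mathrm{IQR}$, with points beyond listed as
outliers.

# Pseudo-bulk differential expression

Raw UMIs (never normalized values) are summed over all cells of each
(sample, cell type); pairs with fewer than 10 cells are dropped —
strictly fewer, so exactly 10 is kept. Each cell type is analyzed
independently with a two-group intercept design; the expression filter
keeps genes with at least 10 UMIs in at least three analyzed columns
(inclusive, per "at least").

Size factors are median-of-ratios: for genes positive in every column,
the factor of column $j$ is the median over genes of
$B_{gj} / (\prod_k B_{gk})^{1/m}$. The median is taken on the ratio
scale, matching the formula as stated; this coincides with the
log-scale convention of the standard tool whenever the gene count is
odd, and differs only in the interpolation of an even-count median
(the cross-check test uses an odd count to make the comparison exact).
Factors are not rescaled to unit geometric mean afterwards, matching
the reference behavior.

Precision weights follow the mean-variance modeling approach for
count data: $\log_2$-CPM with a 0.5 pseudo-count,
$y_{gj} = \log_2\!\big((B_{gj}+0.5)/(\tilde N_j + 1)\times 10^6\big)$,
where the effective library size $\tilde N_j$ is proportional to the
size factors, rescaled to preserve the geometric-mean library size —
so the depth estimate used for CPM is consistent with the
normalization already applied to $B$. Gene-wise linear models give
residual SDs; a LOWESS curve (span 0.5, the reference default) of
$\sqrt{\text{SD}}$ against mean log count is interpolated at each
observation's fitted log count, and the weight is the predicted SD to
the power $-4$ (inverse predicted variance).

The moderated fit is gene-wise weighted least squares with
empirical-Bayes shrinkage of the residual variances toward a
scaled-F prior $(d_0, s_0^2)$, estimated by moment-matching the log
variances through digamma/trigamma identities with Newton inversion of
the trigamma function. The posterior variance is
$(d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and the moderated $t$ carries
$d_0 + d$ degrees of freedom. When the trigamma equation has no
positive root the prior degrees of freedom are infinite and all
variances shrink fully to $s_0^2$; setting the prior df to zero
recovers the ordinary WLS t exactly, which the tests use as an oracle.
Benjamini–Hochberg adjustment is applied within each (cell type,
contrast) gene list — the workflow reports per-cell-type DEG counts, so
each list is its own family. A DEG requires $q < 0.01$ *and*
$|\log_2\text{FC}| > 1.5$, both strict, so boundary genes are excluded.

# Bulk signature layer

nRPKM is size-factor-normalized RPKM:
$\text{nRPKM}_{gj} = B_{gj} / s_j / (L_g/10^3) / (D/10^6)$ with $D$
the median size-factor-corrected column total. (The originating
definition lives in prior work; this formula is this package's
documented stand-in, reducing to classic RPKM at unit factors and
equal totals.) Gene-set scores average $\log_2(\text{nRPKM}+1)$ over
the set. Heatmap matrices floor $\log_2(\text{nRPKM})$ at a
configurable value (default $-4$) — which also resolves the $-\infty$
of zero counts — then z-score each gene across samples with the
sample SD ($\text{ddof}=1$); constant genes get zero rows and a flag.
The floor default is a package choice, explicit and overridable, not
an inherited constant. Top heatmap genes are chosen by mean z-score
within a designated reference sample group, descending, ties by gene
identifier.

# The synthetic-data generator

The generator emulates the study design the analysis assumes: several
genotype groups with a few animals each, ~10 cell types dominated by
glia, a target of 10,000 cells per animal (scaled fixtures use
120–5000), log-normal library sizes (default $\sigma = 0.3$) around a
mean UMI count, and negative-binomial gene counts with mean $\mu$ and
variance $\mu + \alpha\mu^2$ (default $\alpha = 0.1$), the standard
RNA-seq parameterization. Each cell type gets a disjoint marker block
with an elevated mean (default 8-fold); mitochondrial mass (default 5%
of UMIs) is split over `mt-`-prefixed genes; composition effects
multiply a type's baseline proportion in a group before
renormalization; DE effects multiply specific genes' means in one
(group, cell type). Optional Dirichlet overdispersion on per-animal
proportions and pairwise-sum doublet injection exercise the
corresponding analysis features. The generator's truth object carries
every planted fact, and synthetic analogues of the scored modules
(disease-associated, homeostatic, immediate-early, MHC-II-like) are
carved from the marker blocks so the scoring code runs end-to-end.

What it does *not* emulate — ambient RNA, batch effects, UMI
collision, read-level artifacts, cell-cycle structure, continuous
lineages — bounds what green tests show: they validate the
*statistical contracts* of the pipeline on data satisfying its
assumptions, not robustness to every artifact of real tissue.

# Numerical choices and degenerate inputs

* Even-count medians are the mean of the central pair everywhere.
* Normalization requires positive cell totals; zero-total cells are an
  error at that stage (they are flagged, fraction 0, by the QC report).
* HVG selection errors when no gene varies or when more genes are
  requested than vary; bins with fewer than two genes get z-score 0.
* Ties: annotation ties break lexicographically with a flag; gene
  rankings tie-break by identifier; BH keeps original order stability.
* All stochastic steps (simulation, Louvain) consume explicit seeds;
  identical configuration and seed reproduce byte-identical outputs.

# Problem sizes in the tests

Test fixtures use 120–400 cells per sample with 150–300 genes, chosen
so clustering and DE retain clear planted signal at small scale;
calibration simulations use the sizes natural for the questions they
ask (2000 genes × 12 pseudo-bulk columns for DE null/recovery; 20
replicate cohorts of 4800–60,000 cells for composition null/power).
The acceptance script reruns the same computations from scratch at
those sizes and reports sensitivity, false-discovery proportion,
calibration rates, clustering agreement (ARI), and the end-to-end
findings.

# Known limitations

* Composition tests are plain Welch t-tests on percentages — no
  compositional transforms or mixed models; with very few animals per
  group the normal approximation is rough.
* One design per two-group contrast; no covariates, random effects or
  duplicate-correlation handling.
* The DE path assumes pseudo-bulks behave like bulk libraries; very
  small columns (near the 10-cell floor) are noisier than their
  weights acknowledge.
* Louvain's resolution behavior depends on `k`; cluster counts are not
  comparable across parameter settings, which is why planted-truth
  agreement (ARI), not cluster count, is the tested quantity.
* Embeddings (tSNE/UMAP) are deliberately out of scope; all
  quantitative claims flow through cluster labels.
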