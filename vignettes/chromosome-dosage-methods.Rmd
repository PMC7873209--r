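---
title: "Methods: chromosome-element expression ratios, permutation inference, and territory geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-element expression ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaratio)
```

## The scientific problem

Male *Drosophila* carry a single X. Somatic cells equalize X output against
the paired autosomes by dosage compensation, so the expression of the X
relative to the major autosomes sits near parity. Whether germ cells
compensate — and whether primary spermatocytes instead *inactivate* the X
(meiotic sex chromosome inactivation, MSCI) — is read out from single-cell
RNA-seq of the larval testis as a per-cell ratio:

\[
R_c \;=\; \frac{\sum_{g \in S \cap X} \mathrm{cpm}_{gc} \,/\, |S \cap X|}
               {\sum_{g \in S \cap A} \mathrm{cpm}_{gc} \,/\, |S \cap A|}
\]

where $A$ is the set of major autosomal arms (2L, 2R, 3L, 3R) and $S$ an
active gene set. The same ratio with the dot 4th chromosome as the focal
element probes whether the 4th is co-regulated with the X. Three regimes
anchor interpretation: $R \approx 1$ under full compensation, $R \approx
0.5$ under no compensation or inactivation of one of two expected doses,
and intermediate values during the transition.

Two design choices in the ratio matter:

* **Gene-count normalization by set size.** The denominators $|S \cap X|$
  and $|S \cap A|$ are the sizes of the gene-set intersections, not the
  number of genes detected in the cell. This makes the normalization vary
  with the active gene set (all expressed genes vs a housekeeping subset)
  and keeps the estimator unbiased by per-cell dropout.
* **Depth invariance.** $R_c$ is a ratio of within-cell quantities, so any
  per-cell scaling (library size, cpm normalization) cancels exactly; this
  is tested as an exact identity.

"TPM" for 3' UMI single-cell data is implemented as counts-per-million:
UMI counts are not length-proportional, so a length term would be wrong.
Bulk libraries use conventional length-normalized TPM (counts divided by
gene length in kb, then scaled to $10^6$), with union-exon-style lengths
carried in the annotation.

## Housekeeping gene sets

Testis expression is dominated by specialist genes, so chromosome-wide
claims need gene sets with "housekeeping" character:

* **Tau** on an adult multi-tissue panel: tissue means of
  $\log_2(\mathrm{TPM}+1)$, rescaled by the per-gene maximum;
  $\tau = \sum_i (1-\hat x_i)/(N-1)$; membership at $\tau \le 0.5$. The
  log transform is the common convention for Tau; a linear mode is
  provided.
* **TSPS**: the relative entropy of the linear tissue-mean shares against
  a uniform profile, $\sum_i p_i \log_2(p_i N)$ bits; membership at
  $\mathrm{TSPS} \le 1$. Exactly scale-invariant by construction.
* **CTSP**, the cell-level criterion: genes detected (count > 0) in at
  least a third of QC-passing cells. The most stringent of the three and
  the one that best isolates widely expressed genes within the tissue
  itself.

Tissue means pool the sexes by default (the sets describe breadth across
tissues, not sex bias); a per-sex analysis can be run by subsetting the
panel. Genes with no adult expression have undefined Tau/TSPS and are
reported `NA`, never coerced to a membership.

## Cell-level permutation inference

Per-cell measures are sparse and not identically distributed, so simple
count aggregation across cells is avoided; inference runs at the cell
level. For a pairwise comparison of two cell types, the observed
Mann-Whitney U (midrank ties) is compared against U recomputed under
`n_iter` random permutations of the pooled type labels; the reported
p-value is the add-one estimator
$(1 + \#\{|U_\pi - E[U]| \ge |U_{obs} - E[U]|\})/(n_{iter}+1)$, two-sided
on the distance from $E[U] = n_a n_b / 2$ (the paper-style procedure does
not fix a sidedness; one-sided options are exposed). The add-one form
guarantees $p \ge 1/(n_{iter}+1)$ and exact validity.

For the comparison of one cell type against the experiment, each iteration
draws a uniform random sample of the same size from all cells and runs the
U test; the result is the fraction of iterations significant at
$\alpha$ (default 0.01). The source procedure aggregates these
iterations into "the average number of times the observed distribution was
significantly different" — a proportion rather than a conventional
p-value — so this package reports the significant fraction explicitly and
makes the overall call at a configurable decision threshold (default
0.95), documented rather than asserted as the original authors' exact
rule.

Supporting statistics are delegated to base R behind stable surfaces:
`wilcox.test` (exact when $\min(n) \le 8$ without ties, otherwise the
tie- and continuity-corrected normal approximation), `p.adjust("BH")`,
`chisq.test(correct = FALSE)`, with percentile bootstrap CIs of the mean
implemented directly. Permutation loops use a pre-ranked fast path (ranks
are invariant under label permutation), which is what keeps 10,000
iterations cheap.

## Multiplet screening

**Homotypic multiplets** ride the top of the expressed-genes-per-cell
distribution, but a hard cap risks discarding high-content cell types. The
grid search drops cells above each candidate threshold, re-clusters the
remainder (log1p(cpm), 2,000 most variable genes, PCA, k-nearest-neighbour
graph, Louvain modularity at resolution 0.3), and compares labelings by
adjusted Rand index on the cells retained at every threshold. "Does not
drastically change clustering" is operationalized as ARI at least
`stability` (default 0.95) against the most permissive threshold — the
reference choice is exposed as an option. This rule is explicit, monotone
in `stability` (tested), and reproducible.

**Heterotypic multiplets** look like intermediate cell types. For every
unordered pair of clusters and mixing fraction, a mixture profile is
formed from the clusters' mean cpm profiles *in linear space* — a doublet
is a sum of two cells' counts, so log-space averaging would place the
mixture far from any real doublet — and compared on the log1p scale. A
cell is flagged when its best Pearson correlation to a mixture beats its
best correlation to a pure centroid. One subtlety: doublets numerous
enough to earn their own cluster would hide behind their own centroid, so
with three or more clusters the centroids themselves are screened first,
and clusters better explained as mixtures of two other clusters are
excluded from the pure reference set. On injected 50:50 doublets between
two well-separated synthetic types this recalls essentially all doublets
at zero singlet false-positive rate; margins tighten as types become more
similar.

## Per-cell gene-set enrichment

The per-cell enrichment score is the classic weighted Kolmogorov-Smirnov
running sum over the cell's expression ranking (ties broken by gene id):
hits advance by $|x|^w$ normalized to 1, misses by $1/(N-|S|)$, and the
score is the signed maximum deviation, bounded in $[-1, 1]$. Default
weight 1 (canonical weighted form); weight 0 gives the unweighted KS
statistic. The implementation is checked against a brute-force running-sum
oracle on small instances for both weights.

## Bulk per-arm sex bias

For each chromosome element and sample: summed TPM of the element's
expressed genes divided by the number of expressed genes on that arm. Per
element, each sex's mean gets a percentile bootstrap CI; male vs female is
a Welch t-test across replicates, BH-corrected across elements, and an
element is called male-reduced at $q \le 0.01$ with male < female.
Sex-bias class labels (male / female / unbiased per gene) are consumed as
input — differential-expression calling belongs to dedicated tools — and
tabulated per element for a Pearson chi-squared test of independence.

## Territory geometry

Chromosome territories arrive as binary voxel masks (multi-page TIFF or
coordinate TSV) with physical voxel sizes, including anisotropic z.

* **Volume** is occupied voxels times voxel volume.
* **Surface area** uses the co-area formula on a Gaussian-smoothed
  indicator: $A = \sum |\nabla u| \cdot v_{voxel}$, with gradients in
  physical units. Voxel-face counting was rejected because it
  systematically overestimates area and deflates sphericity; the
  smoothed-gradient estimator is within a few percent of analytic values
  for digitized balls of radius $\ge 10$ voxels (tested against spheres
  and ellipsoids). The smoothing bandwidth defaults to the smallest voxel
  size.
* **Sphericity** $\psi = \pi^{1/3}(6V)^{2/3}/A$ equals 1 for a sphere and
  decreases with elongation; measured $\psi$ stays within 0.02 of 1 for
  digitized balls (discretization bound, tested).
* **Probe corrections**: volumes are reported per Mb of probe span and,
  separately, further divided by copy number — the copy correction's
  validity is debatable, so corrected and uncorrected values are always
  emitted side by side.
* **Distances**: minimum Euclidean distance from the boundary voxels of a
  probe mask ("outer probe edge") to any voxel of a reference mask
  (e.g. the nucleolus); zero when masks touch.
* **Intensity ratios**: per territory, integrated (signal − mean
  background) over integrated (total − mean background), then log2 of the
  focal quotient against the mean autosomal quotient. Non-positive
  denominators after background subtraction are reported missing, not
  clamped.

The published fluorescence values for real spermatocyte nuclei derive from
unreleased image data; only the formulas and synthetic-shape behavior are
testable here.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the statistical
structure the analysis assumes so every stage is testable without external
data.

* **Layout**: elements X (200 genes, 1 copy), Y (12, 1), 2L/2R/3L/3R (250
  each, 2), 4th (30, 2); ten cell types in two lineages with the relative
  abundances of a larval testis atlas scaled to 8,000 cells.
* **Dosage regimes** (per-copy multipliers $m_{e,t}$): X at 2.0 in somatic
  types and spermatogonia, decaying 1.4 / 1.1 / 1.0 through E1 / M1 / L1 —
  somatic compensation, germline transition, spermatocyte inactivation;
  4th at 1.0 except 0.85 in M1/L1; Y at 0.05 in soma, 0.3 in G, 1.0 in
  spermatocytes; majors fixed at 1 (the reference). The intermediate E1/M1
  levels are not quantified anywhere and are exposed as plain config
  values.
* **Expression program**: per-gene log-normal base rates ($\mu_0 = 0$,
  $\sigma_0 = 1$); 30% of each autosomal element's genes and 25% of X
  genes are broad (expressed in all types); Y has none. Restricted genes
  are single-type markers with a log-normal fold boost (median 4). Two
  consequences are intentional: markers give community detection a crisp
  signal, and no restricted gene can reach the CTSP detection bar, because
  the largest cell type holds 24% of cells — so the CTSP set coincides
  with the broad class, as a housekeeping criterion should.
* **Standardization**: base rates are standardized to mean 1 within each
  (element x breadth class x cell type) stratum, making the configured
  dosage multipliers the *only* systematic driver of element-level
  ratios. Without this, sampling variation in which genes happen to be
  active would perturb the expected ratios by several percent and the
  generator's truth would not be the documented truth.
* **Counts**: within-cell rates are normalized and scaled by a log-normal
  library size (median 5,000 UMI, sdlog 0.3), then drawn negative binomial
  with dispersion 10 (Poisson available) — realistic overdispersion
  without zero-inflation machinery.
* **Doublets**: appended barcodes summing two real cells, optionally
  forced homotypic or heterotypic; truth records both constituents.
* **Bulk panel**: same gene layout; broad genes everywhere with mild
  tissue jitter, restricted genes in 1-2 tissues, optional intrinsic
  sex-biased fold changes and per-element male multipliers (e.g. a halved
  male X); read rates are proportional to expression times length so
  length-TPM recovers expression. One replicate set per run;
  multi-replicate integration is out of scope.

What the generator does **not** emulate: ambient RNA, batch effects,
cell-cycle structure, spliced/unspliced counts, empty droplets, or
sequence-level features. Passing tests therefore demonstrate that the
pipeline recovers known dosage structure from overdispersed sparse counts
with realistic cell-type composition — not that it is robust to every
artifact of real droplet data.

## Numerical conventions and problem sizes

Quartiles use linear interpolation (R type 7), so the documented IQR
examples are exact; the notch CI of the median is
$\mathrm{median} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$. All randomness flows
from explicit integer seeds (config seed for generation; per-call seeds
for permutation, bootstrap, clustering), and identical inputs give
byte-identical outputs.

The test suite and the reproduction script run at desk scale by design:
the default dataset is 8,000 cells x 1,242 genes; permutation calibration
uses 500 null datasets of 400 cells at 2,000 iterations; the QC recovery
scenarios use 1,200-1,500 cells (the grid-search one on a gene-rich,
shallower 9,936-gene configuration where detected-gene counts are
informative about doublets). These sizes give stable medians and
calibration estimates while keeping a full run in about a minute.

## Known limitations

* The CTSP criterion selects on detection, which interacts with dosage: in
  late spermatocytes, weakly expressed broad X genes fall below the
  detection bar slightly more often than autosomal ones, biasing the L1
  CTSP X:A ratio upward by a few hundredths at the default depth. This is
  a property of the criterion itself (the same selection acts on real
  data) and is left visible rather than corrected.
* The in-silico mixing screen assumes cluster centroids approximate pure
  cell types; continuous differentiation trajectories blur that
  assumption, and margins should be chosen conservatively there.
* The surface-area estimator is first-order in voxel size; shapes thinner
  than ~3 voxels or sharp edges (cubes) are smoothed, biasing their area
  low and sphericity high. Territory masks at typical confocal resolution
  are well inside the validated regime.
* Differential-expression calling for sex-bias labels is consumed as
  input; the built-in Welch t-test fallback is a stand-in for a dedicated
  DE tool, not a replacement.
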