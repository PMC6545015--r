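---
title: "Inferring chromosomal instability and copy-number-independent expression from single-cell RNA-seq"
author: "cinsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosomal instability and copy-number-independent expression from single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinsight)
```

# Overview

Chromosomally unstable (CIN) tumor cells mis-segregate whole chromosomes at
a persistently high rate, so every cell in the population can carry a
different karyotype. Because transcription scales, for most genes, with gene
dosage, these karyotype fluctuations translate into cell-to-cell expression
heterogeneity. `cinsight` implements a complete expression-based workflow for
studying this phenomenon when only single-cell RNA-seq is available:

1. **QC and normalization** of a gene-by-cell count matrix containing a
   diploid *reference* population and a *test* population.
2. **Copy-number inference**: per-cell estimated copy number (ECN) from
   sliding-window averages of relative expression against the diploid
   reference, plus a per-cell **chromosomal instability index**.
3. **Copy-number-adjusted differential expression**: a per-gene logistic
   model that separates differential expression explained by copy number
   from differential expression that is independent of it.
4. **CI signature scoring** of bulk cohorts with the binary weight profiles
   built from the copy-number-independent genes, followed by grade and
   survival association (ANOVA, chi-square, Kaplan-Meier, log-rank, Cox).
5. A **synthetic-data generator** with known karyotypes, known
   dosage-buffered genes and known survival structure, which is the
   package's acceptance surface.

# Copy-number inference from expression

## Relative expression

Normalized expression is compared against a diploid reference profile: the
per-gene geometric mean over reference cells, computed with a pseudocount
(default 1) so zeros are admissible,

$$\mathrm{profile}_g = \exp\Big(\tfrac1{n_\mathrm{ref}}\sum_k
  \ln(\mathrm{norm}_{gk} + c)\Big).$$

Relative expression is the log2 ratio
$X_{gk} = \log_2(\mathrm{norm}_{gk} + c) - \log_2(\mathrm{profile}_g)$,
median-centered per cell. Median centering makes the per-cell median of
$X$ exactly 0: a uniform scaling of a whole cell is absorbed, and — as long
as most of the genome is unaltered — the diploid state sits at $X = 0$.
A consequence worth knowing: a cell at exactly twice the reference on
*every* gene is indistinguishable from diploid (the global shift is
centered away). Whole-genome doublings are invisible to this method by
design; it measures *relative* chromosome-scale imbalance.

## Sliding windows and zero-forcing

With genes arranged by chromosome and coordinate, the estimated copy number
of gene $i$ in cell $k$ averages relative expression over the gene and its
$r$ = 50 upstream and 50 downstream neighbors:

$$ECN_k(i) = \frac{\sum_{j=i-r}^{i+r} X_k(j)}{2r + 1}.$$

Numerical choices:

* **Windows never cross chromosome boundaries** — copy number is a
  chromosome-level property. Near chromosome ends the window truncates and
  the denominator is the actual neighbor count, so end genes are unbiased
  (at the price of higher variance) rather than shrunk toward 0.
* **Zero-forcing**: entries with $|ECN| <$ 0.5 are set to exactly 0, so
  ECN = 0 reads as "diploid expression level". The dead-zone default of
  0.5 on the log2 scale is half-way between diploid (0) and a
  single-chromosome gain from two to four copies (+1); it suppresses window
  noise while passing whole-chromosome gains/losses, whose expected
  magnitudes are $|\log_2(r_\mathrm{copy})| \ge 0.58$ for any single-copy
  change from diploid. The threshold is configurable.
* Mitochondrial genes (and any genes on unplaced contigs flagged as such)
  are excluded from windows.

On simulated whole-chromosome events the window estimator recovers log2
dosage closely: a chromosome at 4 copies (base 2) sits near mean ECN +1 and
one at 1 copy near −1; the residual deviation (typically under 0.1) comes
from the pseudocount and from Jensen-type compression of log ratios at
finite counts.

## Chromosomal instability index and chromosome calls

The per-cell chromosomal instability index is the mean absolute ECN over
all genes used,

$$\mathrm{CIN}_k = \frac{\sum_{i=1}^{n} |ECN_k(i)|}{n},$$

zero exactly when the cell's whole profile is diploid after zero-forcing.
Chromosome-level gain/loss calls average ECN per (cell, chromosome) and
apply a symmetric cutoff (default 0.25, half the dead-zone; the cutoff is a
package choice — no canonical value exists).

## The shuffle control

`shuffleGenePositions()` permutes the gene-to-position map over the same
position set. After shuffling, a gene's expression is unrelated to its
neighbors', so window averages collapse toward each cell's global mean and
are almost entirely zero-forced; both the chromosome-scale block structure
(lag-1 autocorrelation of ECN along the genome) and the CIN-index
difference between populations should disappear. This is the package's
negative control for "the signal is positional, not expression-level".
The control behaves as intended only after low-abundance genes are
filtered out (see below): very lowly expressed genes have log-ratio
outliers that would otherwise leak through the dead-zone.

# QC and normalization

The QC stage mirrors standard practice for plate/microfluidics single-cell
data, with every threshold computed on the robust MAD scale
(`stats::mad`, 1.4826 consistency constant):

1. **Cell QC**: remove cells with library size below
   median − 3·MAD, or mitochondrial fraction above median + 3·MAD, both on
   the pre-filter distribution (filters are applied once, not iterated).
2. **Normalization**: size factors scaled to mean 1; `libsize` (total
   counts), `median_ratio` (median ratio to the per-gene geometric mean,
   robust to a minority of DE genes), or `external` for factors computed by
   any other tool (e.g. pooled deconvolution). Size-factor methods that
   couple cells through the mean-1 rescaling leave relative expression —
   the input to all downstream steps — unchanged.
3. **Gene filter**: genes whose mean normalized expression lies at or
   below the 70th percentile of per-gene means are dropped
   (nearest-rank percentile; ~30% of the universe is retained). Beyond
   noise reduction, this filter is what keeps window estimates and the
   shuffle control clean.
4. **Second cell filter**, over the retained genes only: cells with a
   normalized library size below an absolute cutoff (or median − 2·MAD in
   the default "auto" mode) or expressing fewer than 75% of the retained
   genes are removed.

Gene order is never changed, so genomic ordering is preserved for the
window stage.

# Copy-number-adjusted differential expression

Unadjusted differential expression uses a two-sided Mann-Whitney U test per
gene (exact for group sizes up to 20, tie-corrected normal approximation
otherwise), a Welch t statistic, the log2 fold change of group means, and
Bonferroni correction across genes; significance means corrected p < 0.05.

For the adjustment, every gene gets a logistic regression of the cell label
(1 = test population) on two predictors:

$$\mathrm{logit}\,P(Y=1) = \beta_0 + \beta_1\,\mathrm{exp} +
  \beta_2\,\mathrm{CNV},$$

where `exp` is the gene's log2(normalized + 1) expression standardized
across cells, and `CNV` is the per-cell ECN of that gene — estimated by the
windows where available and otherwise **imputed** from the nearest flanking
genes with estimates on the same chromosome (one-sided nearest at
chromosome ends; genes on chromosomes with no estimates are excluded with a
flag). A significant $\beta_1$ means expression separates the populations
*given* copy number: the copy-number-independent component. Genes
significant before adjustment but not after are classified
copy-number-dependent; direction (up/down) comes from the sign of
$\beta_1$.

Numerical choices:

* Expression is standardized per gene so $\beta_1$ is comparable across
  genes and fits are stable; the scale of the expression predictor is a
  package choice.
* $\beta_1$ is tested by its Wald z by default (the conventional GLM
  output); a likelihood-ratio test is available by configuration.
* **Separation**: single-gene logistic fits on strongly separated data do
  not converge. Such fits (detected from glm warnings, runaway
  coefficients or exploding standard errors) are refit with a small L2
  penalty, $\lambda = 1/(2 n_\mathrm{cells})$, and flagged. For these
  refits $\beta_1$ is tested with a penalized likelihood ratio rather than
  a Wald test: under separation the penalized information matrix is
  dominated by the penalty itself, so a Wald z shrinks toward 0 for
  arbitrarily strong genes, whereas the deviance difference between the
  penalized fits with and without the expression term remains informative.
* The Wald test has a power optimum at moderate effects (the
  Hauck–Donner effect: its z statistic eventually *decreases* as group
  separation grows). This is a property of the per-gene model, inherited
  by the classifier, and is the reason the recovery simulations plant
  ~2-fold effects rather than extreme ones.
* Constant-expression genes are skipped with a flag; a constant (e.g.
  all-zero) ECN column is dropped from the model, which then degenerates
  to the unadjusted single-predictor logistic fit.

# CI signature and cohort scoring

The copy-number-independent genes define binary weight profiles: up genes
get $w^+_i = 1$, down genes $w^-_i = 1$, everything else 0. Two scoring
methods are implemented because the integration step has no canonical
formula:

* `meanz` (default, deterministic): z-score each gene across the cohort;
  a sample's score is the mean z over $w^+$ genes minus the mean z over
  $w^-$ genes. Shift-invariant per gene, antisymmetric under swapping the
  profiles, monotone in any $w^+$ gene.
* `rank_es`: per sample, genes are ranked by expression and the score is
  the running-sum enrichment statistic (maximum lead of the cumulative
  signature-gene fraction over the background fraction) for $w^+$ minus
  that for $w^-$ — a rank-based analogue of weighted signature-projection
  methods, not a replication of any specific one.

Both methods order noise-free monotone data identically. Signature genes
missing from a cohort's platform are dropped with a warning, not imputed.
Samples are dichotomized at the cohort median score (CI-Hi above, CI-Lo at
or below — ties deterministically conservative for the Hi group).

Clinical association uses one-way ANOVA of score across grade strata,
Pearson chi-square on the CI-group × grade table, and survival analysis
with a univariate Cox model (CI-Lo reference, Breslow tie handling —
differences from Efron are negligible at these cohort scales), Wald 95% CI
for the hazard ratio, a two-group log-rank test, and Kaplan-Meier curves
with at-risk counts. Samples missing clinical fields are dropped per
analysis with a logged count.

# The synthetic-data generator

The generator provides ground truth for every downstream stage. Per cell,
whole chromosomes deviate from base ploidy (±1 copy, independently across
cells and chromosomes) with a configurable mis-segregation probability;
optional clonal events put a shared aneuploidy (e.g. chr1 at 4 copies) into
a fraction of the test population, emulating the clonal gains/losses that
dominate real tumor lines. Counts are negative binomial: the expected
expression of a non-buffered gene scales with the copy ratio, times a
log-normal per-cell size factor, times $2^{\mathrm{effect}}$ for planted
group effects in test cells. **Buffered genes ignore copy number
entirely** — they model dosage compensation, and planted group effects on
buffered genes are the ground-truth copy-number-independent DE set.
Mitochondrial genes sit on a dedicated pseudo-chromosome at constant
ploidy, excluded from windows.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| baseline mean | log-normal, meanlog 3, sdlog 1 | median ≈ 20 counts/cell, plate-data scale |
| dispersion (NB size) | 10 | extra CV² ≈ 0.3 at moderate expression, typical for full-length protocols |
| dropout | 0.5 at zero mean, decay 0.3/count | zero inflation is strongly mean-dependent in real data; with these values extra zeros are confined to genes under ~15 counts and essentially never hit well-expressed genes |
| library-size sdlog | 0.2 | ±20% cell-to-cell depth variation after QC |
| buffered fraction | 0.2 | consistent with reports that 10–30% of genes on aneuploid chromosomes are dosage-compensated |
| mis-segregation rate | 0.3/chromosome | no measured rate exists for the motivating cell line; chosen for clearly aneuploid, heterogeneous karyotypes and test power |
| planted group effects | ±1.2 log2 (~2.3-fold) | realistic strong markers for cell-line contrasts; within the Wald test's power optimum |

What the generator does **not** emulate: doublets, ambient RNA, UMI
structure, focal (sub-chromosomal) CNVs, batch effects, cell-cycle
covariation, or realistic gene names and chromosome lengths. Passing tests
demonstrate parameter recovery under the stated generative model — whole
chromosome events, independent NB noise — not performance on any real
dataset.

Bulk cohorts are generated from a latent per-sample score: signature genes
shift with the score (up genes positively, down genes negatively), survival
is exponential with log-hazard −(hazard coefficient)·score with independent
exponential censoring, and grade follows score tertiles (high score → low
grade). This is the plumbing used to verify that scoring and survival
analysis recover a planted prognostic signal; it makes no claim of
emulating any particular cohort beyond its size.

# Problem sizes used by the test suite

The test and verification suites run the pipeline at these scales, chosen
to keep every check well-powered while remaining quick to run:

* window-oracle equivalence: 50 random 200-gene × 20-cell matrices;
* dosage recovery: 10 chromosomes × 150 genes, 100 + 100 cells,
  no dropout, 4-copy and 1-copy clonal chromosomes;
* CIN-index separation and shuffle control: 22 chromosomes × 300 genes
  (~6,600 genes, the scale of a filtered single-cell study), 50 + 50
  cells, mis-segregation rate 0.3, 100 seeded replicates, full QC;
* classification recovery: 10 × 100 genes, 60 + 60 cells, clonal chr1
  gain / chr2 loss in 80% of test cells, 100 buffered genes plus 30 up /
  20 down planted copy-number-independent genes;
* cohort recovery: 200-sample cohorts for score–latent correlation;
  500-sample cohorts for hazard-ratio recovery; 400 null replicates for
  log-rank calibration and 1,000 null genes for Mann-Whitney calibration.

# Known limitations

* ECN is *relative* copy number. A diploid reference population is
  required; using the test population itself as reference erases shared
  (clonal) events, and whole-genome ploidy shifts are invisible.
* Resolution is ~100 genes; focal events and breakpoints are out of scope
  (no HMM segmentation, no integer copy calling beyond gain/neutral/loss).
* The per-gene logistic adjustment conditions on *estimated* copy number;
  when the window estimate is noisy, residual dosage signal can leak into
  the copy-number-independent class. Simulations bound this leakage under
  the generative model only.
* Bonferroni correction is deliberately conservative, matching the
  upstream analysis convention; alternative corrections are a config hook,
  not a default.
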