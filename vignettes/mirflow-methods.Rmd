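---
title: "mirflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflow)
```

## What the package computes

`mirflow` is a self-contained pipeline for circulating (serum) microRNA
profiling by small RNA sequencing, of the kind used to compare miRNA
expression between groups of older adults differing in physical activity and
cardiovascular risk. It covers five analysis stages plus a synthetic-data
generator that makes every stage testable against known truth:

1. **Quantification** — adapter removal, a 15-nt length filter, collapsing of
   identical reads, mapping to miRNA precursor sequences, 5p/3p arm
   assignment by the precursor-half rule, and fractional (1/N) counting of
   multi-mapping reads.
2. **Filtering and normalization** — an expression filter keyed to the
   smallest group, and trimmed-mean-of-M-values (TMM) scaling factors.
3. **Differential expression** — pairwise negative-binomial (NB) exact tests
   with a common dispersion estimated by quantile-adjusted conditional
   maximum likelihood (qCML), with Benjamini–Hochberg FDR control and the
   significant set taken as the union over the three pairwise comparisons.
4. **Phenotype association** — Spearman correlation of per-miRNA log-CPM
   with physiological parameters, ordered by average-linkage clustering to
   expose correlated blocks.
5. **PCA** — principal component analysis of the combined (z-scored) matrix
   of significant miRNAs and log-transformed phenotypes, with per-feature
   contribution scores and a group-separation summary on PC1.

## Quantification model

Reads are `mature sequence + 3' adapter`, sequenced single-end. Trimming
finds the leftmost full-adapter occurrence (allowing 10% of its length in
substitutions) or an adapter prefix of at least 10 nt at the read end; reads
with no adapter hit are kept whole, since a long insert can fill the read and
the length filter and mapper dispose of artifacts anyway. Inserts shorter
than 15 nt are discarded.

Mapping is substitution-only, end-to-end, against the precursor sequences
(sense strand; small-RNA libraries are stranded), with a default budget of 1
mismatch. A 7-mer seed index with the pigeonhole rule (`max_mismatches + 1`
segments, one of which must match exactly) generates candidates, which are
verified by Hamming distance; only the minimal-mismatch stratum per read is
kept. Mapping directly to precursors rather than to a whole genome is a
declared simplification: reads from non-miRNA loci are simply unmapped, and
the retained reads are exactly those on precursor loci, which are the only
ones counted downstream anyway. The mapper is oracle-tested against a
brute-force all-offsets Hamming scan.

A read hitting `N` loci contributes `1/N` to each locus; arm assignment uses
the read midpoint on the precursor (0-based): first half (ties included) is
5p, second half 3p. The tie rule is a deterministic convention; with the
generator's arm geometry (5p entirely in the first half, 3p entirely in the
second) the rule recovers the generating arm exactly, which is what makes the
count-recovery test exact.

## Filtering and TMM

A miRNA counts as expressed in a sample when
`count / median(library size) * 1e6 >= 10`. The sample quota is
`ceiling(0.7 * n_smallest)` — e.g. 26 for a smallest group of 36. The default
mode retains a miRNA when *any* group meets the quota (the `filterByExpr`
convention); a strict smallest-group-only mode is available
(`mode = "smallest-only"`). Both are shipped because the description "at
least 10 in at least 70% of the samples of the smallest group" does not
decide between them.

TMM follows the published trimmed-mean-of-M-values definition exactly:
upper-quartile-based reference selection, M/A values over genes positive in
both libraries, 30%/5% two-tail trims on M and A, inverse-asymptotic-variance
weights, factors rescaled to geometric mean 1. The implementation is checked
to 1e-10 against an independent reference implementation on random matrices.
Note one subtlety the tests document: duplicating a sample with all counts
doubled gives *exactly* the same factor only for the unweighted trimmed mean;
the default precision weights depend on absolute counts, so equality is then
approximate (still within a few percent).

log-CPM uses `log2((count + prior_j) / (efflib_j + 2 prior_j) * 1e6)` with
`prior = 2` scaled proportionally to the effective library size. The prior
lives on the count scale, so global count rescaling is exactly neutral only
at `prior = 0` and approximately neutral otherwise; tests assert both at the
level that holds.

## NB exact test and dispersion

The count model is `Var = mu + phi * mu^2`; `phi = 0` is the Poisson limit.
The common dispersion is estimated by qCML: counts are mapped to a common
library size with quantile-to-quantile NB pseudo-counts (tail-matched normal
and gamma approximations, averaged), and the conditional log-likelihood of
within-group counts given group sums is maximized over
`delta = phi / (1 + phi)` by a coarse grid plus golden-section refinement,
with one refresh of the pseudo-counts at the estimate; `phi` is clamped to
`[0, 50]`. Genes with total count below 6 are excluded from the likelihood
(they carry almost no dispersion information). Tagwise or trended shrinkage
is deliberately out of scope; this is a recorded divergence risk versus
analyses that use it.

The exact test equalizes the two groups' effective library sizes to their
arithmetic mean, rounds the group pseudo-sums, and computes a two-sided
p-value on the conditional distribution of the group-A sum given the total
(sums of i.i.d. NB variables), doubling the smaller tail with the observed
outcome included in both tails and capping at 1. For totals where both group
sums exceed 900 the enumeration switches to the continuity-corrected beta
approximation of `s1/s`, the standard large-count device; near the cutoff the
two routes agree to about 1e-4, and the enumeration route is oracle-tested to
1e-8 against brute-force convolution of per-sample pmfs. log-fold-changes use
prior-augmented group mean pseudo-counts (prior 0.125); average log-CPM uses
prior 2. Both priors are conventions of the named procedure, not estimates.

TMM factors matter here beyond cosmetics: with 10% of miRNAs shifted by
|log2FC| = 2, library sizes absorb the shift and an unnormalized exact test
shows a false-discovery proportion of ~0.3-0.5 at a nominal FDR of 0.05;
with TMM factors the observed FDP returns below the nominal target. The
recovery tests run with TMM, as the pipeline does.

## Correlation and PCA

Spearman correlations are computed on TMM log-CPM (not raw counts — ranks of
raw counts are library-size sensitive), with pairwise-complete deletion of
missing phenotype values; pairs with fewer than 3 complete observations or a
constant member are flagged `NA`, never 0. No p-values are attached — the
display is of magnitudes and block structure. Rows and columns are ordered by
average-linkage clustering on Euclidean distances of correlation profiles;
inputs are label-sorted first so the order is permutation-invariant, and
missing entries enter the distance as 0 only.

The PCA feature matrix concatenates log-CPM of the significant miRNAs with
phenotype columns, log-transforms phenotypes whose observed values are all
strictly positive, mean-imputes missing entries per column, and z-scores each
column. "Centered and scaled across both parameters and patients" is read as
standard per-feature centering/scaling of the sample-by-feature matrix; a
literal double standardization is not meaningful for PCA. Missing-value
handling (mean imputation) is a choice the original description leaves open.
Components come from the SVD with eigenvalues `d^2 / (n - 1)`; each
component's sign is fixed so its largest-magnitude loading is positive, for
backend-independent reproducibility. Contributions are
`100 * loading^2 / sum(loading^2)` per component, combined over components by
eigenvalue-weighted means.

## The synthetic cohort

The generator emulates a three-group cohort of 38/36/84 (active analog,
sedentary analog, at-risk analog), the default study condition. Counts are
`NB(s_j * mu_i * 2^eff, phi = 0.1)` with expected library sizes uniform in
1.5-2.5e5 reads (desk scale) and baseline log2 relative abundances uniform in
[-4, 10], so that, as in real serum profiles, a substantial minority of
annotated miRNAs sits below the expression filter. Differential expression is
a 13-miRNA "risk block" up in the at-risk group, a 6-miRNA "health block" up
in the active group (both drawn from the better-expressed half, as
well-characterized serum miRNAs are), plus unstructured DE up to 10% of
miRNAs at |log2FC| = 2. Phenotypes (28 parameters named and scaled after
typical cardiovascular-cohort summaries) are linear-Gaussian in a group
effect and the standardized log-latent abundances of their associated block
miRNAs; only the association *signs* are treated as ground truth, because the
downstream check is rank-based. Reads are mature + adapter truncated to 76
bases with independent per-base substitution errors (default 0.001 — a
convention, since no read-level error model is implied by the analysis being
emulated), constant quality strings (qualities are never used), and read
names that encode only sample and serial number, so no truth leaks into the
pipeline path.

What the generator does *not* emulate — isomiRs, degradation fragments,
ligation bias, UMI structure, realistic quality profiles, non-miRNA
background reads — bounds what passing tests show: they validate the
statistical pipeline and its bookkeeping, not robustness to every artifact of
real libraries.

One bookkeeping subtlety: a configurable fraction of mature sequences
(default 5%) is duplicated across two precursors. Reads from such a sequence
necessarily map to both loci and are split 0.5/0.5, so the generator exposes
both the counts as generated (`true_counts`) and their redistribution across
identical-sequence loci (`expected_counts`); an exact quantifier recovers the
latter, and the two coincide when nothing is shared.

## Numerical choices and degenerate inputs

* Ties in arm assignment go to 5p; ties in contributor ranking break on
  feature name; clustering inputs are label-sorted — all for determinism.
* Zero totals in both groups give p = 1 and logFC = 0; all-singleton groups
  abort dispersion estimation ("no replication"); a sample sharing no
  positive genes with the TMM reference aborts with a diagnostic;
  zero-variance PCA columns are dropped with a warning.
* Every run is reproducible from the design seed: reference, counts and
  reads derive their RNG streams from `seed`, `seed + 1`, `seed + 2`, and
  identical configurations produce byte-identical FASTA/GFF3/FASTQ and
  identical pipeline manifest hashes.

## Problem sizes used by the test suite

The suite validates count recovery on 12 samples of ~2e5 error-free reads
over 300 miRNAs; the mapper oracle on 200 reads against 50 precursors; the
exact-test oracle on all totals up to 60 in a 2+2 design; calibration and
recovery on 2000-gene simulations (5v5 null, 30+30 with 10% DE); and the
correlation/PCA structure on the full 158-sample default design over 10
seeds. These sizes were chosen so the whole suite runs in a few minutes on a
single core while leaving the Monte-Carlo bands meaningful.

## A worked example

```{r example, eval = FALSE}
library(mirflow)

design <- sim_design(seed = 1)           # default three-group cohort
run <- run_pipeline(pipeline_config(
  out_dir = tempfile("mirflow_run_"),
  simulate = design
))
run$summary$union_size                    # miRNAs significant in any pairwise test
run$pca$var_frac[1:2]                     # PC1/PC2 variance fractions
run$separation$accuracy                   # PC1 threshold accuracy, extreme groups
```

## Known limitations

* Common (not tagwise) dispersion: heterogeneous per-miRNA overdispersion is
  averaged, which can under- or over-state significance for outlier miRNAs.
* Precursor-space mapping cannot distinguish reads that would multi-map
  elsewhere in a genome, and does not model cross-mapping from non-miRNA
  small RNAs.
* The phenotype generator is linear-Gaussian; effect sizes are not
  calibrated to any particular cohort, so only sign recovery (not magnitude)
  is a meaningful target.
* p-values for correlations are intentionally absent; the correlation stage
  is descriptive.
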