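# mirflow

Circulating microRNAs (miRNAs) measured in serum by small RNA sequencing are
candidate biomarkers of cardiovascular health, physical activity and
metabolic risk. Analyses of such data follow a common shape: process reads
into per-miRNA counts, filter and normalize, test for differential
expression between participant groups, correlate expression with
physiological parameters, and summarize the joint structure by PCA. `mirflow`
implements that pipeline end to end as a tested, reusable R package, together
with a synthetic-data generator that reproduces the statistical structure the
pipeline assumes — so every stage can be validated against known ground
truth without access to any cohort's raw data.

It is aimed at analysts who want a transparent, fully reproducible
implementation of this workflow (each statistical step is written out and
oracle-tested, not hidden behind a monolithic tool), and at method developers
who need a ground-truthed small-RNA simulation to benchmark against.

## The pipeline

**Quantification.** Reads are adapter-trimmed (leftmost adapter occurrence,
10% mismatch tolerance, minimum 10-nt terminal overlap), inserts < 15 nt are
discarded, identical reads are collapsed, and unique reads are aligned
end-to-end to miRNA precursor sequences (≤ 1 substitution by default, via a
k-mer seed index with pigeonhole candidate generation). A read mapping to
*N* loci adds 1/*N* to each locus; each alignment is assigned to the mature
5p miRNA if its midpoint lies in the first half of the precursor, else to
the 3p (ties to 5p).

**Filtering and TMM.** A miRNA is kept when its normalized count
(count / median library size × 10⁶) is ≥ 10 in at least
⌈0.7 · n<sub>smallest group</sub>⌉ samples of some group. Normalization
factors follow the trimmed mean of M-values (TMM): gene-wise
M = log₂[(y<sub>g,j</sub>/N<sub>j</sub>)/(y<sub>g,r</sub>/N<sub>r</sub>)]
values, trimmed 30% on each tail (5% on abundance), precision-weighted,
rescaled to geometric mean 1.

**Differential expression.** Counts are modelled as negative binomial,
Var = μ + φμ². A common φ is estimated by quantile-adjusted conditional
maximum likelihood (qCML); each pair of groups is compared by the NB exact
test — the group sum conditional on the total, two-sided by doubling the
smaller tail — and each comparison is adjusted by Benjamini–Hochberg. The
significant set is the union of miRNAs with FDR ≤ 0.05 in any of the three
pairwise comparisons.

**Association and PCA.** Spearman correlations between per-miRNA log-CPM and
each physiological parameter (pairwise-complete), ordered by average-linkage
clustering to expose correlated blocks; then PCA of the combined z-scored
matrix of significant miRNAs and log-transformed parameters, with
per-feature contribution scores (100·loading²/Σloading²) and a PC1
group-separation report.

## Worked example

Simulate the default three-group cohort (38/36/84 participants; 300 mature
miRNAs with a planted 13-miRNA risk block and 6-miRNA health block) and run
the full count-level pipeline:

```r
library(mirflow)

design <- sim_design(seed = 1)
run <- run_pipeline(pipeline_config(out_dir = "mirflow_run",
                                    simulate = design))
run$de
#> pairwise NB exact tests (common dispersion 0.1005):
#>   HS_vs_HA     249 miRNAs, 11 at FDR <= 0.05
#>   SR_vs_HA     249 miRNAs, 32 at FDR <= 0.05
#>   SR_vs_HS     249 miRNAs, 23 at FDR <= 0.05
#> significant union: 38 miRNAs
round(run$pca$var_frac[1:2], 3)
#> [1] 0.507 0.078
run$separation$accuracy      # PC1 classifier, extreme groups
#> [1] 1
run$separation$intermediate  # sedentary-healthy analog between the extremes
#> [1] TRUE
```

Reading the output: 249 of 300 annotated miRNAs pass the expression filter;
the exact tests recover the injected dispersion (φ̂ ≈ 0.10, truth 0.10) and
find 38 significant miRNAs, 28 of them among the 30 injected (the union
includes the planted risk and health blocks, plus the false discoveries the
5% FDR union admits); the comparison against the at-risk analog
(SR_vs_HA) carries most of the signal, as the injected design intends. PC1
of the combined miRNA + phenotype matrix separates the active from the
at-risk analog perfectly, with the sedentary-healthy analog at intermediate
coordinates.

Adding `read_level = TRUE` to the config generates gzipped FASTQ files and
runs the full read-processing path; with error-free reads the recovered
count matrix equals the simulated truth exactly.

A thin command-line wrapper with `simulate`, `quantify`, `normalize`,
`detest`, `correlate`, `pca` and `run` subcommands is installed at
`inst/cli/mirflow.R` (see its header for usage).

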