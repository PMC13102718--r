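---
title: "Methods: single-cell translational profiling from C-to-U editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell translational profiling from C-to-U editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostamp)
library(dplyr)
```

## The measurement

Ribo-STAMP fuses the cytidine deaminase APOBEC1 to a ribosomal protein
(RPS2), so that translating ribosomes deposit C-to-U edits on the mRNAs
they traverse. Sequencing the same molecules that were edited turns
editing density into an internally normalised proxy for ribosome
occupancy: for each cell and gene, the edits-per-read ratio

$$\mathrm{EPR} = \frac{\text{total C-to-U edits}}{\text{total reads}}$$

plays the role that ribosome-footprint density plays in Ribo-seq, but at
single-cell resolution and without a separate library. For long-read
(isoform-resolved) libraries the analogous per-isoform metric also
normalises for target size:

$$\mathrm{EditsC} = \frac{\text{edited cytosines}}
{\text{cytosines in the spliced transcript} \times \text{reads}},$$

which makes values comparable between isoforms of different length and
base composition. This package implements the full path from barcoded
alignments to these metrics and the downstream statistics: the edit
caller, the editor-expression correction, pseudobulk and pseudocell
aggregation, mixture-model state assignment, bootstrap and Welch
differential tests, and transcript-feature statistics, together with a
seeded synthetic-data generator used to validate every stage against
known truth.

## Edit calling from MD and CIGAR tags

The caller never touches the reference genome. Every substitution a read
carries is reconstructed from its MD tag (which records the reference
base at each substituted or deleted position) combined with its CIGAR
string (which places each query base on the reference). Insertions and
soft clips consume query but no reference; deletions and reference skips
(`N`, spliced alignments) consume reference but contribute no read base;
the MD walk runs in the space of aligned match positions, which the
CIGAR provides. Reads whose MD tag is inconsistent with their CIGAR are
skipped and counted rather than guessed at.

Read-level exclusions: unmapped, secondary, supplementary and QC-fail
flags; a mapping-quality floor (default 0 — barcoded short reads are
already confidently placed upstream); for 10x-style libraries, absence of
the `xf:i:25` tag that marks the representative read of a UMI (off by
default for bulk or long-read libraries, which are deduplicated
upstream); and cell barcodes outside the whitelist. Base-level
exclusions: Phred quality below 20 and positions closer than 5 bases to
either read end, where quality decays. The same base-level filters are
applied when counting coverage, so edit counts and ref/alt depths are
mutually consistent; `N` bases count as neither mismatch nor coverage.

Candidate sites are then pushed through a fixed filter cascade, each
drop attributed to the first failing rule and per-rule counts logged:

1. sites at which more than one alternate base was observed;
2. sites overlapping the SNP mask (known germline variants, e.g. dbSNP);
3. sites with fewer than 3 edits pooled over all cells;
4. sites where more than 5% of pooled covering reads carry the edit
   (clonal variants rather than stochastic editing);
5. sites whose supporting-read strand conflicts with every overlapping
   annotated gene (antisense artefacts), determined by strand-specific
   intersection with the annotation;
6. finally, only the target conversion (C>T on the transcript strand) is
   retained. When the strand-aware mode is on, sites are re-oriented to
   transcript strand before this comparison, so a C-to-U event on a
   minus-strand gene — G>A in genomic forward space — is recognised; this
   single mechanism implements both the antisense filter and the
   orientation of edit types. Sites overlapping several same-strand genes
   are counted in each; with ambiguous strand overlap a site is kept if
   at least one overlapping gene matches.

The cascade order is a design choice (the filters themselves come with
no prescribed order); fixing it makes drop counts auditable and
reproducible. Whether the edited fraction is pooled across cells or
computed per cell is likewise not dictated by the definitions; the
pooled form is used because rule 4 targets site-level artefacts
(SNPs/clonal variants), which manifest in the pooled fraction.

Processing is partitioned by genomic interval: reads are assigned to the
region containing their leftmost aligned position and per-region counts
merge by summation, so a partitioned run is bit-identical to a
single-pass run. Memory then scales with the region, time with the
number of edited reads.

## Editor-expression normalization

Cells expressing more of the editor construct edit more, independently
of translation. The correction regresses, over cells with non-zero
editor expression,

$$\log(\text{mean EPR} + 1) = A \cdot \log(\text{editor CPM} + 1) + b$$

by ordinary least squares, where a cell's mean EPR averages `edits/reads`
over its edited genes (at least one edit and at least **3** reads — the
regression's gene rule is deliberately looser than the 5-read matrix
mask; both thresholds are configurable and logged). Residuals are
exponentiated back to rate scale and min-max rescaled onto the range of
the uncorrected mean EPR:

$$r' = e^{\text{residual}}, \qquad
\text{corrected} = \frac{r' - \min r'}{\max r' - \min r'}
\times (\max \overline{\mathrm{EPR}} - \min \overline{\mathrm{EPR}})
+ \min \overline{\mathrm{EPR}},$$

so the corrected values keep the original dynamic range and stay
non-negative (the exact rescale arithmetic is this package's choice; the
anchoring of minimum and maximum is the method's stated intent). Each
cell's correction factor is corrected/original mean EPR; its edit counts
are multiplied by the factor (fractional counts are expected) and rates
recomputed against unadjusted reads. Cells with zero editor expression,
cells with zero mean EPR, and degenerate fits (constant predictor or
zero-width residual range) all get factor 1. Natural `log1p` is the
default on both axes, matching single-cell convention; a base-10 switch
is provided.

## Aggregation: pseudobulk and pseudocells

Pseudobulk values are pooled ratios — sum of edits over sum of reads per
(cell type, sample) — never means of per-cell ratios; the two differ
whenever coverage is uneven, and the pooled form weights cells by
evidence. Observations under 5 reads are excluded before pooling. A
feature is retained when in at least one cell type all samples have at
least 5 total reads, at least 5 total edits, and at least `min_cells`
cells passing the read threshold (`min_cells` = 1 for cell-type-level
analyses, 5 for stricter within-type analyses; both presets exposed).

Because per-cell edit signals are sparse, clustering operates on
pseudocells: within each cell type, cells are shuffled with a seeded
generator and chunked into groups of 5, 10 or 15; edits and reads are
summed per chunk and the pooled rate recomputed. Remainder cells are
dropped so every pseudocell has identical size (the alternative — one
undersized chunk — would add heteroscedastic rows). The shuffle is
repeated (default 5 times) with seeds derived from the master seed, so
each repeat is independent yet reproducible.

## Translational states

The per-cell total editing rate (total edits over total reads) is
bimodal in some neuronal populations, suggesting discrete high and low
translational states. Cells are assigned by a two-component univariate
Gaussian mixture fitted by EM: means initialised at the 25th and 75th
percentiles, both variances at the pooled variance, equal weights —
a deterministic initialisation that is robust for one-dimensional
bimodal data and removes run-to-run variation. Convergence is declared
when the log-likelihood gain falls below 1e-6 (up to 1000 iterations);
component variances are floored at 1e-8 of the data variance to prevent
collapse. The component with the larger mean is labelled "high";
assignment is by maximum posterior probability. Zero-variance input
returns a flagged degenerate fit with every cell "low" rather than an
error. A quantile-band cell filter (default the 0.65–0.80 window) is
provided to match editor-RNA levels between state groups before
comparing their editing, which separates state differences from editor
dosage.

## Differential translation

**Bootstrap (EPR, between cell types).** Genes are retained per
replicate if edited in at least two cells, cells retained per gene at a
minimum of five reads, and only genes with non-zero EPR in all
replicates are tested. For each feature, per-replicate pseudobulk values
of the two groups are pooled; in each of `n_boot` iterations the pooled
values are resampled with replacement and reassigned to the two groups
at their original sizes; the empirical p-value is the fraction of
iterations whose mean difference is at least the observed one. The
observed wording ("greater than or equal to the observed statistic")
leaves sidedness open; the default compares absolute differences
(two-sided), matching volcano-style reporting, with a one-sided switch.
The plain fraction is reported by default; a `(1+k)/(1+B)` smoothing
switch avoids exact zeros. With three replicates per group this test is
calibrated at the working tail (rejection at p<0.05 close to 0.05) and
detects large shifts essentially always, but its null p-value
distribution is not uniform mid-range: at such small sample sizes the
resampled null distribution conditions on the observed group separation,
inflating mid-range rejection (empirical CDF near 0.22 at p = 0.15).
This is a structural property of pooled resampling at n = 3, not an
implementation artefact, and iteration count does not remove it; the
package documents it rather than substituting a different test.

**Welch (EditsC, per transcript).** A two-sample unequal-variance t-test
with Welch–Satterthwaite degrees of freedom across samples; transcripts
with zero reads and edits in any sample are excluded. When both groups
have zero variance the p-value is 1 for equal means and 0 otherwise.
Fold changes are `log2` ratios of group means, finite only when both
means are positive.

**Discordant isoforms.** Transcripts with p < 0.05 are grouped by gene;
a gene is reported when at least one isoform has significantly increased
and another significantly decreased translation — isoform-level
regulation invisible at the gene level.

**Stratification.** Quartile labels are rank-based with near-equal bins,
ties broken by feature id for determinism, over transcripts edited in
every sample. Per-gene extremes take the argmax/argmin EditsC isoforms
among transcripts with more than 20 total reads. Isoform-pair
coordination is summarised by Spearman correlations of mean values
across cell types for every unordered isoform pair of multi-isoform
genes, computed identically for RNA and EditsC so the two distributions
are directly comparable; constant profiles are skipped and counted.

## Transcript features

UTR and CDS lengths are spliced interval sums; when a GTF supplies CDS
but no explicit UTR features, UTRs are derived from the exon/CDS
geometry strand-awarely. GC content excludes `N` bases from the
denominator. Binding-site burden (miRNA target regions, RBP CLIP peaks)
is the number of site intervals intersecting a transcript's 3' UTR by at
least 1 bp, each site counted once per transcript — interval-set
semantics matching standard BED tooling, strand-aware by default with a
switch (the convention in published site sets varies). Group contrasts
use the two-sided Mann–Whitney U test: exact by complete enumeration up
to 8 observations per group without ties, otherwise the tie-corrected
normal approximation. Inputs must share one genome assembly; no liftover
is performed. A 5'TOP flag (5'-terminal C followed by four or more
pyrimidines) is available behind an option and labelled heuristic —
curated lists are preferable where available.

## The synthetic-data generator

`simulate_alignments()` builds a two-contig genome with six genes (one
spliced, two minus-strand), plants C-to-U edits at sense-strand
cytosines with per-cell-type Bernoulli rates, and writes
FASTA/GTF/VCF/whitelist plus a coordinate-sorted SAM whose MD/CIGAR tags
are constructed from the planted sequences. One deterministic decoy per
filter rule is planted — multi-alternate, all-cell SNP, two-edit,
half-edited, antisense — plus sites visible only through low-quality or
read-end bases, and read-level decoys (unmapped, secondary, tagless,
off-whitelist, low mapq, indel and soft-clip CIGARs). The truth tables
record realized per-barcode counts and each site's expected fate, so
the caller can be compared exactly, not just statistically. Default
scale (24 cells, ~25 reads per cell-gene, 90-bp reads, ~3,700 reads) is
chosen so a brute-force per-base oracle remains practical while every
rule is exercised with realistic coverage (~90x pooled per site).
Regular edits are planted only on sense-strand reads, since planting on
the antisense decoy reads that also cover plus-strand genes would
corrupt the inferred site strand by construction.

`simulate_matrices()` generates cell-by-gene tables with negative
binomial reads and Poisson edits given a per-cell rate that follows
either the editor-expression confound (`log1p`-linear with chosen slope,
intercept and residual spread) or a two-state Gaussian mixture. Editor
CPM is kept on a compressed scale (integer counts against a fixed
library size, with the predictor recomputed from the rounded counts) so
the planted linear model holds exactly in realized data while rates stay
in a plausible band. `simulate_replicate_values()` draws per-replicate
pseudobulk values for null and shifted features, and
`simulate_isoform_dataset()` builds a two-cell-type isoform dataset with
planted discordant genes. The discordance preset defaults to 12 genes
(4 discordant): the detector is an alpha = 0.05 screen, so each null
gene carries a small false-discordance probability, and the preset is
sized so that exact recovery of the planted set is the overwhelmingly
expected outcome rather than a coin flip.

What the generator does not emulate: sequencer error profiles (all
non-edited bases match the reference), barcode errors, doublets and
ambient RNA, UMI structure (deduplication is upstream of this package's
scope), inter-replicate batch effects, and isoform mis-assignment. Tests
passing on this generator therefore validate the arithmetic, the filter
semantics and the statistical calibration of the methods — not
robustness to upstream artefacts in real libraries.

## Problem sizes and numerical choices

The test-suite and acceptance-script runs use: the default alignment
simulation (~3,700 reads) for caller/oracle equivalence; 2,000 cells for
slope recovery and 5,000 for post-correction independence; 2,000 null
features at 2,000 bootstrap iterations for calibration (the analyses on
real data use 10,000 iterations; the calibration structure does not
depend on the count); 1,000 cells for mixture recovery; and 1,000 random
fixtures for the sequence/interval utilities. All randomness flows from
explicit seeds; derived seeds stay within 32-bit integer range.
Floating-point identities (rate times reads equals edits) are asserted
at 1e-9; analytic tests against closed-form oracles at 1e-10.

## Known limitations

The edit caller is written for datasets that fit the tidy in-memory
model (tens of millions of edited reads are fine; whole-genome BAMs at
full depth should be processed per region). The bootstrap's mid-range
null non-uniformity at three replicates is documented above; p-values
near the 0.05 boundary should be read with that in mind. The Mann-
Whitney exact path is limited to 8 per group; beyond that the
tie-corrected normal approximation is used. The heuristic 5'TOP scan is
no substitute for curated annotations.
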