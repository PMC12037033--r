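---
title: "spatac: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatac: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spatac processes spatially barcoded single-end ATAC-seq: reads whose spot
barcode (16 nt) and UMI (12 nt) were carried on read 1 and resolved by an
upstream barcode-correction tool, while read 2 (trimmed to 75 bp) was
aligned to the genome by a conventional aligner. This document explains the
models and procedures the package implements, the parameters that matter,
and the choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite does not itself compute.

## Barcode transfer and duplicate removal

The two alignment streams describe the same reads, so annotation transfer
is a join on read name: `buildReadBarcodeTable()` collects one `(barcode,
UMI)` pair per read name from the barcode-resolved stream (a read name with
two conflicting pairs is a hard error, since it means the streams are not
the same library), and `attachBarcodes()` joins it onto the genome stream,
dropping and counting reads without a table entry.

Duplicates are removed on `(barcode, contig, strand, 5' position)` plus
UMI. The 5' position — `pos` for forward reads, `pos + alignedLength - 1`
for reverse reads — is the genuine Tn5 insertion site, so grouping by it
(not by leftmost coordinate) makes forward and reverse duplicates
symmetric. Within a group, UMIs are merged with the directional network
rule used by standard UMI deduplicators: UMI *a* absorbs UMI *b* when they
differ at one base and `count(a) >= 2*count(b) - 1`, expanding transitively
from higher-count UMIs. This removes apparent molecules created by PCR or
sequencing errors in the UMI; an `exact` mode (every distinct UMI its own
molecule) is kept for debugging. Determinism is enforced everywhere ties
can arise: seeds are taken in decreasing count with lexicographically
smaller UMI winning; the representative record of a collapsed set is the
smallest `(pos, readName)`; output is sorted by group key then UMI. The
test suite checks the directional implementation against an independent
brute-force network oracle, exhaustively over all small UMI groups.

## Fragment synthesis

Each deduplicated single-end record becomes one interval of a synthetic
paired-end-style fragments file (TSV: contig, start, end, barcode, count;
0-based half-open; sorted). Only the 5' end of the read is a real insertion
site; the 3' end is synthetic, taken from the aligned span. Tn5
duplication-offset correction defaults to `(+4, -5)`, the community
convention, applied end-for-end: the 5' end always moves inward by 4 and
the 3' end by 5, on both strands. The upstream protocol this mirrors does
not state whether any offset was applied when fragments were synthesized,
so the shift is configurable and `(0, 0)` is supported (and used by the
oracle tests, where intervals must equal the simulator's truth exactly).
Records whose shifted interval becomes empty are dropped and counted. No
size filtering is applied and QC thresholds (minimum fragments per spot,
minimum TSS enrichment) are *reported, not enforced*: the intended regime
keeps nearly all barcodes and leaves filtering to the caller.

Downstream counting treats **both** fragment ends as insertions by default
(`countMode = "both"`), because that is what every consumer of fragment
files assumes; it is a documented bias (one of the two ends per fragment is
synthetic). A `five-prime` mode counts only the genuine end and requires
the in-memory stranded fragments, since the on-disk format has no strand.
Tile and gene matrices and copy-number densities count one insertion per
fragment end at the *molecule* level (duplicate multiplicity is not
re-inflated); the mitochondrial read fraction is read-weighted, because it
describes sequencing composition rather than molecular accessibility.

## Per-spot QC: TSS enrichment

Insertions are aggregated in a strand-oriented profile of +/- 2000 bp
around all TSS. The background is the mean per-position count over the
outermost 100 positions of each side; the score is the normalized mean
over a 101-bp window centered on the TSS. Averaging over a center window
rather than reading a single base makes the score stable at realistic
insertion counts (at 10,000 profile insertions the single-base estimate
has >60% relative noise; the 101-bp mean has ~6%). A flat profile scores
~1 by construction; a spot with zero flank signal is scored 0 with a
warning rather than dividing by zero. The score is invariant under uniform
scaling of fragment counts.

## Tile and gene matrices, concordance

The tile matrix bins insertions into fixed 5-kb tiles (rows) per spot
(columns), the peak-free feature set appropriate when spot counts are too
shallow for peak calling; the last tile of a contig may be short. The gene
score is deliberately a transparent counting model — insertions in the
gene body plus a 2-kb strand-aware promoter window, overlapping genes each
credited — rather than a replica of any specific toolkit's distance-decay
model; it is documented as non-equivalent and is treated as a consumer, not
a contribution.

Cross-modality concordance between accessibility gene scores and gene
expression works on per-spot library-size-normalized values (counts per
10,000). For every gene and every pair of clusters, each modality gets a
Wilcoxon rank-sum test (normal approximation, tie and continuity
corrected; cross-checked against `stats::wilcox.test` in the tests) and a
log2 fold change of cluster means with pseudocount 1. A gene passes when
any pair reaches `p <= 0.05` and `|log2FC| >= 1` in either modality — the
source analysis does not name its test, so the rank-sum choice is recorded
as an assumption; no multiple-testing correction is applied because the
filter is defined on raw p-values. Passing genes are summarized by the
Pearson correlation of per-cluster means between modalities. Cluster
labels are an *input*; clustering itself is out of scope.

## Copy number from GC-matched background windows

Windows of 3 Mb slide in 1-Mb steps across each contig (full-width windows
only; a contig shorter than one window contributes a single whole-contig
window). Blacklisted and ambiguous (N) bases are excluded from the GC
numerator/denominator and from the effective length; windows more than
half excluded are dropped. For each window, insertions per effective bp
are compared to the 200 windows nearest in GC content *anywhere in the
genome*, excluding the window itself and windows genomically overlapping
it. The genome-wide reading of "neighboring windows with similar GC" was
chosen over literal genomic neighbors because an amplified locus would
contaminate its own neighborhood's background. The log2 fold change is the
mean over background windows of per-pair log ratios
`log2((d_w + eps_w)/(d_b + eps_b))`, with pseudocount `eps = 1/effective
length` (one insertion per window) keeping the log defined for empty
windows at the cost of exact depth invariance (invariance holds to ~1e-3
at >=50 insertions per window, which the tests assert). A
`ratio_of_means` mode (log ratio of window density to mean background
density) is provided; the two agree exactly when the background is
constant. Copy number follows the diploid baseline `CN = 2 * 2^log2FC`,
applied genome-wide with no ploidy correction for sex chromosomes. Gene
CN is the arithmetic mean over windows overlapping the gene by >= 1 bp.

Per-spot amplicon CN has no published recipe; the package's own
construction is the simplest depth-invariant ratio: a spot's insertion
density inside the amplicon over the same spot's density across all
windows not overlapping the amplicon, times 2. Spots with no background
insertions are undefined (NA), not zero.

**Known limitation — small window pools.** The background model assumes
the number of candidate windows greatly exceeds the number of matched
backgrounds (a human-genome-scale assumption: ~3,100 windows vs 200
backgrounds). When a genome yields fewer windows than requested
backgrounds, the pool collapses to "every non-overlapping window" and any
strongly amplified region contaminates *every* window's background,
biasing diploid windows downward (for one 3-Mb CN-40 amplicon in a 100-Mb
genome the bias is about -0.23 in log2, i.e. median diploid CN ~1.7
instead of 2). The estimator warns when it lowers the background count.
Amplified-window estimates themselves are unaffected, because overlapping
windows are excluded from their own backgrounds.

## Mitochondrial variants

The package re-implements the stated core of spot-resolved mtDNA
genotyping — per-barcode stranded base counts, a strand-correlation pass
filter, per-spot heteroplasmy — and deliberately not the full feature set
of the external tool it mirrors (no variance-to-mean ratio metrics, no
coverage smoothing); equivalence with that tool is not claimed. Positions
are reported 1-based, the mtDNA nomenclature convention (the package's
nuclear interval types are 0-based half-open at the file level; the
boundary is documented on each type).

`countAlleles()` walks CIGARs and counts only match/mismatch bases,
skipping insertions, deletions and clips, with a Phred >= 20 floor when
qualities are present. For each candidate substitution the strand
correlation is the Pearson correlation, across spots with coverage at the
position, between forward- and reverse-strand alternate counts, computed
on raw counts (a frequency mode exists). Genuine variants co-vary across
spots on both strands because spots differ in mtDNA content and
heteroplasmy; strand-specific artifacts do not. The pass threshold is
0.25. The correlation is undefined — and the variant fails — when either
strand has zero variance or fewer than 5 spots carry the allele; that
floor is this package's guard against spurious correlations at tiny n, not
part of the published filter. All pass-filter variants are reported with
their heteroplasmy; no germline/somatic classification is attempted. NUMT
handling is an upstream alignment concern (a masked reference); the
simulator instead supports injecting misassigned reads to test robustness.

## The simulator: what it emulates and what it does not

`simulateSpatialAtac()` generates every input the pipeline touches —
random genome with per-contig GC, spot layout on a grid with unique
16-mers, both alignment streams over the same reads, FASTA and length
index — plus machine-readable truth (read-to-molecule map, molecule
intervals, per-variant per-spot allele counts). One seed drives a single
RNG stream, so outputs are bit-identical across runs. Reads are emitted
pre-aligned as SAM text: alignment is out of scope and this keeps the
fixture loop closed.

Defaults describe the intended library type: 16/12-nt barcodes/UMIs, 75-bp
reads, PCR duplicate rate 0.5 (duplicates re-emit an existing molecule of
the same spot under a fresh name), UMI error rate 0.01 (one substituted
base). Amplicons scale read density inside the interval by `trueCn/2` in
affected spots. Mitochondrial reads carry real sequence with alleles
injected per strand: a variant with strand bias *b* and spot heteroplasmy
*h* is emitted on forward reads with probability `min(1, 2hb)` and reverse
with `min(1, 2h(1-b))`, so the marginal frequency is *h* for balanced or
moderate bias, and a fully biased artifact (b = 1) has literally zero
reverse support. Spots vary in mtDNA abundance (lognormal, sdlog 0.3) and
per-spot heteroplasmy (beta around the clone mean, concentration 20);
these two dispersions are what give genuine variants their between-spot
strand covariance, the signal the 0.25 filter relies on — with perfectly
homogeneous spots, forward and reverse counts would be independent
binomials and the filter could not discriminate. They were chosen once as
realistic tissue-scale variability.

The simulator does **not** model fragment-length or nucleosome structure,
chromatin domains, GC amplification bias, mappability, barcode hopping, or
an RNA modality beyond the Poisson gene-count generator used for the
concordance test. Passing tests therefore demonstrate correctness of the
algorithms under known ground truth, not performance on real tissue.

## Problem sizes and numerical notes

The test suite runs everything at deliberately small scale: unit fixtures
of tens of reads; recovery tests at 10-50 spots and 100-2,000 reads per
spot; the copy-number recovery scenario on a 10-contig, 100-Mb genome
(~100,000 reads, 80 windows); mitochondrial recovery on a 1-kb
mitochondria-like contig at 100x per-spot coverage. The exhaustive
directional-merge oracle sweeps all UMI groups of size <= 4 over a
structured 6-UMI universe with counts in {1, 2, 5} (and {1, 2, 3, 5} in
the unit test). Tie-breaks, pseudocounts and degenerate-input rules
(empty windows, zero-coverage spots, zero-flank TSS profiles, short
alignments) are each pinned by a dedicated test rather than left to
chance.
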