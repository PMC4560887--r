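---
title: "From antibody peak sets to target genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From antibody peak sets to target genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiptarget)
```

## The problem

A transcription factor ChIP-seq experiment run with several independent
antibodies yields one peak set per antibody, each a mixture of true binding
sites and antibody-specific artifacts. `chiptarget` implements the downstream
arc from those peak calls to a ranked list of candidate target genes:

1. consensus filtering and union merging across antibodies;
2. where along gene bodies the factor binds (binding preference);
3. how binding relates to transcription start sites (TSS proximity);
4. which genes the peaks collectively point at (distance-decay scoring);
5. whether peak sequences carry the factor's motif (E-box scanning);
6. whether the targets overlap externally defined gene categories;
7. ChIP-qPCR quantification for wet-lab confirmation of individual sites.

Throughout, intervals are 0-based half-open, matching BED. GTF/GFF3 input
(1-based inclusive) is converted on read. Two intervals overlap when they
share at least one base; touching half-open intervals do not overlap.

## Consensus peaks

A peak is retained when it overlaps at least one peak from at least
`min_support - 1` (default 1) of the other antibody sets; retained peaks are
then collapsed to their union. Each consensus interval records its support
(distinct contributing antibodies) and its midpoint, `floor((start+end)/2)`,
which serves as the peak location in every downstream step. Reproducibility
between two antibody sets is summarized as the signed Pearson correlation of
per-bin occupancy (bases covered per fixed genomic bin, default 1000 bp).
A squared correlation is sometimes quoted for such comparisons, but squaring
discards the sign and cannot express anti-correlation between unrelated
factors, so the signed coefficient is reported.

## Binding preference along gene segments

One representative transcript is chosen per gene — the one with the greatest
genomic span, ties broken toward the lexicographically smallest transcript
id — to avoid double counting positions shared by isoforms. Summed exon
length would be a defensible alternative; genomic span is used because the
segment map tiles the full transcript span, introns included. Each
representative transcript is decomposed into 5'UTR, CDS and 3'UTR exon
segments and introns, indexed 1..k in 5'-to-3' order within each class.
Exons of transcripts without an annotated CDS form a fifth class,
`noncoding_exon`, kept intragenic but outside the four-class comparison. A
position covered by two overlapping representative transcripts is assigned
to the gene with the smaller (chrom, start, gene_id) sort key; occurrences
are reported via a message.

Observed midpoint counts per (class, index) cell are compared against a
null in which the same number of intragenic peaks is reassigned uniformly
*per base* over the union of representative transcript bodies — longer
segments attract proportionally more null peaks, which is exactly what makes
the comparison length-normalized. The statistic is

$$bp = \frac{n - \bar n}{\sigma}$$

with \(\bar n\) and \(\sigma\) estimated from `R` randomizations (default
1000, seed mandatory). Because classifying independent per-base uniform
draws is a multinomial experiment over disjoint segment cells, the null
counts are drawn as `rmultinom` over effective (overlap-resolved) cell
lengths — distributionally identical to placing and classifying each peak,
and orders of magnitude faster. Cells with \(\sigma = 0\) are flagged
undefined rather than given a number. Two tail probabilities are reported:
an add-one empirical p, \((1 + \#\{n^{(r)} \ge n\})/(1 + R)\) (mirrored for
depletion), whose resolution is bounded by \(1/(R+1)\), and the Gaussian
tail of \(bp\) as a parametric reference for deviations far beyond empirical
resolution. Segment indices above 10 are pooled into a "10+" cell.

## TSS proximity

Two framings are exposed, because both are useful: the all-pairs signed
distance list (every peak/TSS pair within \(10^6\) bp; positive downstream
in the gene's reading direction) for the distance histogram, and a
nearest-TSS reduction per peak for summary fractions such as the share of
peaks within 1 kb of a TSS. Histogram bins (default 1000 bp) are centered
so one bin is symmetric around 0; splitting the origin at a bin edge would
halve the apparent promoter-proximal accumulation.

## Distance-decay gene scoring

Each consensus peak is assigned to the gene whose representative TSS is
nearest its midpoint (ties toward the smaller (chrom, tss, gene_id) key) and
contributes \(e^{-d/d_0}\) to that gene's cumulative score. The exponential
is the standard distance-decay form for peak-to-gene association; the decay
scale \(d_0\) (default 5000 bp) means a peak 5 kb from a TSS carries
\(1/e\) the weight of one directly on it, and is an explicit configuration
knob rather than a claim about any particular published implementation. A
background score per gene is computed by scoring the same number of
uniformly placed random peaks, averaged over 10 repetitions to damp the
seed sensitivity a single draw would have; the normalized score is raw
minus background. Targets are genes whose normalized score exceeds the mean
by more than `threshold_sigma` (default 1) population standard deviations,
computed over all annotated genes, zeros included.

## Motif scanning and enrichment

Patterns are IUPAC strings — the E-box core `CANNTG`, the extended E-box
`CAKMTGK` = CA(G/T)(C/A)TG(G/T). Scanning counts all (possibly overlapping)
match positions on both strands, deduplicating palindromic double counts at
the same start; `N` in a sequence never matches. The enrichment statistic is
the fraction of peaks containing at least one match (presence/absence, which
damps repeat-driven multi-match artifacts), compared against per-peak
dinucleotide shuffles (Altschul–Erickson Euler-path shuffles, preserving
each peak's exact dinucleotide composition and hence CpG content). This is a
scanning surrogate for de novo discovery tools: it tests whether a *given*
motif is unexpectedly present, not what the most enriched unknown motif is.

## Gene-set overlap

Overlap between the target list and each user-supplied category is tested
with the exact hypergeometric upper tail over a declared gene universe
(default: all annotated genes; exact, case-sensitive id matching), with
Benjamini–Hochberg adjustment across the supplied categories, alongside an
empirical baseline: the mean overlap fraction of equally many randomly drawn
genes. The baseline mean converges to the hypergeometric expectation; it is
reported because it is the directly interpretable "random genes" comparison.

## ChIP-qPCR

Input Ct values are adjusted by \(\log_2(1/f)\) for input fraction \(f\)
(3.32 cycles for the conventional 10% input), and percent input is
\(100 \times 2^{\text{adjusted input Ct} - \text{ChIP Ct}}\). Technical
replicates are averaged to one Ct per (sample, amplicon, role) before any
transformation; fold enrichment over a control ChIP is the ratio of means
across biological samples with a first-order delta-method standard error
and a Welch t-test.

## The synthetic data generator

Every stage is testable without downloads via `sim_config()` /
`simulate_dataset()`. The generator emulates: non-overlapping multi-exon
genes with interior CDS (so each gene has 5'UTR, CDS and 3'UTR segments);
true binding sites placed with Laplace-distributed offsets (scale 200 bp)
around the TSSs of a designated target subset, reproducing a sharp ±1 kb
promoter-proximal accumulation; three antibody datasets that each emit a
true site with probability 0.8 plus five times as many uniform noise peaks;
uniform random genome sequence with a concrete extended E-box instance
planted under half of the true sites; target-enriched and background gene
categories; and a back-computed qPCR Ct table.

Defaults are 3 chromosomes × 10 Mb, 500 genes (introns 2–8 kb, roughly 30%
of the genome intragenic), 150 true sites and 750 noise peaks per antibody
— about 30 peaks/Mb, within an order of magnitude of genome-wide peak
densities in real TF ChIP-seq. Density matters: on a genome made several-
fold denser, independent noise peaks collide across antibodies and pass
consensus filtering at rates never seen in real data, and precision of
target recovery degrades for reasons that say nothing about the method.

What the generator does *not* emulate: mappability and GC bias, read-level
noise, correlated artifacts between antibodies (each antibody's noise is
independent, so consensus filtering is more effective here than against
shared artifacts such as hyper-ChIPable regions), overlapping genes, and
realistic transcript isoform complexity. Passing recovery tests on this
generator therefore demonstrates correctness of the computational chain
under its stated assumptions, not robustness to every real-data pathology.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at the
default scale above (about half a minute end to end), with R = 1000
randomizations, 100 dinucleotide shuffles and 1000 random-gene draws;
interval and scoring oracles run on hundreds of randomized small instances.
Empirical p-values use the add-one estimator and can never be 0. All
randomized components take explicit seeds, and the pipeline salts one master
seed per stage so stages are independently reproducible. Degenerate inputs
are contracts, not accidents: zero-variance occupancy signals refuse to
produce a correlation, σ = 0 cells refuse a bp value, an all-equal
normalized score vector selects no targets (with a warning), and empty peak
files load as empty sets with a warning.
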