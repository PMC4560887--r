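# chiptarget

`chiptarget` takes the peak calls from a transcription-factor ChIP-seq
experiment performed with several independent antibodies and turns them into
a ranked list of candidate target genes, with the intermediate statistics a
regulatory-genomics analysis needs along the way. It is aimed at analysts
who already have per-antibody peak files (BED/narrowPeak) and a genome
annotation, and want the downstream arc — consensus integration, genomic
context, TSS proximity, target scoring, motif and gene-set enrichment,
qPCR confirmation arithmetic — as tested, reusable functions rather than
one-off scripts.

## What it computes

- **Consensus peaks.** Peaks supported by ≥ 2 antibodies are kept and
  collapsed to their union; each consensus interval carries its support and
  midpoint. Antibody reproducibility is summarized as the Pearson
  correlation of binned occupancy signals.
- **Binding preference.** One representative (longest) transcript per gene
  is segmented into 5′UTR/CDS/3′UTR exons and introns, indexed 5′→3′. The
  observed midpoint count *n* per segment cell is compared with a null that
  reassigns the intragenic peaks uniformly per base over transcript bodies:

      bp = (n − n̄) / σ

  with n̄ and σ from R randomizations — a length-normalized enrichment in
  units of null standard deviations, with empirical and Gaussian-tail
  p-values.
- **TSS proximity.** Signed peak–TSS distance histogram (all pairs within
  1 Mb, positive downstream) and the fraction of peaks within a window of
  their nearest TSS.
- **Target scoring.** Each peak is assigned to its closest representative
  TSS and contributes exp(−d/d₀) (default d₀ = 5 kb) to that gene; a gene's
  normalized score subtracts the score of equally many randomly placed
  peaks, and targets are genes more than 1 SD above the mean normalized
  score.
- **Motif enrichment.** IUPAC scanning (E-box `CANNTG`, extended E-box
  `CAKMTGK`) on both strands; the fraction of peaks with a match is tested
  against per-peak dinucleotide shuffles.
- **Gene-set overlap.** Exact hypergeometric upper-tail p (BH-adjusted) plus
  a random-gene baseline for user-supplied categories.
- **ChIP-qPCR.** Percent input `100 × 2^(adjusted input Ct − ChIP Ct)` with
  the log2(1/input fraction) adjustment (3.32 for 10% input), and fold
  enrichment over a control ChIP with delta-method errors.

A synthetic-data module (`sim_config()`, `simulate_dataset()`) generates
annotation, peak sets, genome sequence, gene categories and qPCR tables with
known ground truth, so the entire pipeline is exercisable and testable
without downloading anything.

## Worked example

```r
library(chiptarget)
cfg <- sim_config(seed = 1337)          # 500 genes, 3 antibodies, known truth
sim <- simulate_dataset(cfg, tempdir())

res <- run_pipeline(list(
  peaks      = as.list(sim$paths$peaks),
  annotation = sim$paths$annotation,
  fasta      = sim$paths$fasta,
  seed       = 1
))

m <- res$manifest$counts
cat(sprintf("%d peaks in -> %d retained -> %d consensus peaks\n",
            m$input_peaks, m$retained_peaks, m$consensus_peaks))
bp <- as.data.frame(res$binding_preference)
cat(sprintf("bp(first 5UTR exon) = %.1f vs bp(first intron) = %.1f\n",
            bp$bp[bp$class == "UTR5_exon" & bp$index == 1],
            bp$bp[bp$class == "intron" & bp$index == 1]))
cat(sprintf("%.0f%% of consensus peaks lie within 1 kb of a TSS\n",
            100 * res$tss$fraction_within))
cat(sprintf("%d target genes selected; motif enrichment ratio %.2f\n",
            length(res$targets), res$motif$enrichment_ratio))
truth <- sim$truth$true_target_genes
cat(sprintf("recall %.2f, precision %.2f against the planted truth\n",
            mean(truth %in% res$targets), mean(res$targets %in% truth)))
```

prints

```
2605 peaks in -> 421 retained -> 101 consensus peaks
bp(first 5UTR exon) = 16.6 vs bp(first intron) = 0.9
69% of consensus peaks lie within 1 kb of a TSS
51 target genes selected; motif enrichment ratio 2.18
recall 1.00, precision 0.98 against the planted truth
```

Reading it: of 2605 raw peaks across the three antibody sets, 421 are
reproduced by a second antibody and merge into 101 consensus regions. The
planted sites sit at TSSs, so binding is massively enriched on first 5′UTR
exons (16.6 null SDs above expectation) but not on introns; 69% of
consensus peaks fall within 1 kb of a TSS. Target selection recovers the
50 planted target genes essentially perfectly, and the extended E-box
planted under half the true sites shows up as a 2.2-fold enrichment over
the dinucleotide-shuffle null.

The same stages are available as individual functions (`read_peaks()`,
`consensus_filter()`, `merge_union()`, `build_segment_map()`,
`randomize_intragenic()`, `score_genes()`, `peak_motif_enrichment()`,
`gene_set_enrichment()`, `qpcr_percent_input()`, ...) for use outside the
orchestrated pipeline, and `inst/scripts/chiptarget.R` is a small
command-line wrapper (`run`, `simulate`) over the same functions.

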