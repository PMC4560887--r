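Package: chiptarget
Title: Transcription-Factor ChIP-Seq Peak Integration and Target Gene Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of transcription-factor ChIP-seq peak calls:
    consensus peak integration across antibodies, genomic-segment binding
    preference statistics against a randomization null, peak-to-TSS proximity
    mapping, distance-decaying gene target scoring with a random-peak
    background, IUPAC motif-occurrence enrichment against a
    dinucleotide-shuffle null, gene-set overlap enrichment with a random-gene
    baseline, and percent-input ChIP-qPCR quantification. Includes a synthetic
    data generator with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
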