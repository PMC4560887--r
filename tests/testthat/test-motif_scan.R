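test_that("IUPAC scanning matches the worked examples", {
  # extended E-box CA(G/T)(C/A)TG(G/T)
  expect_equal(scan_sequence("CAGCTGG", "CAKMTGK", both_strands = FALSE), 1L)
  expect_equal(scan_sequence("CACGTGCACGTG", "CANNTG", both_strands = FALSE),
               2L)
  expect_equal(scan_sequence("AAAAAA", "CANNTG"), 0L)
  expect_error(scan_sequence("ACGTX", "CANNTG"), "invalid sequence")
  expect_error(iupac_pattern("CAQ"), "invalid IUPAC")
  # N in the subject never matches, even against pattern N
  expect_equal(scan_sequence("CANNTG", "CANNTG"), 0L)
})

test_that("overlapping matches and palindromes are counted correctly", {
  # CACGTG is its own reverse complement: no double counting per position
  expect_equal(scan_sequence("CACGTG", "CANNTG", both_strands = TRUE), 1L)
  # here the reverse complement adds no new start position
  expect_equal(scan_sequence("CAGCTGG", "CAKMTGK", both_strands = TRUE), 1L)
  # CAGCTG core: reverse strand contributes a second, offset match
  expect_equal(scan_sequence("GCAGCTGC", "CANNTG", both_strands = TRUE),
               brute_scan("GCAGCTGC", "CANNTG", both_strands = TRUE))
})

test_that("scanning agrees with a regular-expression oracle", {
  set.seed(61)
  pats <- c("CANNTG", "CAKMTGK")
  for (i in 1:150) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    p <- sample(pats, 1)
    expect_equal(scan_sequence(s, p, both_strands = TRUE),
                 brute_scan(s, p, both_strands = TRUE))
    expect_equal(scan_sequence(s, p, both_strands = FALSE),
                 brute_scan(s, p, both_strands = FALSE))
  }
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(62)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(scan_sequence(s, "CAKMTGK", both_strands = TRUE),
                 scan_sequence(rc, "CAKMTGK", both_strands = TRUE))
  }
})

test_that("dinucleotide shuffling preserves exact dinucleotide counts", {
  set.seed(63)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:300, 1),
                      replace = TRUE), collapse = "")
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    # endpoints are preserved by the Euler-path construction
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)),
                 substr(s, nchar(s), nchar(s)))
  }
  # shuffles actually move things for typical sequences
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  expect_true(any(vapply(1:5, function(i) dinuc_shuffle(s) != s,
                         logical(1))))
})

test_that("composition-preserved control gives enrichment ratio near 1", {
  set.seed(64)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")))
  s <- as.integer(seq(100, 18000, length.out = 40))
  cons <- data.table::data.table(chrom = "chr1", start = s, end = s + 200L)
  res <- peak_motif_enrichment(cons, genome, "A", n_shuffles = 20, seed = 9L)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$enrichment_ratio, 1)
  expect_error(peak_motif_enrichment(cons[0, ], genome, "A"), "zero peaks")
})

test_that("planted E-boxes are detected as enriched over the shuffle null", {
  cfg <- sim_config(n_genes = 60L, chrom_length = 1.2e6, n_true_sites = 50L,
                    n_noise_peaks = 0L, detection_prob = 1,
                    motif_plant_rate = 0.9, seed = 65L)
  ann <- generate_annotation(cfg)
  ps <- generate_peak_sets(ann, cfg)
  sq <- generate_sequences(ann, ps$truth, cfg)
  cons <- merge_union(consensus_filter(ps$peak_sets)$retained)
  res <- peak_motif_enrichment(cons, sq$genome, "CAKMTGK",
                               n_shuffles = 100, seed = 66L)
  expect_gt(res$enrichment_ratio, 1)
  expect_lte(res$p_emp, 0.01)
})

test_that("peaks outside the sequence bounds are reported by index", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  cons <- data.table::data.table(chrom = "chr1", start = 5L, end = 20L)
  expect_error(peak_sequences(cons, genome), "peak 1")
})

test_that("plant-rate extremes behave as the closed form predicts", {
  cfg1 <- sim_config(n_genes = 40L, chrom_length = 1e6, n_true_sites = 40L,
                     n_noise_peaks = 0L, detection_prob = 1,
                     motif_plant_rate = 1, seed = 67L)
  ann <- generate_annotation(cfg1)
  ps <- generate_peak_sets(ann, cfg1)
  sq <- generate_sequences(ann, ps$truth, cfg1)
  seqs <- peak_sequences(ps$truth$true_sites, sq$genome)
  hits <- vapply(seqs, function(s) scan_sequence(s, "CAKMTGK") > 0,
                 logical(1))
  expect_true(all(hits))

  # plant rate 0: fraction close to the random-background closed form
  cfg0 <- cfg1; cfg0$motif_plant_rate <- 0; cfg0$seed <- 68L
  ann0 <- generate_annotation(cfg0)
  ps0 <- generate_peak_sets(ann0, cfg0)
  sq0 <- generate_sequences(ann0, ps0$truth, cfg0)
  expect_equal(nrow(sq0$planted_motifs), 0)
  seqs0 <- peak_sequences(ps0$truth$true_sites, sq0$genome)
  frac <- mean(vapply(seqs0, function(s) scan_sequence(s, "CAKMTGK") > 0,
                      logical(1)))
  # per-position match probability (either strand) for CA(G/T)(C/A)TG(G/T)
  p1 <- (1 / 4)^4 * (1 / 2)^3
  w <- nchar(seqs0) - 6
  expected <- mean(1 - (1 - 2 * p1)^w)  # union bound, near-exact at this p
  expect_lt(abs(frac - expected), 0.15)
})
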