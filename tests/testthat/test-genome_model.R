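test_that("GTF is parsed into the 0-based half-open convention", {
  path <- write_gtf_lines(c(
    "##sequence-region chr1 1 1000",
    "chr1\tsrc\ttranscript\t101\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tsrc\texon\t251\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"
  ))
  ann <- read_annotation(path)
  expect_equal(length(unique(ann$transcripts$gene_id)), 1)
  expect_equal(nrow(ann$exons), 2)
  # 1-based inclusive 101..200 becomes [100, 200)
  expect_equal(ann$exons$start, c(100L, 250L))
  expect_equal(ann$exons$end, c(200L, 300L))
  expect_equal(ann$chromosomes, c(chr1 = 1000))
  expect_equal(ann$transcripts$tss, 100L)
})

test_that("malformed and inconsistent annotations are rejected with context", {
  bad <- write_gtf_lines(c(
    "chr1\tsrc\ttranscript\t101\t300\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "chr1 only three fields"
  ))
  expect_error(read_annotation(bad), "line 2")
  outside <- write_gtf_lines(c(
    "chr1\tsrc\ttranscript\t101\t300\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "chr1\tsrc\texon\t101\t400\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"
  ))
  expect_error(read_annotation(outside), "exon outside")
})

test_that("GFF3 ID/Parent hierarchy is understood", {
  path <- write_gtf_lines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 1000",
    "chr1\tsrc\tmRNA\t101\t300\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t300\t.\t-\t.\tParent=t1"
  ))
  path2 <- sub("\\.gtf$", ".gff3", path); file.rename(path, path2)
  ann <- read_annotation(path2)
  expect_equal(ann$transcripts$gene_id, "g1")
  expect_equal(ann$transcripts$tss, 299L)  # minus strand: span end - 1
})

test_that("representative transcript is the longest span, ties lexicographic", {
  tx <- data.frame(
    transcript_id = c("tB", "tA", "tC"),
    gene_id = c("g1", "g1", "g2"),
    chrom = "chr1", strand = "+",
    start = c(0L, 0L, 500L), end = c(2000L, 1000L, 600L)
  )
  rep <- select_representatives(tx)
  expect_equal(rep$transcript_id[rep$gene_id == "g1"], "tB")
  # equal spans: lexicographically smallest id
  tx$end <- c(1000L, 1000L, 600L)
  rep <- select_representatives(tx)
  expect_equal(rep$transcript_id[rep$gene_id == "g1"], "tA")
  expect_equal(rep$transcript_id[rep$gene_id == "g2"], "tC")
  expect_error(select_representatives(tx[0, ]), "no transcripts")
})

test_that("segment map matches the manual walk on both strands", {
  map <- build_segment_map(toy_annotation("+"))
  expect_equal(map$start, c(0L, 50L, 100L, 200L, 250L))
  expect_equal(map$end, c(50L, 100L, 200L, 250L, 300L))
  expect_equal(map$class,
               c("UTR5_exon", "CDS_exon", "intron", "CDS_exon", "UTR3_exon"))
  expect_equal(map$index, c(1L, 1L, 1L, 2L, 1L))

  # same coordinates on the minus strand: roles and indices flip 5'->3'
  mapm <- build_segment_map(toy_annotation("-"))
  expect_equal(mapm$class,
               c("UTR3_exon", "CDS_exon", "intron", "CDS_exon", "UTR5_exon"))
  expect_equal(mapm$index, c(1L, 2L, 1L, 1L, 1L))
  expect_equal(mapm$start[mapm$class == "UTR5_exon"], 250L)
})

test_that("degenerate transcripts segment correctly", {
  # single-exon fully coding -> one CDS_exon, no introns
  ann <- genome_annotation(
    c(chr1 = 1000),
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", start = 0L, end = 100L),
    data.frame(transcript_id = "t1", start = 0L, end = 100L),
    data.frame(transcript_id = "t1", start = 0L, end = 100L))
  map <- build_segment_map(ann)
  expect_equal(map$class, "CDS_exon")
  expect_equal(map$index, 1L)

  # no CDS record -> noncoding_exon segments
  ann2 <- genome_annotation(
    c(chr1 = 1000),
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", start = 0L, end = 300L),
    data.frame(transcript_id = c("t1", "t1"), start = c(0L, 200L),
               end = c(100L, 300L)))
  map2 <- build_segment_map(ann2)
  expect_equal(sort(unique(map2$class)), c("intron", "noncoding_exon"))

  # CDS endpoint in an intron -> validation error
  ann3 <- toy_annotation("+")
  ann3$cds$end <- 150L
  expect_error(build_segment_map(ann3), "CDS not contained")
})

test_that("positions classify to the expected segments", {
  map <- build_segment_map(toy_annotation("+"))
  got <- classify_position(map, "chr1", c(150L, 10L, 750L))
  expect_equal(got$class, c("intron", "UTR5_exon", "intergenic"))
  expect_equal(got$index, c(1L, 1L, NA_integer_))
  expect_equal(got$gene_id, c("g1", "g1", NA_character_))
})

test_that("segments tile each representative transcript exactly", {
  cfg <- sim_config(n_genes = 40L, chrom_length = 1e6, seed = 21L)
  ann <- generate_annotation(cfg)
  map <- build_segment_map(ann)
  per_tx <- map[, list(total = sum(end - start)), by = "transcript_id"]
  tx <- ann$transcripts
  expect_equal(per_tx$total[match(tx$transcript_id, per_tx$transcript_id)],
               tx$end - tx$start)
})

test_that("classification agrees with a per-base scan and is strand symmetric", {
  cfg <- sim_config(n_genes = 8L, chrom_length = 2e5, n_chromosomes = 1L,
                    seed = 33L)
  ann <- generate_annotation(cfg)
  map <- build_segment_map(ann)
  set.seed(1)
  pos <- sample.int(2e5, 400L) - 1L
  got <- classify_position(map, "chr1", pos)
  # brute force: scan the segment list per position
  for (i in seq_along(pos)) {
    hit <- which(map$start <= pos[i] & pos[i] < map$end)
    if (length(hit) == 0) {
      expect_equal(got$class[i], "intergenic")
    } else {
      h <- hit[which.min(map$gene_rank[hit])]
      expect_equal(got$class[i], map$class[h])
      expect_equal(got$index[i], map$index[h])
    }
  }

  # reflecting all coordinates and flipping strands preserves labels
  L <- 2e5
  refl <- genome_annotation(
    ann$chromosomes,
    within(as.data.frame(ann$transcripts), {
      s <- start; start <- L - end; end <- L - s
      strand <- ifelse(strand == "+", "-", "+")
      rm(s)
    })[, c("transcript_id", "gene_id", "chrom", "strand", "start", "end")],
    within(as.data.frame(ann$exons), {
      s <- start; start <- L - end; end <- L - s; rm(s)
    }),
    within(as.data.frame(ann$cds), {
      s <- start; start <- L - end; end <- L - s; rm(s)
    }))
  rmap <- build_segment_map(refl)
  rgot <- classify_position(rmap, "chr1", L - 1L - pos)
  expect_equal(rgot$class, got$class)
  expect_equal(rgot$index, got$index)
})
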