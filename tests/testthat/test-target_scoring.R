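tssf <- function(tss, strand = "+", gene = paste0("g", seq_along(tss)),
                 chrom = "chr1") {
  data.table::data.table(gene_id = gene, transcript_id = paste0(gene, ".t"),
                         chrom = chrom, tss = as.integer(tss),
                         strand = strand)
}

consf <- function(mid, chrom = "chr1") {
  data.table::data.table(chrom = chrom, midpoint = as.integer(mid))
}

test_that("peak_score is the exponential distance decay", {
  expect_equal(peak_score(0), 1.0)
  expect_equal(peak_score(5000, d0 = 5000), exp(-1))
  expect_equal(peak_score(50000, d0 = 5000), exp(-10))
  expect_error(peak_score(-1), "non-negative")
})

test_that("gene scores accumulate over closest-TSS assignments", {
  tssdt <- tssf(c(0, 10000))
  sc <- score_genes(consf(2000), tssdt, d0 = 5000)
  expect_equal(sc$raw_score[sc$gene_id == "g1"], exp(-2000 / 5000))
  expect_equal(sc$raw_score[sc$gene_id == "g2"], 0)

  # equidistant midpoint: tie toward the smaller (chrom, tss, gene_id)
  sc2 <- score_genes(consf(5000), tssdt, d0 = 5000)
  expect_equal(sc2$raw_score[sc2$gene_id == "g1"], exp(-1))
  expect_equal(sc2$raw_score[sc2$gene_id == "g2"], 0)

  # two peaks at distances 0 and d0 from the same gene
  sc3 <- score_genes(consf(c(0, 5000 - 10000)), tssf(0), d0 = 5000)
  sc3 <- score_genes(consf(c(0, 5000)), tssf(c(0, 100000)), d0 = 5000)
  expect_equal(sc3$raw_score[sc3$gene_id == "g1"], 1 + exp(-1))
  expect_error(score_genes(consf(1), tssf(integer(0))), "empty")
})

test_that("score_genes equals the brute-force closest-TSS double loop", {
  set.seed(19)
  for (rep in 1:40) {
    ng <- sample(3:30, 1)
    np <- sample(1:60, 1)
    tssdt <- tssf(sample.int(1e6, ng), gene = sprintf("g%02d", 1:ng),
                  strand = sample(c("+", "-"), ng, replace = TRUE))
    cons <- consf(sample.int(1e6, np))
    d0 <- sample(c(1000, 5000, 20000), 1)
    got <- score_genes(cons, tssdt, d0)
    want <- brute_score_genes(cons, tssdt, d0)
    expect_equal(got$raw_score, unname(want[got$gene_id]))
  }
})

test_that("adding a peak never decreases any raw score", {
  set.seed(23)
  tssdt <- tssf(sample.int(1e6, 20), gene = sprintf("g%02d", 1:20))
  mids <- sample.int(1e6, 30)
  s1 <- score_genes(consf(mids), tssdt)$raw_score
  s2 <- score_genes(consf(c(mids, 123456L)), tssdt)$raw_score
  expect_true(all(s2 >= s1))
})

test_that("random background is reproducible and scale dependent", {
  cfg <- scoring_config(seed = 101L, background_reps = 5L)
  tssdt <- tssf(5000)
  b1 <- random_background(c(chr1 = 1e5), tssdt, 50L, cfg)
  b2 <- random_background(c(chr1 = 1e5), tssdt, 50L, cfg)
  expect_identical(b1, b2)
  # single gene on a single chromosome: positive random score
  expect_gt(b1$random_score, 0)
  # the gene's expected random score falls as the genome grows
  scores <- vapply(c(1e5, 1e6, 1e7), function(L) {
    random_background(c(chr1 = L), tssdt, 50L, cfg)$random_score
  }, 0)
  expect_true(all(diff(scores) < 0))
})

test_that("target selection thresholds at mean + sigma of normalized scores", {
  tab <- data.table::data.table(
    gene_id = paste0("g", 1:5),
    raw_score = c(10, 0, 0, 0, 0),
    random_score = 0,
    normalized_score = c(10, 0, 0, 0, 0))
  # population SD of {10,0,0,0,0}: mean 2, SD 4 -> only the 10 passes
  tab$is_target <- tab$normalized_score >
    mean(tab$normalized_score) + sqrt(mean((tab$normalized_score -
                                              mean(tab$normalized_score))^2))
  expect_equal(select_targets(tab), "g1")
})

test_that("gene_score_table flags targets and handles degenerate SD", {
  tssdt <- tssf(c(1000, 50000, 90000))
  cons <- consf(c(1000, 1100, 1200))  # all peaks at g1
  tab <- gene_score_table(cons, tssdt, c(chr1 = 1e5),
                          scoring_config(seed = 3L))
  expect_true(tab$is_target[tab$gene_id == "g1"])
  expect_equal(sum(tab$is_target), 1)
  expect_equal(tab$normalized_score, tab$raw_score - tab$random_score)

  # threshold_sigma 0 selects everything above the mean
  tab0 <- gene_score_table(cons, tssdt, c(chr1 = 1e5),
                           scoring_config(seed = 3L, threshold_sigma = 0))
  expect_true(all(tab0$normalized_score[tab0$is_target] >
                    mean(tab0$normalized_score)))
})

test_that("zero spread in normalized scores yields no targets, with warning", {
  # a single annotated gene: the population SD over genes is necessarily 0
  tssdt <- tssf(1000)
  cons <- consf(1000)
  expect_warning(
    tab <- gene_score_table(cons, tssdt, c(chr1 = 1e5),
                            scoring_config(seed = 3L, background_reps = 2L)),
    "no targets")
  expect_equal(select_targets(tab), character(0))
})

test_that("KS comparison of score distributions behaves", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_score_distributions(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(4)
  far <- compare_score_distributions(rnorm(1000), rnorm(1000, 5))
  expect_lt(far$p_value, 1e-10)
  disj <- compare_score_distributions(1:5, 11:15)
  expect_equal(disj$statistic, 1)
})

test_that("planted targets are recovered with high precision and recall", {
  cfg <- sim_config(seed = 1337L)
  ann <- generate_annotation(cfg)
  ps <- generate_peak_sets(ann, cfg)
  cons <- merge_union(consensus_filter(ps$peak_sets)$retained)
  tab <- gene_score_table(cons, tss_table(ann), ann$chromosomes,
                          scoring_config(seed = 1338L))
  targets <- select_targets(tab)
  truth <- ps$truth$true_target_genes
  expect_gte(mean(truth %in% targets), 0.8)  # recall
  expect_gte(mean(targets %in% truth), 0.8)  # precision
})
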