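#' Scoring configuration for distance-decay target scoring
#'
#' Each peak contributes `exp(-d / d0)` to the gene owning its closest TSS,
#' where `d` is the midpoint-to-TSS distance. The functional form is the
#' standard exponential distance decay; `d0` sets the length scale over which
#' a peak's influence falls to 1/e.
#'
#' @param d0 decay scale in bp (default 5000).
#' @param background_reps number of random-peak background repetitions
#'   averaged to stabilize the background score (default 10).
#' @param seed RNG seed for the background (default 1337).
#' @param threshold_sigma target threshold in units of population SD above
#'   the mean normalized score (default 1).
#' @return list of class `ScoringConfig`.
#' @export
scoring_config <- function(d0 = 5000, background_reps = 10L, seed = 1337L,
                           threshold_sigma = 1.0) {
  .assert(d0 > 0, "d0 must be positive")
  .assert(threshold_sigma >= 0, "threshold_sigma must be >= 0")
  structure(list(d0 = d0, background_reps = as.integer(background_reps),
                 seed = as.integer(seed), threshold_sigma = threshold_sigma),
            class = "ScoringConfig")
}

#' Distance-decay score of a single peak
#'
#' @param distance non-negative distance in bp (vectorized).
#' @param d0 decay scale in bp.
#' @return `exp(-distance / d0)`, in (0, 1].
#' @export
peak_score <- function(distance, d0 = 5000) {
  .assert(all(distance >= 0), "distance must be non-negative")
  .assert(d0 > 0, "d0 must be positive")
  exp(-distance / d0)
}

#' Cumulative closest-TSS gene scores
#'
#' Every peak is assigned to exactly one gene -- the one whose representative
#' TSS is closest to the peak midpoint (ties toward the smaller
#' (chrom, tss, gene_id) sort key) -- and each gene accumulates the sum of
#' `exp(-d / d0)` over its assigned peaks. Genes with no assigned peak score
#' zero.
#'
#' @param consensus a [merge_union()] result (needs `chrom`, `midpoint`).
#' @param tss a [tss_table()] result.
#' @param d0 decay scale in bp (default 5000).
#' @return data.table with columns `gene_id`, `raw_score`, covering every
#'   gene in `tss`.
#' @export
score_genes <- function(consensus, tss, d0 = 5000) {
  .assert(nrow(tss) > 0, "TSS table is empty")
  nearest <- nearest_tss_distance(consensus, tss)
  contrib <- if (nrow(nearest)) {
    data.table::data.table(
      gene_id = nearest$gene_id,
      s = peak_score(abs(nearest$distance), d0)
    )[, list(raw_score = sum(s)), by = "gene_id"]
  } else data.table::data.table(gene_id = character(), raw_score = numeric())
  out <- data.table::data.table(gene_id = unique(tss$gene_id))
  out <- merge(out, contrib, by = "gene_id", all.x = TRUE)
  out$raw_score[is.na(out$raw_score)] <- 0
  data.table::setorderv(out, "gene_id")
  out[]
}

#' Random-peak background gene scores
#'
#' Draws `n_peaks` positions uniformly per base over the chromosome lengths,
#' scores them with [score_genes()], and averages over
#' `config$background_reps` repetitions.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param tss a [tss_table()] result.
#' @param n_peaks number of random peaks per repetition (normally the
#'   consensus peak count).
#' @param config a [scoring_config()].
#' @return data.table with columns `gene_id`, `random_score`.
#' @export
random_background <- function(chrom_lengths, tss, n_peaks, config) {
  .assert(n_peaks >= 1, "n_peaks must be >= 1")
  probs <- chrom_lengths / sum(chrom_lengths)
  acc <- NULL
  .with_seed(config$seed, {
    for (b in seq_len(config$background_reps)) {
      chs <- sample(names(chrom_lengths), n_peaks, replace = TRUE,
                    prob = probs)
      pos <- floor(stats::runif(n_peaks) * chrom_lengths[chs])
      fake <- data.table::data.table(chrom = chs, midpoint = as.integer(pos))
      sc <- score_genes(fake, tss, config$d0)
      acc <- if (is.null(acc)) sc$raw_score else acc + sc$raw_score
    }
  })
  sc <- score_genes(data.table::data.table(chrom = character(),
                                           midpoint = integer()),
                    tss, config$d0)
  data.table::data.table(gene_id = sc$gene_id,
                         random_score = acc / config$background_reps)
}

#' Build the full gene score table
#'
#' @param consensus a [merge_union()] result.
#' @param tss a [tss_table()] result.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param config a [scoring_config()].
#' @return A `GeneScoreTable`: data.table with `gene_id`, `raw_score`,
#'   `random_score`, `normalized_score` (raw - random) and `is_target`
#'   (normalized score more than `threshold_sigma` population SDs above the
#'   mean over all genes).
#' @export
gene_score_table <- function(consensus, tss, chrom_lengths,
                             config = scoring_config()) {
  raw <- score_genes(consensus, tss, config$d0)
  bg <- random_background(chrom_lengths, tss, nrow(consensus), config)
  tab <- merge(raw, bg, by = "gene_id")
  tab$normalized_score <- tab$raw_score - tab$random_score
  mu <- mean(tab$normalized_score)
  sdev <- sqrt(mean((tab$normalized_score - mu)^2))  # population SD
  if (sdev == 0) {
    warning("all normalized scores are equal; no targets can be selected")
    tab$is_target <- FALSE
  } else {
    tab$is_target <- tab$normalized_score > mu + config$threshold_sigma * sdev
  }
  data.table::setattr(tab, "threshold",
                      if (sdev == 0) NA_real_
                      else mu + config$threshold_sigma * sdev)
  data.table::setattr(tab, "class",
                      c("GeneScoreTable", class(data.table::data.table())))
  tab[]
}

#' Select target genes from a score table
#'
#' @param table a [gene_score_table()] result.
#' @return character vector of target gene ids, sorted by descending
#'   normalized score.
#' @export
select_targets <- function(table) {
  t <- table[table$is_target == TRUE, ]
  data.table::setorderv(t, "normalized_score", order = -1L)
  t$gene_id
}

#' Compare two score distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the score distributions (e.g. raw
#' scores from observed peaks vs. scores from randomly placed peaks).
#'
#' @param scores_a,scores_b numeric vectors.
#' @return list with `statistic` and `p_value`.
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  .assert(length(scores_a) > 0 && length(scores_b) > 0,
          "both score vectors must be non-empty")
  kt <- suppressWarnings(stats::ks.test(scores_a, scores_b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Write a gene score table as TSV
#' @param table a [gene_score_table()] result.
#' @param path output file.
#' @export
gene_scores_to_tsv <- function(table, path) {
  data.table::fwrite(
    table[, c("gene_id", "raw_score", "random_score", "normalized_score",
              "is_target")],
    path, sep = "\t")
  invisible(path)
}
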