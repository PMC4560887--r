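#' Binding preference of peaks along gene segments
#'
#' Compares the observed peak count per segment class (first intron, first
#' 5'UTR exon, ...) with a null in which the same number of intragenic peaks
#' is reassigned uniformly per base over the union of representative
#' transcript bodies. Because placement is per base, longer segments attract
#' proportionally more null peaks, which is what makes the resulting fold
#' comparison length-normalized. The statistic is
#' \deqn{bp = (n - \bar n) / \sigma}
#' where \eqn{\bar n} and \eqn{\sigma} are the mean and standard deviation of
#' the null counts.
#'
#' @name binding_preference_module
NULL

# Effective (disjoint) segment lengths per (class, pooled index) cell.
# Where representative transcripts overlap, a base belongs to the gene with
# the smaller gene_rank, matching classify_position().
.effective_cell_lengths <- function(map, index_cap = 10L) {
  map <- data.table::as.data.table(map)
  map$pooled <- pmin(map$index, index_cap)
  map$eff <- as.numeric(map$end - map$start)
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    sub <- map[rows, ]
    if (data.table::uniqueN(sub$gene_rank) <= 1) next
    covered <- IRanges::IRanges()
    for (g in sort(unique(sub$gene_rank))) {
      ri <- which(sub$gene_rank == g)
      ir <- IRanges::IRanges(sub$start[ri] + 1L, sub$end[ri])
      if (length(covered)) {
        hits <- IRanges::findOverlaps(ir, covered)
        if (length(hits)) {
          ov <- IRanges::pintersect(ir[S4Vectors::queryHits(hits)],
                                    covered[S4Vectors::subjectHits(hits)])
          lost <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
          map$eff[rows[ri[as.integer(names(lost))]]] <-
            map$eff[rows[ri[as.integer(names(lost))]]] - as.numeric(lost)
        }
      }
      covered <- IRanges::reduce(c(covered, ir))
    }
  }
  cells <- map[, list(length = sum(eff)), by = c("class", "pooled")]
  data.table::setnames(cells, "pooled", "index")
  data.table::setorderv(cells, c("class", "index"))
  cells[]
}

#' Count consensus peaks per gene segment cell
#'
#' Each peak is counted once, at its midpoint, in the (class, index) cell of
#' the segment containing it; indices above `index_cap` are pooled.
#'
#' @param consensus a [merge_union()] result (or any table with `chrom` and
#'   `midpoint` columns).
#' @param map a [build_segment_map()] result.
#' @param index_cap pool segment indices above this value (default 10).
#' @return list with `counts` (data.table `class`, `index`, `n`),
#'   `n_intragenic` and `n_intergenic`.
#' @export
count_by_segment <- function(consensus, map, index_cap = 10L) {
  cls <- classify_position(map, consensus$chrom, consensus$midpoint)
  intra <- cls$class != "intergenic"
  counts <- data.table::data.table(
    class = cls$class[intra],
    index = pmin(cls$index[intra], index_cap)
  )
  counts <- counts[, list(n = .N), by = c("class", "index")]
  data.table::setorderv(counts, c("class", "index"))
  list(counts = counts[], n_intragenic = sum(intra),
       n_intergenic = sum(!intra))
}

#' Null distribution of segment-cell counts under random reassignment
#'
#' Reassigns `n_peaks` intragenic peaks uniformly per base over the union of
#' representative transcript bodies, `R` times, and tabulates the count per
#' (class, index) cell. Per-base uniform placement over disjoint cells is a
#' multinomial draw with cell probabilities proportional to effective cell
#' lengths, which is how the replicates are generated.
#'
#' @param n_peaks number of intragenic peaks to reassign.
#' @param map a [build_segment_map()] result.
#' @param R number of randomizations (default 1000).
#' @param seed RNG seed (mandatory for reproducibility; default 1337).
#' @param index_cap pool segment indices above this value (default 10).
#' @return list with `cells` (data.table `class`, `index`, `length`),
#'   `n_bar`, `sigma` (per cell), `replicates` (cells x R count matrix),
#'   `R`, `seed`.
#' @export
randomize_intragenic <- function(n_peaks, map, R = 1000L, seed = 1337L,
                                 index_cap = 10L) {
  .assert(n_peaks >= 1, "n_peaks must be >= 1")
  .assert(R >= 100, "R must be >= 100")
  cells <- .effective_cell_lengths(map, index_cap)
  total <- sum(cells$length)
  .assert(total > 0, "empty transcript union")
  reps <- .with_seed(seed,
    stats::rmultinom(R, size = n_peaks, prob = cells$length / total))
  list(
    cells = cells,
    n_bar = rowMeans(reps),
    sigma = apply(reps, 1, stats::sd),
    replicates = reps,
    R = R,
    seed = seed
  )
}

#' Binding preference statistics per segment cell
#'
#' Combines observed counts with a randomization null into
#' `bp = (n - n_bar) / sigma` per cell, with an add-one empirical p-value
#' (upper tail for enrichment, lower tail for depletion, following the sign
#' of `bp`) and the Gaussian tail probability of `bp` as a parametric
#' reference. Cells with `sigma = 0` are flagged undefined.
#'
#' @param observed a [count_by_segment()] result.
#' @param null a [randomize_intragenic()] result.
#' @return data.table with columns `class`, `index`, `n`, `n_bar`, `sigma`,
#'   `bp`, `p_emp`, `p_normal`, `undefined`; attributes `R` and `seed`.
#' @export
binding_preference <- function(observed, null) {
  res <- data.table::copy(null$cells)
  res <- merge(res, observed$counts, by = c("class", "index"), all.x = TRUE)
  res$n[is.na(res$n)] <- 0L
  res$n_bar <- null$n_bar[match(paste(res$class, res$index),
                                paste(null$cells$class, null$cells$index))]
  res$sigma <- null$sigma[match(paste(res$class, res$index),
                                paste(null$cells$class, null$cells$index))]
  res$undefined <- res$sigma == 0
  res$bp <- ifelse(res$undefined, NA_real_, (res$n - res$n_bar) / res$sigma)

  reps <- null$replicates
  key <- match(paste(res$class, res$index),
               paste(null$cells$class, null$cells$index))
  R <- null$R
  upper <- vapply(seq_len(nrow(res)), function(i) {
    sum(reps[key[i], ] >= res$n[i])
  }, 0L)
  lower <- vapply(seq_len(nrow(res)), function(i) {
    sum(reps[key[i], ] <= res$n[i])
  }, 0L)
  enrich <- is.na(res$bp) | res$bp >= 0
  res$p_emp <- ifelse(enrich, (1 + upper) / (1 + R), (1 + lower) / (1 + R))
  res$p_normal <- ifelse(res$undefined, NA_real_,
                         stats::pnorm(abs(res$bp), lower.tail = FALSE))
  data.table::setorderv(res, c("class", "index"))
  data.table::setattr(res, "R", R)
  data.table::setattr(res, "seed", null$seed)
  res[]
}

#' Write a binding preference table as TSV
#'
#' Pooled top index cells are labeled `"<cap>+"`.
#' @param result a [binding_preference()] result.
#' @param path output file.
#' @param index_cap the pooling cap used upstream (default 10).
#' @export
binding_preference_to_tsv <- function(result, path, index_cap = 10L) {
  out <- data.table::copy(result)
  mx <- max(out$index)
  out$index <- ifelse(out$index >= index_cap & mx >= index_cap,
                      paste0(index_cap, "+"), as.character(out$index))
  data.table::fwrite(
    out[, c("class", "index", "n", "n_bar", "sigma", "bp", "p_emp",
            "p_normal")],
    path, sep = "\t")
  invisible(path)
}
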