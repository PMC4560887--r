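#' Read peak calls from BED or narrowPeak
#'
#' BED coordinates are already 0-based half-open and are kept as-is. For
#' narrowPeak (BED6+4) the score column is retained and the remaining
#' statistics columns are ignored.
#'
#' @param path BED3+ or narrowPeak file.
#' @param source_label antibody / dataset label attached to every peak.
#' @return data.table with columns `chrom`, `start`, `end`, `score`,
#'   `source`, sorted by (chrom, start).
#' @export
read_peaks <- function(path, source_label) {
  .assert(file.exists(path), "peak file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty peak file: ", path)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), score = numeric(),
                                  source = character()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  .assert(ncol(dt) >= 3, "peak file must have at least 3 columns: ", path)
  peaks <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]),
    end = as.integer(dt[[3]]),
    score = if (ncol(dt) >= 5) suppressWarnings(as.numeric(dt[[5]]))
            else NA_real_,
    source = source_label
  )
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) {
    stop(sprintf("invalid peak on line %d of %s: start >= end", bad[1], path),
         call. = FALSE)
  }
  data.table::setorderv(peaks, c("chrom", "start"))
  peaks[]
}

#' Filter peaks to those reproduced across antibodies
#'
#' A peak is retained if it overlaps (shares at least one base with) at least
#' one peak from at least `min_support - 1` of the other sets. Overlap is
#' half-open interval intersection: touching intervals do not overlap.
#'
#' @param peak_sets list (length >= 2) of [read_peaks()] tables.
#' @param min_support minimum number of supporting antibodies (>= 2).
#' @return list with `retained` (data.table of original peaks that pass) and
#'   `discarded` (count of peaks dropped).
#' @export
consensus_filter <- function(peak_sets, min_support = 2L) {
  .assert(is.list(peak_sets) && length(peak_sets) >= 2,
          "need at least two peak sets")
  .assert(min_support >= 2, "min_support must be >= 2")
  .assert(min_support <= length(peak_sets),
          "min_support exceeds the number of peak sets")
  k <- length(peak_sets)
  grs <- lapply(peak_sets, .gr0)
  keep <- vector("list", k)
  for (i in seq_len(k)) {
    n_i <- nrow(peak_sets[[i]])
    if (n_i == 0) { keep[[i]] <- logical(0); next }
    supp <- rep(0L, n_i)
    for (j in seq_len(k)[-i]) {
      if (nrow(peak_sets[[j]]) == 0) next
      supp <- supp +
        (GenomicRanges::countOverlaps(grs[[i]], grs[[j]]) > 0)
    }
    keep[[i]] <- supp >= (min_support - 1L)
  }
  retained <- data.table::rbindlist(
    Map(function(p, k) p[k, ], peak_sets, keep)
  )
  discarded <- sum(vapply(keep, function(x) sum(!x), 0L))
  data.table::setorderv(retained, c("chrom", "start"))
  list(retained = retained[], discarded = discarded)
}

#' Merge retained peaks to the union consensus set
#'
#' Overlapping intervals are collapsed to their union; each consensus
#' interval records its support (number of distinct source antibodies
#' contributing an overlapping original peak) and midpoint
#' `floor((start + end) / 2)`.
#'
#' @param peaks data.table of retained peaks (from [consensus_filter()]).
#' @return A `ConsensusPeakSet`: data.table with columns `chrom`, `start`,
#'   `end`, `support`, `midpoint`; intervals per chromosome are disjoint.
#' @export
merge_union <- function(peaks) {
  .assert(nrow(peaks) > 0, "no peaks to merge")
  gr <- .gr0(peaks)
  # min.gapwidth = 0: touching half-open intervals share no base, keep apart
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(red, gr)
  h <- data.table::data.table(
    m = S4Vectors::queryHits(hits),
    source = peaks$source[S4Vectors::subjectHits(hits)]
  )
  supp <- h[, list(support = data.table::uniqueN(source)), by = "m"]
  out <- .dt0(red)
  out$support <- 0L
  out$support[supp$m] <- supp$support
  out$midpoint <- (out$start + out$end) %/% 2L
  data.table::setorderv(out, c("chrom", "start"))
  data.table::setattr(out, "class",
                      c("ConsensusPeakSet", class(data.table::data.table())))
  out[]
}

#' Correlate two peak sets over genomic bins
#'
#' The genome is tiled in fixed-width bins; for each set the per-bin
#' occupancy signal is the number of bases covered by peaks. The signed
#' Pearson correlation of the two signals is returned. (Squared correlations
#' are sometimes quoted for such comparisons, but a squared quantity cannot
#' be negative and cannot distinguish anti-correlated factors, so the signed
#' coefficient is reported.)
#'
#' @param a,b peak tables (`chrom`, `start`, `end`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 1000).
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
correlate_peak_sets <- function(a, b, chrom_lengths, bin_size = 1000L) {
  .assert(nrow(a) > 0 && nrow(b) > 0, "both peak sets must be non-empty")
  occupancy <- function(p) {
    out <- numeric(0)
    for (ch in names(chrom_lengths)) {
      nb <- ceiling(chrom_lengths[[ch]] / bin_size)
      sig <- numeric(nb)
      pc <- p[p$chrom == ch, ]
      if (nrow(pc)) {
        bins <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(start = (seq_len(nb) - 1L) * bin_size + 1L,
                               end = pmin(seq_len(nb) * bin_size,
                                          chrom_lengths[[ch]])))
        gr <- GenomicRanges::reduce(.gr0(pc))
        hits <- GenomicRanges::findOverlaps(bins, gr)
        if (length(hits)) {
          ov <- IRanges::pintersect(
            IRanges::ranges(bins)[S4Vectors::queryHits(hits)],
            IRanges::ranges(gr)[S4Vectors::subjectHits(hits)])
          w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
          sig[as.integer(names(w))] <- as.numeric(w)
        }
      }
      out <- c(out, sig)
    }
    out
  }
  sa <- occupancy(a); sb <- occupancy(b)
  .assert(stats::sd(sa) > 0 && stats::sd(sb) > 0,
          "undefined correlation: zero-variance occupancy signal")
  stats::cor(sa, sb)
}

#' Write a consensus peak set as BED4 (name = support count)
#' @param consensus a [merge_union()] result.
#' @param path output file.
#' @export
consensus_to_bed <- function(consensus, path) {
  bed <- data.table::data.table(chrom = consensus$chrom,
                                start = consensus$start,
                                end = consensus$end,
                                name = consensus$support)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
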