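#' Signed peak-to-TSS distances
#'
#' Emits the signed distance for every (peak midpoint, TSS) pair on the same
#' chromosome that lies within `max_distance`: positive downstream of the TSS
#' in the gene's reading direction, negative upstream.
#'
#' @param consensus a [merge_union()] result (needs `chrom`, `midpoint`).
#' @param tss a [tss_table()] result.
#' @param max_distance cap on |distance| in bp (default 1e6).
#' @return data.table with columns `peak` (row index into `consensus`),
#'   `gene_id`, `distance`.
#' @export
peak_tss_distances <- function(consensus, tss, max_distance = 1e6) {
  .assert(nrow(tss) > 0, "TSS table is empty")
  out <- vector("list", 0)
  for (ch in unique(consensus$chrom)) {
    pi <- which(consensus$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (!length(ti)) next
    q <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(consensus$midpoint[pi] + 1L, width = 1L))
    win <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(pmax(tss$tss[ti] - max_distance, 0) + 1,
                           tss$tss[ti] + max_distance + 1))
    hits <- GenomicRanges::findOverlaps(q, win)
    if (!length(hits)) next
    pk <- pi[S4Vectors::queryHits(hits)]
    tk <- ti[S4Vectors::subjectHits(hits)]
    raw <- consensus$midpoint[pk] - tss$tss[tk]
    d <- ifelse(tss$strand[tk] == "+", raw, -raw)
    keep <- abs(raw) <= max_distance
    out[[length(out) + 1L]] <- data.table::data.table(
      peak = pk[keep], gene_id = tss$gene_id[tk[keep]],
      distance = as.numeric(d[keep]))
  }
  res <- if (length(out)) data.table::rbindlist(out) else {
    data.table::data.table(peak = integer(), gene_id = character(),
                           distance = numeric())
  }
  data.table::setorderv(res, c("peak", "distance"))
  res[]
}

#' Nearest-TSS signed distance per peak
#'
#' Reduces the all-pairs distance list to one entry per peak: the TSS with
#' the smallest |distance| (ties toward the gene with the smaller
#' (chrom, tss, gene_id) sort key). Peaks on chromosomes without any TSS are
#' omitted.
#'
#' @inheritParams peak_tss_distances
#' @return data.table with columns `peak`, `gene_id`, `distance`.
#' @export
nearest_tss_distance <- function(consensus, tss) {
  .assert(nrow(tss) > 0, "TSS table is empty")
  ts <- data.table::copy(tss)
  data.table::setorderv(ts, c("chrom", "tss", "gene_id"))
  out <- vector("list", 0)
  for (ch in unique(consensus$chrom)) {
    pi <- which(consensus$chrom == ch)
    tc <- ts[ts$chrom == ch, ]
    if (!nrow(tc)) next
    mids <- consensus$midpoint[pi]
    # nearest by binary search over sorted TSS positions
    lo <- findInterval(mids, tc$tss)
    hi <- pmin(lo + 1L, nrow(tc))
    lo <- pmax(lo, 1L)
    dlo <- abs(mids - tc$tss[lo])
    dhi <- abs(mids - tc$tss[hi])
    # tie (dlo == dhi) goes to the smaller (tss, gene_id), i.e. lo
    pick <- ifelse(dhi < dlo, hi, lo)
    # co-located TSSs: route to the first row (smallest gene_id) at that tss
    pick <- match(tc$tss[pick], tc$tss)
    raw <- mids - tc$tss[pick]
    d <- ifelse(tc$strand[pick] == "+", raw, -raw)
    out[[length(out) + 1L]] <- data.table::data.table(
      peak = pi, gene_id = tc$gene_id[pick], distance = as.numeric(d))
  }
  res <- if (length(out)) data.table::rbindlist(out) else {
    data.table::data.table(peak = integer(), gene_id = character(),
                           distance = numeric())
  }
  data.table::setorderv(res, "peak")
  res[]
}

#' Histogram of signed peak-TSS distances
#'
#' Bins are centered so that one bin is symmetric around 0 (edges at
#' ..., -bin/2, +bin/2, ...), which keeps the promoter-proximal accumulation
#' in a single central bin instead of splitting it at 0.
#'
#' @param distances numeric vector of signed distances (bp).
#' @param bin_size bin width in bp (default 1000).
#' @param max_distance range cap (default 1e6).
#' @return data.table with columns `mid` (bin center), `count`.
#' @export
distance_histogram <- function(distances, bin_size = 1000L,
                               max_distance = 1e6) {
  d <- distances[abs(distances) <= max_distance]
  centers <- round(d / bin_size) * bin_size
  tab <- table(centers)
  res <- data.table::data.table(mid = as.numeric(names(tab)),
                                count = as.integer(tab))
  data.table::setorderv(res, "mid")
  res[]
}

#' Fraction of peaks with a TSS within a window
#'
#' @param nearest a [nearest_tss_distance()] result (or a numeric vector of
#'   per-peak nearest signed distances).
#' @param window half-width in bp (default 1000).
#' @return fraction in [0, 1].
#' @export
fraction_within <- function(nearest, window = 1000) {
  d <- if (is.numeric(nearest)) nearest else nearest$distance
  .assert(length(d) > 0, "empty peak set")
  mean(abs(d) <= window)
}
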