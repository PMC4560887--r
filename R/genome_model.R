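#' Genome annotation model
#'
#' A `GenomeAnnotation` holds chromosome lengths and a gene -> transcript ->
#' exon/CDS hierarchy, with one representative transcript chosen per gene
#' (the transcript of greatest genomic span; ties broken toward the
#' lexicographically smallest transcript id). All coordinates are stored
#' 0-based half-open; GTF/GFF3 input (1-based inclusive) is converted on read.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#' @param cds data.frame with columns `transcript_id`, `start`, `end`
#'   (one row per coding transcript, spanning the full coding region).
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(chromosomes, transcripts, exons, cds = NULL) {
  .assert(length(chromosomes) > 0 && !is.null(names(chromosomes)),
          "chromosomes must be a named vector of lengths")
  .assert(!anyDuplicated(names(chromosomes)), "chromosome names must be unique")
  tx <- data.table::as.data.table(transcripts)
  ex <- data.table::as.data.table(exons)
  cd <- if (is.null(cds) || nrow(cds) == 0) {
    data.table::data.table(transcript_id = character(), start = integer(),
                           end = integer())
  } else data.table::as.data.table(cds)

  .assert(!anyDuplicated(tx$transcript_id), "transcript ids must be unique")
  .assert(all(tx$chrom %in% names(chromosomes)),
          "transcript on unknown chromosome")
  .assert(all(tx$strand %in% c("+", "-")), "strand must be '+' or '-'")
  lens <- chromosomes[tx$chrom]
  .assert(all(tx$start >= 0 & tx$end <= lens & tx$start < tx$end),
          "transcript interval outside chromosome bounds")

  # exon containment and disjointness per transcript
  exv <- merge(ex, tx[, c("transcript_id", "start", "end")],
               by = "transcript_id", suffixes = c("", ".tx"))
  .assert(all(exv$start >= exv$start.tx & exv$end <= exv$end.tx),
          "exon outside its transcript span")
  data.table::setorderv(ex, c("transcript_id", "start"))
  ovl <- ex[, any(start[-1] < end[-length(end)]) && .N > 1,
            by = "transcript_id"]
  .assert(!any(ovl$V1 %in% TRUE), "overlapping exons within a transcript")

  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  ann <- structure(
    list(chromosomes = chromosomes, transcripts = tx, exons = ex, cds = cd),
    class = "GenomeAnnotation"
  )
  ann$representative <- select_representatives(ann)
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf(
    "GenomeAnnotation: %d chromosome(s), %d gene(s), %d transcript(s)\n",
    length(x$chromosomes), length(unique(x$transcripts$gene_id)),
    nrow(x$transcripts)))
  invisible(x)
}

# Parse one attribute key out of a GTF ('key "value"') or GFF3 ('key=value')
# attribute string; NA when absent.
.attr_field <- function(attrs, key, gff3) {
  if (gff3) {
    pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
  } else {
    pat <- paste0("(?:^|;)\\s*", key, "\\s+\"([^\"]+)\"")
  }
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, "")
}

#' Read a GTF or GFF3 annotation
#'
#' Accepts GTF (attributes `gene_id`/`transcript_id`) or GFF3 (`ID`/`Parent`)
#' with gene, transcript (or mRNA) and exon records, plus optional CDS
#' records. Chromosome lengths are taken from `##sequence-region` directives
#' when present and otherwise inferred as the maximum end coordinate per
#' chromosome. 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path path to a GTF or GFF3 file.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(path) {
  .assert(file.exists(path), "annotation file not found: ", path)
  lines <- readLines(path)
  seqreg <- grep("^##sequence-region", lines, value = TRUE)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))

  nfield <- lengths(strsplit(lines[body_idx], "\t", fixed = TRUE))
  bad <- which(nfield < 9)
  if (length(bad)) {
    stop(sprintf("malformed annotation line %d: expected 9 tab-separated fields, got %d",
                 body_idx[bad[1]], nfield[bad[1]]), call. = FALSE)
  }
  f <- data.table::as.data.table(
    do.call(rbind, strsplit(lines[body_idx], "\t", fixed = TRUE))[, 1:9,
                                                                  drop = FALSE])
  data.table::setnames(f, c("chrom", "source", "type", "start", "end",
                            "score", "strand", "frame", "attrs"))
  f$start <- suppressWarnings(as.integer(f$start))
  f$end <- suppressWarnings(as.integer(f$end))
  if (anyNA(f$start) || anyNA(f$end)) {
    stop(sprintf("malformed annotation line %d: non-numeric coordinates",
                 body_idx[which(is.na(f$start) | is.na(f$end))[1]]),
         call. = FALSE)
  }

  gff3 <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "##gff-version 3")) ||
    (!any(grepl("\"", f$attrs, fixed = TRUE)) && any(grepl("=", f$attrs,
                                                           fixed = TRUE)))

  is_tx <- f$type %in% c("transcript", "mRNA")
  is_ex <- f$type == "exon"
  is_cds <- f$type == "CDS"
  .assert(any(is_tx), "no transcript/mRNA records in ", path)
  .assert(any(is_ex), "no exon records in ", path)

  if (gff3) {
    tx_id <- .attr_field(f$attrs, "ID", TRUE)
    parent <- .attr_field(f$attrs, "Parent", TRUE)
    tx <- data.table::data.table(
      transcript_id = tx_id[is_tx], gene_id = parent[is_tx],
      chrom = f$chrom[is_tx], strand = f$strand[is_tx],
      start = f$start[is_tx] - 1L, end = f$end[is_tx]
    )
    ex_parent <- parent
    ex <- data.table::data.table(transcript_id = ex_parent[is_ex],
                                 start = f$start[is_ex] - 1L,
                                 end = f$end[is_ex])
    cds_raw <- data.table::data.table(transcript_id = ex_parent[is_cds],
                                      start = f$start[is_cds] - 1L,
                                      end = f$end[is_cds])
  } else {
    gene_id <- .attr_field(f$attrs, "gene_id", FALSE)
    tx_id <- .attr_field(f$attrs, "transcript_id", FALSE)
    tx <- data.table::data.table(
      transcript_id = tx_id[is_tx], gene_id = gene_id[is_tx],
      chrom = f$chrom[is_tx], strand = f$strand[is_tx],
      start = f$start[is_tx] - 1L, end = f$end[is_tx]
    )
    ex <- data.table::data.table(transcript_id = tx_id[is_ex],
                                 start = f$start[is_ex] - 1L,
                                 end = f$end[is_ex])
    cds_raw <- data.table::data.table(transcript_id = tx_id[is_cds],
                                      start = f$start[is_cds] - 1L,
                                      end = f$end[is_cds])
  }
  .assert(!anyNA(tx$transcript_id) && !anyNA(tx$gene_id),
          "transcript record missing id attributes")
  # collapse per-exon CDS records to the genomic span of the coding region
  cds <- if (nrow(cds_raw)) {
    cds_raw[, list(start = min(start), end = max(end)), by = "transcript_id"]
  } else NULL

  if (length(seqreg)) {
    parts <- strsplit(trimws(seqreg), "\\s+")
    chromosomes <- vapply(parts, function(p) as.numeric(p[4]), 0)
    names(chromosomes) <- vapply(parts, function(p) p[2], "")
  } else {
    mx <- f[, list(len = max(end)), by = "chrom"]
    chromosomes <- stats::setNames(as.numeric(mx$len), mx$chrom)
  }
  genome_annotation(chromosomes, tx, ex, cds)
}

#' Pick the representative transcript of each gene
#'
#' The representative is the transcript with the greatest genomic span
#' (end - start), not summed exon length; ties are broken toward the
#' lexicographically smallest transcript id.
#'
#' @param annotation a [genome_annotation()] object (or its transcript table).
#' @return data.table with columns `gene_id`, `transcript_id`.
#' @export
select_representatives <- function(annotation) {
  tx <- if (inherits(annotation, "GenomeAnnotation")) {
    annotation$transcripts
  } else data.table::as.data.table(annotation)
  .assert(nrow(tx) > 0, "no transcripts to select from")
  tx <- data.table::copy(tx)
  tx$span <- tx$end - tx$start
  data.table::setorderv(tx, c("gene_id", "span", "transcript_id"),
                        order = c(1L, -1L, 1L))
  tx[!duplicated(tx$gene_id), c("gene_id", "transcript_id")]
}

# Segment one representative transcript into UTR5/CDS/UTR3 exon pieces and
# introns; exons of non-coding transcripts become class "noncoding_exon".
.segment_transcript <- function(exons, cds_start, cds_end, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (is.na(cds_start)) {
      pieces[[length(pieces) + 1L]] <- c(s, e, 0L)  # 0 = noncoding
    } else {
      if (s < cds_start) {
        pieces[[length(pieces) + 1L]] <- c(s, min(e, cds_start), -1L) # left UTR
      }
      ms <- max(s, cds_start); me <- min(e, cds_end)
      if (ms < me) pieces[[length(pieces) + 1L]] <- c(ms, me, 1L)     # CDS
      if (e > cds_end) {
        pieces[[length(pieces) + 1L]] <- c(max(s, cds_end), e, 2L)    # right UTR
      }
    }
  }
  p <- do.call(rbind, pieces)
  if (!is.na(cds_start)) {
    # the coding span may cross introns, but both its endpoints must be exonic
    in_exon <- function(pos) any(exons$start <= pos & pos < exons$end)
    if (!(cds_start < cds_end && in_exon(cds_start) && in_exon(cds_end - 1L))) {
      stop("CDS not contained in the exon union", call. = FALSE)
    }
  }
  cls <- character(nrow(p))
  cls[p[, 3] == 0L] <- "noncoding_exon"
  cls[p[, 3] == 1L] <- "CDS_exon"
  if (strand == "+") {
    cls[p[, 3] == -1L] <- "UTR5_exon"
    cls[p[, 3] == 2L] <- "UTR3_exon"
  } else {
    cls[p[, 3] == -1L] <- "UTR3_exon"
    cls[p[, 3] == 2L] <- "UTR5_exon"
  }
  # introns fill the gaps between consecutive exons
  segs <- data.table::data.table(start = p[, 1], end = p[, 2], class = cls)
  if (nrow(exons) > 1) {
    ints <- data.table::data.table(
      start = exons$end[-nrow(exons)], end = exons$start[-1],
      class = "intron"
    )
    ints <- ints[ints$end > ints$start, ]
    segs <- rbind(segs, ints)
  }
  data.table::setorderv(segs, "start")
  # index 1..k per class in transcript 5'->3' order
  segs$index <- NA_integer_
  for (cl in unique(segs$class)) {
    idx <- which(segs$class == cl)
    if (strand == "-") idx <- rev(idx)
    segs$index[idx] <- seq_along(idx)
  }
  segs
}

#' Build the segment map of representative transcripts
#'
#' Exonic bases of each gene's representative transcript are split into
#' 5'UTR, CDS and 3'UTR exon segments by the coding region and strand; gaps
#' between exons are emitted as introns. Within each class, segments are
#' indexed 1..k in transcript 5'->3' order. Transcripts without a CDS record
#' contribute "noncoding_exon" segments (kept out of the four-class binding
#' preference analysis but still intragenic).
#'
#' @param annotation a [genome_annotation()] object.
#' @return A `SegmentMap`: data.table with columns `chrom`, `start`, `end`,
#'   `strand`, `class`, `index`, `gene_id`, `transcript_id`, `gene_rank`
#'   (priority used to resolve positions covered by two genes).
#' @export
build_segment_map <- function(annotation) {
  .assert(inherits(annotation, "GenomeAnnotation"),
          "annotation must be a GenomeAnnotation")
  rep <- annotation$representative
  tx <- merge(rep, annotation$transcripts, by = c("gene_id", "transcript_id"))
  cds <- annotation$cds
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ti <- tx$transcript_id[i]
    ex <- annotation$exons[annotation$exons$transcript_id == ti, ]
    ci <- cds[cds$transcript_id == ti, ]
    segs <- .segment_transcript(
      as.data.frame(ex),
      if (nrow(ci)) ci$start[1] else NA_integer_,
      if (nrow(ci)) ci$end[1] else NA_integer_,
      tx$strand[i]
    )
    segs$chrom <- tx$chrom[i]
    segs$strand <- tx$strand[i]
    segs$gene_id <- tx$gene_id[i]
    segs$transcript_id <- ti
    out[[i]] <- segs
  }
  map <- data.table::rbindlist(out)
  # position-assignment priority: smaller (chrom, transcript start, gene_id)
  data.table::setorderv(tx, c("chrom", "start", "gene_id"))
  tx$gene_rank <- seq_len(nrow(tx))
  map <- merge(map, tx[, c("gene_id", "gene_rank")], by = "gene_id")
  data.table::setorderv(map, c("chrom", "start", "end"))
  data.table::setcolorder(map, c("chrom", "start", "end", "strand", "class",
                                 "index", "gene_id", "transcript_id",
                                 "gene_rank"))
  data.table::setattr(map, "chromosomes", annotation$chromosomes)
  data.table::setattr(map, "class",
                      c("SegmentMap", class(data.table::data.table())))
  map[]
}

#' Classify genomic positions against a segment map
#'
#' Vectorized point lookup. A position covered by segments of two
#' overlapping representative transcripts is assigned to the gene with the
#' smaller (chrom, transcript start, gene_id) sort key; such collisions are
#' reported with a message.
#'
#' @param map a [build_segment_map()] result.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions (recycled against `chrom`).
#' @return data.table with one row per query: `class` (a segment class or
#'   `"intergenic"`), `index`, `gene_id`.
#' @export
classify_position <- function(map, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  s <- .gr0(map)
  hits <- GenomicRanges::findOverlaps(q, s)
  h <- data.table::data.table(
    q = S4Vectors::queryHits(hits),
    s = S4Vectors::subjectHits(hits)
  )
  res <- data.table::data.table(
    class = rep("intergenic", n),
    index = rep(NA_integer_, n),
    gene_id = rep(NA_character_, n)
  )
  if (nrow(h)) {
    h$gene_rank <- map$gene_rank[h$s]
    ng <- h[, list(k = data.table::uniqueN(gene_rank)), by = "q"]
    ncoll <- sum(ng$k > 1)
    if (ncoll > 0) {
      message(ncoll, " position(s) fell in overlapping transcripts; ",
              "assigned to the first gene in sorted order")
    }
    data.table::setorderv(h, c("q", "gene_rank", "s"))
    h <- h[!duplicated(h$q), ]
    res$class[h$q] <- map$class[h$s]
    res$index[h$q] <- map$index[h$s]
    res$gene_id[h$q] <- map$gene_id[h$s]
  }
  res
}

#' TSS table of representative transcripts
#'
#' @param annotation a [genome_annotation()] object.
#' @return data.table with columns `gene_id`, `transcript_id`, `chrom`,
#'   `tss` (0-based position of the first transcribed base), `strand`.
#' @export
tss_table <- function(annotation) {
  .assert(inherits(annotation, "GenomeAnnotation"),
          "annotation must be a GenomeAnnotation")
  tx <- merge(annotation$representative, annotation$transcripts,
              by = c("gene_id", "transcript_id"))
  out <- tx[, c("gene_id", "transcript_id", "chrom", "tss", "strand")]
  data.table::setorderv(out, c("chrom", "tss", "gene_id"))
  out[]
}

#' Export a segment map as BED6
#'
#' Intervals are written as-is (BED shares the 0-based half-open convention);
#' the name field is `class:index:gene_id`.
#' @param map a [build_segment_map()] result.
#' @param path output file.
#' @export
segment_map_to_bed <- function(map, path) {
  bed <- data.table::data.table(
    chrom = map$chrom, start = map$start, end = map$end,
    name = paste(map$class, map$index, map$gene_id, sep = ":"),
    score = 0L, strand = map$strand
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export a TSS table as BED6
#' @param tss a [tss_table()] result.
#' @param path output file.
#' @export
tss_to_bed <- function(tss, path) {
  bed <- data.table::data.table(
    chrom = tss$chrom, start = tss$tss, end = tss$tss + 1L,
    name = tss$gene_id, score = 0L, strand = tss$strand
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
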