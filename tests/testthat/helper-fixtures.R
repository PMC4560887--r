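# Shared fixtures, built in code.

# The canonical two-exon gene: exons [0,100) and [200,300), CDS [50,250).
toy_annotation <- function(strand = "+") {
  genome_annotation(
    chromosomes = c(chr1 = 1000),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1",
                             chrom = "chr1", strand = strand,
                             start = 0L, end = 300L),
    exons = data.frame(transcript_id = c("t1", "t1"),
                       start = c(0L, 200L), end = c(100L, 300L)),
    cds = data.frame(transcript_id = "t1", start = 50L, end = 250L)
  )
}

# Hand-built segment map: one 100 bp 5'UTR exon followed by a 900 bp intron.
toy_exon_intron_map <- function() {
  map <- data.table::data.table(
    chrom = "chr1", start = c(0L, 100L), end = c(100L, 1000L),
    strand = "+", class = c("UTR5_exon", "intron"), index = c(1L, 1L),
    gene_id = "g1", transcript_id = "g1.t1", gene_rank = 1L
  )
  data.table::setattr(map, "chromosomes", c(chr1 = 1000))
  data.table::setattr(map, "class",
                      c("SegmentMap", class(data.table::data.table())))
  map
}

write_gtf_lines <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

write_bed <- function(df, ext = ".bed") {
  path <- tempfile(fileext = ext)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  path
}

peak_dt <- function(chrom, start, end, source = "ab1") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), score = NA_real_,
                         source = source)
}

# random peak tables for oracle comparisons
random_peak_set <- function(n, space = 10000L, wmax = 30L, source = "ab") {
  s <- sample.int(space - wmax, n, replace = TRUE)
  peak_dt("chr1", s, s + sample.int(wmax, n, replace = TRUE), source)
}

# Brute-force per-base consensus + union oracle over a small coordinate space.
brute_consensus_union <- function(peak_sets, min_support = 2L,
                                  space = 10000L) {
  k <- length(peak_sets)
  cov <- lapply(peak_sets, function(p) {
    v <- logical(space)
    for (i in seq_len(nrow(p))) v[(p$start[i] + 1L):p$end[i]] <- TRUE
    v
  })
  retained <- vector("list", k)
  for (i in seq_len(k)) {
    p <- peak_sets[[i]]
    keep <- logical(nrow(p))
    for (r in seq_len(nrow(p))) {
      idx <- (p$start[r] + 1L):p$end[r]
      nsup <- sum(vapply(seq_len(k)[-i], function(j) any(cov[[j]][idx]),
                         logical(1)))
      keep[r] <- nsup >= (min_support - 1L)
    }
    retained[[i]] <- p[keep, ]
  }
  ret <- data.table::rbindlist(retained)
  # components under >=1-shared-base overlap; touching intervals stay apart
  iv <- data.table::data.table(start = integer(0), end = integer(0))
  if (nrow(ret)) {
    ord <- order(ret$start, ret$end)
    rs <- ret$start[ord]; re <- ret$end[ord]
    cs <- rs[1]; ce <- re[1]
    starts <- integer(0); ends <- integer(0)
    for (i in seq_along(rs)[-1]) {
      if (rs[i] < ce) {
        ce <- max(ce, re[i])
      } else {
        starts <- c(starts, cs); ends <- c(ends, ce)
        cs <- rs[i]; ce <- re[i]
      }
    }
    iv <- data.table::data.table(start = c(starts, cs), end = c(ends, ce))
  }
  list(retained = ret, union = iv,
       discarded = sum(vapply(peak_sets, nrow, 0L)) - nrow(ret))
}

# Brute-force closest-TSS scoring oracle.
brute_score_genes <- function(consensus, tss, d0) {
  consensus <- as.data.frame(consensus)
  tss <- as.data.frame(tss)  # avoid data.table scoping on the tss column
  raw <- stats::setNames(numeric(length(unique(tss$gene_id))),
                         sort(unique(tss$gene_id)))
  for (i in seq_len(nrow(consensus))) {
    tc <- tss[tss$chrom == consensus$chrom[i], ]
    if (!nrow(tc)) next
    d <- abs(consensus$midpoint[i] - tc$tss)
    cand <- which(d == min(d))
    ord <- order(tc$tss[cand], tc$gene_id[cand])
    g <- tc$gene_id[cand[ord[1]]]
    raw[g] <- raw[g] + exp(-min(d) / d0)
  }
  raw
}

# Brute-force IUPAC scanning oracle via regular expressions.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    alt <- strsplit(map[[ch]], "")[[1]]
    if (length(alt) == 1) alt else paste0("[", paste(alt, collapse = ""), "]")
  }, ""), collapse = "")
}

brute_scan <- function(seq, pattern, both_strands = TRUE) {
  starts_of <- function(s, pat) {
    re <- iupac_regex(pat)
    out <- integer(0)
    L <- nchar(s); w <- nchar(pat)
    if (L < w) return(out)
    for (i in seq_len(L - w + 1L)) {
      win <- substr(s, i, i + w - 1L)
      if (!grepl("N", win, fixed = TRUE) && grepl(re, win)) {
        out <- c(out, i)
      }
    }
    out
  }
  st <- starts_of(seq, pattern)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    st <- union(st, starts_of(seq, rc))
  }
  length(st)
}

dinuc_counts <- function(s) {
  x <- strsplit(s, "")[[1]]
  if (length(x) < 2) return(table(character(0)))
  table(paste0(x[-length(x)], x[-1]))
}
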