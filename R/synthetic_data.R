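#' Simulation configuration
#'
#' Defaults describe a compact genome that preserves the structure the
#' pipeline assumes: a few megabase-scale chromosomes tiled with
#' multi-exon protein-coding genes, a subset of genes designated true
#' targets, true binding sites placed with Laplace-distributed offsets
#' around target TSSs (reproducing the sharp promoter-proximal
#' accumulation), three antibody datasets that each detect a true site with
#' probability `detection_prob` plus independent uniform noise peaks (5x the
#' true site count), and an extended E-box planted under half of the true
#' sites.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total genes.
#' @param exons_per_gene length-2 range of exon counts per gene.
#' @param exon_length length-2 range of exon lengths (bp).
#' @param intron_length length-2 range of intron lengths (bp).
#' @param n_true_sites number of true binding sites.
#' @param frac_target_genes fraction of genes designated true targets.
#' @param tss_offset_scale Laplace scale b (bp) of site offsets around TSSs.
#' @param n_antibodies number of antibody datasets.
#' @param detection_prob per-antibody probability of emitting each true site.
#' @param n_noise_peaks uniform noise peaks per antibody.
#' @param peak_width length-2 range of emitted peak widths (bp).
#' @param motif_plant_rate probability of planting an extended E-box under a
#'   true site.
#' @param seed master RNG seed; each generator stage derives its own
#'   sub-seed so stages are independently reproducible.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chrom_length = 1e7,
                       n_genes = 500L,
                       exons_per_gene = c(3L, 6L),
                       exon_length = c(120L, 400L),
                       intron_length = c(2000L, 8000L),
                       n_true_sites = 150L,
                       frac_target_genes = 0.1,
                       tss_offset_scale = 200,
                       n_antibodies = 3L,
                       detection_prob = 0.8,
                       n_noise_peaks = 750L,
                       peak_width = c(150L, 400L),
                       motif_plant_rate = 0.5,
                       seed = 1337L) {
  .assert(detection_prob >= 0 && detection_prob <= 1,
          "detection_prob must be in [0, 1]")
  .assert(motif_plant_rate >= 0 && motif_plant_rate <= 1,
          "motif_plant_rate must be in [0, 1]")
  .assert(frac_target_genes > 0 && frac_target_genes <= 1,
          "frac_target_genes must be in (0, 1]")
  .assert(all(c(chrom_length, exon_length, intron_length, peak_width) > 0),
          "lengths must be positive")
  structure(as.list(environment()), class = "SimConfig")
}

.runif_int <- function(n, range) {
  as.integer(range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1L)))
}

#' Generate a synthetic genome annotation
#'
#' Genes are laid out without overlap, round-robin across chromosomes, with
#' alternating exon/intron structure; the CDS starts inside the first exon
#' and ends inside the last one, so every gene has at least one 5'UTR, CDS
#' and 3'UTR exon segment. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()] object.
#' @export
generate_annotation <- function(config) {
  .with_seed(config$seed, {
    n <- config$n_genes
    k <- .runif_int(n, config$exons_per_gene)
    exon_lens <- lapply(k, function(ki) .runif_int(ki, config$exon_length))
    intron_lens <- lapply(k, function(ki)
      if (ki > 1) .runif_int(ki - 1L, config$intron_length) else integer(0))
    spans <- vapply(seq_len(n), function(i)
      sum(exon_lens[[i]]) + sum(intron_lens[[i]]), 0)
    chrom_of <- rep_len(seq_len(config$n_chromosomes), n)
    strands <- sample(c("+", "-"), n, replace = TRUE)

    chroms <- stats::setNames(rep(config$chrom_length,
                                  config$n_chromosomes),
                              paste0("chr", seq_len(config$n_chromosomes)))
    tx_list <- vector("list", n)
    ex_list <- vector("list", n)
    cds_list <- vector("list", n)
    for (c_i in seq_len(config$n_chromosomes)) {
      gi <- which(chrom_of == c_i)
      total <- sum(spans[gi])
      slack <- config$chrom_length - total - (length(gi) + 1L)
      if (slack < 0) {
        stop("genes cannot fit on the configured chromosomes", call. = FALSE)
      }
      gaps <- as.vector(stats::rmultinom(
        1, slack, rep(1 / (length(gi) + 1L), length(gi) + 1L))) + 1L
      pos <- gaps[1]
      for (j in seq_along(gi)) {
        i <- gi[j]
        gid <- sprintf("G%04d", i)
        tid <- paste0(gid, ".t1")
        starts <- pos + c(0L, cumsum(exon_lens[[i]][-k[i]] +
                                       intron_lens[[i]]))
        ends <- starts + exon_lens[[i]]
        # CDS interior to the first and last exon
        cs <- starts[1] + .runif_int(1, c(1L, exon_lens[[i]][1] - 1L))
        ce <- starts[k[i]] + .runif_int(1, c(1L, exon_lens[[i]][k[i]] - 1L))
        if (k[i] == 1L) {
          pts <- sort(starts[1] + sample.int(exon_lens[[i]][1] - 1L, 2L))
          cs <- pts[1]; ce <- pts[2]
        }
        tx_list[[i]] <- data.table::data.table(
          transcript_id = tid, gene_id = gid,
          chrom = names(chroms)[c_i], strand = strands[i],
          start = pos, end = pos + as.integer(spans[i]))
        ex_list[[i]] <- data.table::data.table(
          transcript_id = tid, start = starts, end = ends)
        cds_list[[i]] <- data.table::data.table(
          transcript_id = tid, start = cs, end = ce)
        pos <- pos + as.integer(spans[i]) + gaps[j + 1L]
      }
    }
    genome_annotation(chroms,
                      data.table::rbindlist(tx_list),
                      data.table::rbindlist(ex_list),
                      data.table::rbindlist(cds_list))
  })
}

#' Generate per-antibody peak sets with known truth
#'
#' True sites are placed with Laplace(`tss_offset_scale`) offsets around the
#' TSSs of the designated target genes (every target gets at least one
#' site). Each antibody emits each true site with `detection_prob`, with its
#' own width draw and a small positional jitter, plus `n_noise_peaks`
#' intervals placed uniformly over the genome.
#'
#' @param annotation a [genome_annotation()] object.
#' @param config a [sim_config()].
#' @return list with `peak_sets` (named list of peak tables) and `truth`
#'   (list: `true_sites`, `true_target_genes`, `provenance`).
#' @export
generate_peak_sets <- function(annotation, config) {
  tssdt <- tss_table(annotation)
  chroms <- annotation$chromosomes
  .with_seed(config$seed + 1L, {
    genes <- sort(unique(tssdt$gene_id))
    n_targets <- max(1L, round(config$frac_target_genes * length(genes)))
    targets <- sort(sample(genes, n_targets))
    ns <- config$n_true_sites
    gene_of_site <- if (ns <= n_targets) sample(targets, ns) else {
      c(targets, sample(targets, ns - n_targets, replace = TRUE))
    }
    ti <- match(gene_of_site, tssdt$gene_id)
    offs <- round(.rlaplace(ns, config$tss_offset_scale))
    w <- .runif_int(ns, config$peak_width)
    mid <- tssdt$tss[ti] + as.integer(offs)
    lens <- chroms[tssdt$chrom[ti]]
    mid <- pmin(pmax(mid, w %/% 2L + 1L), as.integer(lens) - w %/% 2L - 1L)
    true_sites <- data.table::data.table(
      site_id = seq_len(ns),
      chrom = tssdt$chrom[ti],
      start = as.integer(mid - w %/% 2L),
      end = as.integer(mid - w %/% 2L + w),
      midpoint = as.integer(mid),
      gene_id = gene_of_site
    )

    peak_sets <- list()
    prov <- list()
    for (a in seq_len(config$n_antibodies)) {
      lab <- paste0("ab", a)
      det <- stats::runif(ns) < config$detection_prob
      true_pk <- data.table::data.table(
        chrom = true_sites$chrom[det],
        start = true_sites$start[det],
        end = true_sites$end[det],
        origin = "true",
        site_id = true_sites$site_id[det]
      )
      nn <- config$n_noise_peaks
      nw <- .runif_int(nn, config$peak_width)
      nch <- sample(names(chroms), nn, replace = TRUE,
                    prob = chroms / sum(chroms))
      nst <- floor(stats::runif(nn) * (chroms[nch] - nw))
      noise_pk <- data.table::data.table(
        chrom = nch, start = as.integer(nst),
        end = as.integer(nst + nw), origin = "noise",
        site_id = NA_integer_
      )
      all_pk <- rbind(true_pk, noise_pk)
      all_pk$source <- lab
      data.table::setorderv(all_pk, c("chrom", "start"))
      prov[[lab]] <- data.table::copy(all_pk)
      all_pk$score <- NA_real_
      peak_sets[[lab]] <- all_pk[, c("chrom", "start", "end", "score",
                                     "source")]
    }
    list(
      peak_sets = peak_sets,
      truth = list(true_sites = true_sites, true_target_genes = targets,
                   provenance = prov)
    )
  })
}

# a concrete instance of the extended E-box CA(G/T)(C/A)TG(G/T)
.sample_ebox <- function() {
  paste0("CA", sample(c("G", "T"), 1), sample(c("C", "A"), 1), "TG",
         sample(c("G", "T"), 1))
}

#' Generate genome sequence with planted motifs
#'
#' Uniform random nucleotides per chromosome; under each true site, with
#' probability `motif_plant_rate`, one concrete instance of the extended
#' E-box CA(G/T)(C/A)TG(G/T) is written at a uniform position inside the
#' site. Deterministic per seed.
#'
#' @param annotation a [genome_annotation()] object.
#' @param truth the `truth` element of [generate_peak_sets()].
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`) and `planted_motifs`
#'   (data.table `chrom`, `pos`, `instance`).
#' @export
generate_sequences <- function(annotation, truth, config) {
  chroms <- annotation$chromosomes
  .with_seed(config$seed + 2L, {
    seqs <- lapply(names(chroms), function(ch) {
      paste(sample(c("A", "C", "G", "T"), chroms[[ch]], replace = TRUE),
            collapse = "")
    })
    names(seqs) <- names(chroms)
    ts <- truth$true_sites
    plant <- stats::runif(nrow(ts)) < config$motif_plant_rate
    planted <- list()
    for (i in which(plant)) {
      inst <- .sample_ebox()
      lo <- ts$start[i]; hi <- ts$end[i] - nchar(inst)
      if (hi < lo) next
      p <- lo + .runif_int(1, c(0L, hi - lo))  # 0-based plant position
      ch <- ts$chrom[i]
      substr(seqs[[ch]], p + 1L, p + nchar(inst)) <- inst
      planted[[length(planted) + 1L]] <- data.table::data.table(
        chrom = ch, pos = p, instance = inst, site_id = ts$site_id[i])
    }
    # overlapping sites can overwrite an earlier plant; keep intact ones only
    if (length(planted)) {
      planted <- Filter(function(pl) {
        substr(seqs[[pl$chrom]], pl$pos + 1L,
               pl$pos + nchar(pl$instance)) == pl$instance
      }, planted)
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    list(
      genome = genome,
      planted_motifs = if (length(planted)) data.table::rbindlist(planted)
        else data.table::data.table(chrom = character(), pos = integer(),
                                    instance = character(),
                                    site_id = integer())
    )
  })
}

#' Generate gene category lists correlated with the truth
#'
#' Emulates zone-specific differentially-expressed-gene lists: each category
#' draws a configurable fraction of its members from the true target genes
#' and the rest from non-targets.
#'
#' @param annotation a [genome_annotation()] object.
#' @param truth the `truth` element of [generate_peak_sets()].
#' @param sizes named integer vector of category sizes; by default sized
#'   relative to the gene count (10%, 16% and 14%).
#' @param target_frac named numeric vector (same names) of the fraction of
#'   each category drawn from true targets.
#' @param seed RNG seed.
#' @return named list of character vectors.
#' @export
generate_gene_categories <- function(annotation, truth, sizes = NULL,
                                     target_frac = c(svz_iz = 0.35,
                                                     cp = 0.12, vz = 0.06),
                                     seed = 1340L) {
  genes <- sort(unique(annotation$transcripts$gene_id))
  if (is.null(sizes)) {
    sizes <- round(c(svz_iz = 0.10, cp = 0.16, vz = 0.14) * length(genes))
  }
  targets <- truth$true_target_genes
  others <- setdiff(genes, targets)
  .with_seed(seed, {
    out <- lapply(names(sizes), function(nm) {
      nt <- min(round(sizes[[nm]] * target_frac[[nm]]), length(targets))
      no <- min(sizes[[nm]] - nt, length(others))
      c(sample(targets, nt), sample(others, no))
    })
    names(out) <- names(sizes)
    out
  })
}

#' Generate a synthetic ChIP-qPCR Ct table
#'
#' Two biological samples with three technical replicates per role. Bound
#' amplicons get a ChIP percent input around `bound_percent`; unbound
#' amplicons and the control ChIP sit at `background_percent`. Ct values are
#' back-computed from the intended percent input with small technical noise.
#'
#' @param amplicons character vector of amplicon names treated as bound.
#' @param control_amplicons amplicon names treated as unbound.
#' @param bound_percent,background_percent intended percent input levels.
#' @param input_fraction input chromatin fraction (default 0.10).
#' @param seed RNG seed.
#' @return data.table in [read_qpcr()] layout.
#' @export
generate_qpcr_table <- function(amplicons = c("site1", "site2", "site3"),
                                control_amplicons = c("neg1", "neg2"),
                                bound_percent = 5, background_percent = 0.2,
                                input_fraction = 0.10, seed = 1341L) {
  .with_seed(seed, {
    rows <- list()
    for (s in c("bio1", "bio2")) {
      for (a in c(amplicons, control_amplicons)) {
        ct_in <- stats::rnorm(1, 20, 0.15)
        adj <- adjusted_input_ct(ct_in, input_fraction)
        pct_chip <- if (a %in% amplicons) bound_percent else
          background_percent
        ct_chip <- adj - log2(pct_chip / 100)
        ct_ctrl <- adj - log2(background_percent / 100)
        for (r in 1:3) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            sample_id = s, amplicon = a,
            role = c("input", "chip", "control_chip"),
            ct = c(ct_in, ct_chip, ct_ctrl) + stats::rnorm(3, 0, 0.05),
            input_fraction = c(input_fraction, NA, NA))
        }
      }
    }
    data.table::rbindlist(rows)
  })
}

#' Write an annotation as GTF
#'
#' Chromosome lengths are recorded in `##sequence-region` directives. CDS
#' records are emitted per exon piece. Output is byte-identical for
#' identical annotations.
#'
#' @param annotation a [genome_annotation()] object.
#' @param path output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(annotation$chromosomes)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       as.integer(annotation$chromosomes[[ch]])), con)
  }
  tx <- annotation$transcripts
  data.table::setorderv(tx, c("chrom", "start", "transcript_id"))
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id[i], tid)
    writeLines(sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom[i], tx$start[i] + 1L, tx$end[i],
                       tx$strand[i], attrs), con)
    ex <- annotation$exons[annotation$exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                         tx$chrom[i], ex$start[j] + 1L, ex$end[j],
                         tx$strand[i], attrs), con)
    }
    ci <- annotation$cds[annotation$cds$transcript_id == tid, ]
    if (nrow(ci)) {
      for (j in seq_len(nrow(ex))) {
        cs <- max(ex$start[j], ci$start[1])
        ce <- min(ex$end[j], ci$end[1])
        if (cs < ce) {
          writeLines(sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                             tx$chrom[i], cs + 1L, ce, tx$strand[i], attrs),
                     con)
        }
      }
    }
  }
  invisible(path)
}

#' Generate and write a complete synthetic dataset
#'
#' Emits a GTF annotation, one BED file per antibody, a genome FASTA, gene
#' category files, a qPCR CSV and a truth JSON into `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisible list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(config = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  ps <- generate_peak_sets(ann, config)
  sq <- generate_sequences(ann, ps$truth, config)
  cats <- generate_gene_categories(ann, ps$truth, seed = config$seed + 3L)
  qpcr <- generate_qpcr_table(seed = config$seed + 4L)

  paths <- list(annotation = file.path(outdir, "annotation.gtf"),
                fasta = file.path(outdir, "genome.fa"),
                qpcr = file.path(outdir, "qpcr.csv"),
                truth = file.path(outdir, "truth.json"))
  write_annotation_gtf(ann, paths$annotation)
  Biostrings::writeXStringSet(sq$genome, paths$fasta)
  data.table::fwrite(qpcr, paths$qpcr)
  paths$peaks <- character(0)
  for (lab in names(ps$peak_sets)) {
    p <- file.path(outdir, paste0(lab, ".bed"))
    pk <- ps$peak_sets[[lab]]
    data.table::fwrite(pk[, c("chrom", "start", "end")], p, sep = "\t",
                       col.names = FALSE)
    paths$peaks[lab] <- p
  }
  dir.create(file.path(outdir, "categories"), showWarnings = FALSE)
  paths$categories <- character(0)
  for (nm in names(cats)) {
    p <- file.path(outdir, "categories", paste0(nm, ".txt"))
    writeLines(cats[[nm]], p)
    paths$categories[nm] <- p
  }
  jsonlite::write_json(
    list(true_target_genes = ps$truth$true_target_genes,
         true_sites = ps$truth$true_sites,
         planted_motifs = sq$planted_motifs),
    paths$truth, dataframe = "columns")
  invisible(list(annotation = ann, peak_sets = ps$peak_sets,
                 truth = ps$truth, genome = sq$genome,
                 planted_motifs = sq$planted_motifs, categories = cats,
                 qpcr = qpcr, paths = paths))
}
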