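#' Run the full peak-to-target pipeline
#'
#' Orchestrates: per-antibody peak reading -> consensus filtering and union
#' merge -> segment counts and binding preference -> TSS proximity map ->
#' distance-decay gene scoring and target selection -> (optional) motif
#' enrichment -> (optional) gene-set overlap enrichment -> (optional)
#' ChIP-qPCR quantification. Writes stage TSVs and a JSON manifest with
#' parameters, seeds and stage counts. Any stage error aborts with the stage
#' name and cause.
#'
#' @param config either the path to a YAML file or a list with elements:
#'   `peaks` (named list/vector of BED paths), `annotation` (GTF/GFF3 path),
#'   optional `fasta`, `categories` (paths), `qpcr` (CSV path), `outdir`,
#'   and parameters `min_support`, `bin_size`, `R`, `d0`, `threshold_sigma`,
#'   `motif_pattern`, `shuffles`, `draws`, `seed`.
#' @return invisible list of stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_support = 2L, bin_size = 1000L, R = 1000L, d0 = 5000,
                   threshold_sigma = 1.0, motif_pattern = "CAKMTGK",
                   shuffles = 100L, draws = 1000L, max_distance = 1e6,
                   tss_window = 1000L, outdir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  .assert(!is.null(config$seed), "config must set a seed")
  .assert(!is.null(config$peaks) && length(config$peaks) >= 2,
          "config must list at least two peak files")
  .assert(!is.null(config$annotation), "config must set an annotation path")
  for (p in c(unlist(config$peaks), config$annotation, config$fasta,
              unlist(config$categories), config$qpcr)) {
    .assert(file.exists(p), "input path does not exist: ", p)
  }
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- as.integer(config$seed)
  res <- list()
  manifest <- list(parameters = config[c("min_support", "bin_size", "R",
                                         "d0", "threshold_sigma",
                                         "motif_pattern", "shuffles",
                                         "draws", "seed")],
                   counts = list())

  ann <- stage("annotation", read_annotation(config$annotation))
  map <- stage("segment_map", build_segment_map(ann))
  tssdt <- tss_table(ann)
  manifest$counts$genes <- length(unique(ann$transcripts$gene_id))

  labels <- if (!is.null(names(config$peaks))) names(config$peaks) else
    paste0("ab", seq_along(config$peaks))
  peak_sets <- stage("read_peaks", {
    stats::setNames(lapply(seq_along(config$peaks), function(i) {
      read_peaks(config$peaks[[i]], labels[i])
    }), labels)
  })
  manifest$counts$input_peaks <- sum(vapply(peak_sets, nrow, 0L))

  cons <- stage("consensus", {
    filt <- consensus_filter(peak_sets, config$min_support)
    list(filt = filt, union = merge_union(filt$retained))
  })
  manifest$counts$retained_peaks <- nrow(cons$filt$retained)
  manifest$counts$discarded_peaks <- cons$filt$discarded
  manifest$counts$consensus_peaks <- nrow(cons$union)
  res$consensus <- cons$union

  res$correlations <- stage("correlation", {
    out <- list()
    for (i in seq_along(peak_sets)) for (j in seq_along(peak_sets)) {
      if (i < j) {
        out[[paste(labels[i], labels[j], sep = "_vs_")]] <-
          correlate_peak_sets(peak_sets[[i]], peak_sets[[j]],
                              ann$chromosomes, config$bin_size)
      }
    }
    out
  })

  res$binding_preference <- stage("binding_preference", {
    obs <- count_by_segment(cons$union, map)
    manifest$counts$intragenic_peaks <- obs$n_intragenic
    manifest$counts$intergenic_peaks <- obs$n_intergenic
    null <- randomize_intragenic(obs$n_intragenic, map, R = config$R,
                                 seed = seed + 1L)
    binding_preference(obs, null)
  })

  res$tss <- stage("tss_proximity", {
    nearest <- nearest_tss_distance(cons$union, tssdt)
    all_d <- peak_tss_distances(cons$union, tssdt, config$max_distance)
    list(nearest = nearest,
         histogram = distance_histogram(all_d$distance, config$bin_size,
                                        config$max_distance),
         fraction_within = fraction_within(nearest, config$tss_window))
  })

  res$scores <- stage("target_scoring", {
    cfg <- scoring_config(d0 = config$d0, seed = seed + 2L,
                          threshold_sigma = config$threshold_sigma)
    gene_score_table(cons$union, tssdt, ann$chromosomes, cfg)
  })
  res$targets <- select_targets(res$scores)
  manifest$counts$target_genes <- length(res$targets)

  if (!is.null(config$fasta)) {
    res$motif <- stage("motif_enrichment", {
      peak_motif_enrichment(cons$union, config$fasta, config$motif_pattern,
                            n_shuffles = config$shuffles, seed = seed + 3L)
    })
  }

  if (!is.null(config$categories)) {
    res$enrichment <- stage("gene_set_enrichment", {
      cats <- read_gene_sets(unlist(config$categories))
      gene_set_enrichment(res$targets, cats,
                          universe = unique(tssdt$gene_id),
                          n_draws = config$draws, seed = seed + 4L)
    })
  }

  if (!is.null(config$qpcr)) {
    res$qpcr <- stage("qpcr", {
      tab <- read_qpcr(config$qpcr)
      list(percent_input = qpcr_percent_input(tab),
           fold_enrichment = qpcr_fold_enrichment(tab))
    })
  }

  if (!is.null(outdir)) {
    stage("write_outputs", {
      consensus_to_bed(cons$union, file.path(outdir, "consensus.bed"))
      binding_preference_to_tsv(res$binding_preference,
                                file.path(outdir, "binding_preference.tsv"))
      data.table::fwrite(res$tss$histogram,
                         file.path(outdir, "tss_histogram.tsv"), sep = "\t")
      gene_scores_to_tsv(res$scores, file.path(outdir, "gene_scores.tsv"))
      writeLines(res$targets, file.path(outdir, "target_genes.txt"))
      if (!is.null(res$enrichment)) {
        data.table::fwrite(res$enrichment,
                           file.path(outdir, "gene_set_enrichment.tsv"),
                           sep = "\t")
      }
      if (!is.null(res$qpcr)) {
        data.table::fwrite(res$qpcr$fold_enrichment,
                           file.path(outdir, "qpcr_fold_enrichment.tsv"),
                           sep = "\t")
      }
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  res$manifest <- manifest
  invisible(res)
}
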