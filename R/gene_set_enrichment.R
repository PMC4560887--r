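#' Overlap between a target list and a gene category
#'
#' @param targets character vector of target gene ids.
#' @param category character vector of category member gene ids.
#' @return list with `count` (size of the intersection) and `fraction`
#'   (count / |category|).
#' @export
overlap_fraction <- function(targets, category) {
  .assert(length(category) > 0, "empty category")
  targets <- unique(targets)
  category <- unique(category)
  count <- length(intersect(targets, category))
  list(count = count, fraction = count / length(category))
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `overlap` category members among
#' `target_size` genes drawn without replacement from a universe of
#' `universe_size` genes containing `category_size` category members.
#'
#' @param universe_size,category_size,target_size,overlap integers.
#' @return P(X >= overlap), exact.
#' @export
hypergeometric_p <- function(universe_size, category_size, target_size,
                             overlap) {
  .assert(category_size <= universe_size && target_size <= universe_size,
          "category/target size exceeds universe")
  .assert(overlap <= min(category_size, target_size),
          "overlap exceeds min(category, target) size")
  .assert(overlap >= 0, "overlap must be non-negative")
  stats::phyper(overlap - 1, category_size, universe_size - category_size,
                target_size, lower.tail = FALSE)
}

#' Random-gene overlap baseline
#'
#' Draws `target_size` genes uniformly without replacement from the universe,
#' `n_draws` times, and returns the mean fraction of the category overlapped
#' -- the "equivalent numbers of randomly selected genes" comparison.
#'
#' @param universe character vector of all gene ids.
#' @param category character vector of category member ids.
#' @param target_size number of genes per random draw.
#' @param n_draws number of draws (default 1000).
#' @param seed RNG seed (default 1337).
#' @return mean overlap fraction over draws.
#' @export
random_gene_baseline <- function(universe, category, target_size,
                                 n_draws = 1000L, seed = 1337L) {
  .assert(target_size <= length(universe),
          "target_size exceeds universe size")
  .assert(length(category) > 0, "empty category")
  category <- unique(category)
  universe <- unique(universe)
  in_cat <- universe %in% category
  fr <- .with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      sum(in_cat[sample.int(length(universe), target_size)]) /
        length(category)
    }, 0)
  })
  mean(fr)
}

#' Read gene categories from plain-text list files
#'
#' Each file holds one gene id per line; the category name is the file name
#' without extension.
#'
#' @param paths character vector of file paths.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  out <- lapply(paths, function(p) {
    .assert(file.exists(p), "gene set file not found: ", p)
    ids <- readLines(p)
    ids[nzchar(trimws(ids))]
  })
  names(out) <- sub("\\.[^.]*$", "", basename(paths))
  out
}

#' Gene-set overlap enrichment of a target list
#'
#' For each category: overlap count and fraction of the category, exact
#' hypergeometric upper-tail p (Benjamini-Hochberg adjusted across the
#' supplied categories) and the mean overlap fraction of random gene draws of
#' the same size as the target list.
#'
#' @param targets character vector of target gene ids.
#' @param categories named list of character vectors.
#' @param universe character vector of all gene ids (e.g. all annotated
#'   genes). Category members outside the universe are dropped, with a
#'   warning.
#' @param n_draws random draws for the baseline (default 1000).
#' @param seed RNG seed (default 1337).
#' @return data.table with one row per category: `category`, `size`,
#'   `overlap_count`, `overlap_fraction`, `hypergeom_p`, `p_adj`,
#'   `random_baseline_fraction`.
#' @export
gene_set_enrichment <- function(targets, categories, universe,
                                n_draws = 1000L, seed = 1337L) {
  universe <- unique(universe)
  targets <- unique(intersect(targets, universe))
  rows <- lapply(names(categories), function(nm) {
    cat_raw <- unique(categories[[nm]])
    cat_in <- intersect(cat_raw, universe)
    if (length(cat_in) < length(cat_raw)) {
      warning(sprintf("category '%s': %d member(s) outside the universe dropped",
                      nm, length(cat_raw) - length(cat_in)))
    }
    ov <- overlap_fraction(targets, cat_in)
    data.table::data.table(
      category = nm,
      size = length(cat_in),
      overlap_count = ov$count,
      overlap_fraction = ov$fraction,
      hypergeom_p = hypergeometric_p(length(universe), length(cat_in),
                                     length(targets), ov$count),
      random_baseline_fraction = random_gene_baseline(
        universe, cat_in, length(targets), n_draws, seed)
    )
  })
  res <- data.table::rbindlist(rows)
  res$p_adj <- stats::p.adjust(res$hypergeom_p, method = "BH")
  data.table::setcolorder(res, c("category", "size", "overlap_count",
                                 "overlap_fraction", "hypergeom_p", "p_adj",
                                 "random_baseline_fraction"))
  res[]
}
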