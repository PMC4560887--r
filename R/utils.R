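# Internal helpers shared across modules. All genomic intervals in this
# package are 0-based half-open [start, end); conversion to the 1-based
# inclusive convention of GenomicRanges happens only inside these helpers.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom data.table data.table := .N
NULL

.datatable.aware <- TRUE

# data.table(chrom, start, end) -> GRanges (1-based inclusive)
.gr0 <- function(dt, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
  gr
}

# GRanges -> data.table(chrom, start, end), back to 0-based half-open
.dt0 <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Laplace(location = 0, scale = b) deviates as a difference of exponentials.
.rlaplace <- function(n, b) {
  stats::rexp(n, rate = 1 / b) - stats::rexp(n, rate = 1 / b)
}
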