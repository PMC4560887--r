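#' Adjusted input Ct
#'
#' ChIP-qPCR input samples are assayed on a fraction of the chromatin used
#' for the immunoprecipitation; the input Ct is adjusted by subtracting
#' `log2(1 / input_fraction)` cycles, i.e. 3.32 (= log2 10) for a 10% input.
#'
#' @param ct_input raw input Ct (vectorized).
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @return adjusted input Ct.
#' @export
adjusted_input_ct <- function(ct_input, input_fraction) {
  .assert(all(input_fraction > 0 & input_fraction <= 1),
          "input_fraction must be in (0, 1]")
  ct_input - log2(1 / input_fraction)
}

#' Percent input
#'
#' `100 * 2^(adjusted input Ct - ChIP Ct)`: the immunoprecipitated DNA
#' amount expressed as a percentage of input chromatin.
#'
#' @param adjusted_input adjusted input Ct (see [adjusted_input_ct()]).
#' @param ct_chip ChIP sample Ct.
#' @return percent of input, > 0.
#' @export
percent_input <- function(adjusted_input, ct_chip) {
  .assert(all(is.finite(adjusted_input)) && all(is.finite(ct_chip)),
          "Ct values must be finite")
  100 * 2^(adjusted_input - ct_chip)
}

#' Read a ChIP-qPCR Ct table
#'
#' CSV with columns `sample_id`, `amplicon`, `role` (one of `input`, `chip`,
#' `control_chip`), `ct` and `input_fraction` (required on input rows,
#' ignored elsewhere). One row per technical replicate.
#'
#' @param path CSV file.
#' @return validated data.table.
#' @export
read_qpcr <- function(path) {
  .assert(file.exists(path), "qPCR file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("sample_id", "amplicon", "role", "ct")
  .assert(all(need %in% names(dt)), "qPCR table must have columns ",
          paste(need, collapse = ", "))
  .assert(all(dt$role %in% c("input", "chip", "control_chip")),
          "role must be input, chip or control_chip")
  .assert(all(dt$ct > 0), "Ct values must be positive")
  if (!"input_fraction" %in% names(dt)) dt$input_fraction <- NA_real_
  inp <- dt$role == "input"
  .assert(all(!is.na(dt$input_fraction[inp])),
          "input rows must carry input_fraction")
  .assert(all(dt$input_fraction[inp] > 0 & dt$input_fraction[inp] <= 1),
          "input_fraction must be in (0, 1]")
  dt[]
}

#' Percent input per sample and amplicon
#'
#' Technical replicates are averaged to one Ct per (sample, amplicon, role)
#' first; percent input is then computed per biological sample, for the chip
#' and control_chip roles, against that sample's adjusted input.
#'
#' @param qpcr a [read_qpcr()] table.
#' @return data.table with columns `sample_id`, `amplicon`, `role`,
#'   `percent_input`.
#' @export
qpcr_percent_input <- function(qpcr) {
  m <- qpcr[, list(ct = mean(ct),
                   input_fraction = mean(input_fraction)),
            by = c("sample_id", "amplicon", "role")]
  inp <- m[m$role == "input", ]
  .assert(nrow(inp) > 0, "no input rows")
  inp$adj <- adjusted_input_ct(inp$ct, inp$input_fraction)
  ip <- m[m$role != "input", ]
  ip <- merge(ip, inp[, c("sample_id", "amplicon", "adj")],
              by = c("sample_id", "amplicon"))
  ip$percent_input <- percent_input(ip$adj, ip$ct)
  out <- ip[, c("sample_id", "amplicon", "role", "percent_input")]
  data.table::setorderv(out, c("amplicon", "sample_id", "role"))
  out[]
}

#' Fold enrichment of ChIP over a control ChIP
#'
#' Ratio of mean percent input across biological replicates, with the
#' standard error propagated to the ratio by the first-order delta method and
#' a two-sided Welch t-test across replicates (NA when both groups are
#' constant).
#'
#' @param chip_percent numeric vector: percent input per biological replicate.
#' @param control_percent numeric vector for the negative-control ChIP.
#' @return list with `ratio`, `sem`, `p_value`, `n_chip`, `n_control`.
#' @export
fold_enrichment <- function(chip_percent, control_percent) {
  .assert(length(chip_percent) > 0 && length(control_percent) > 0,
          "both replicate vectors must be non-empty")
  mc <- mean(chip_percent); mk <- mean(control_percent)
  .assert(mk > 0, "control percent input must be positive")
  ratio <- mc / mk
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  rel <- sqrt((sem(chip_percent) / mc)^2 + (sem(control_percent) / mk)^2)
  p <- if (length(chip_percent) > 1 && length(control_percent) > 1 &&
           (stats::sd(chip_percent) > 0 || stats::sd(control_percent) > 0)) {
    stats::t.test(chip_percent, control_percent)$p.value
  } else NA_real_
  list(ratio = ratio, sem = ratio * rel, p_value = p,
       n_chip = length(chip_percent), n_control = length(control_percent))
}

#' Fold enrichment per amplicon from a qPCR table
#'
#' @param qpcr a [read_qpcr()] table.
#' @return data.table with one row per amplicon: `amplicon`, `chip_mean`,
#'   `control_mean`, `fold`, `sem`, `p_value`.
#' @export
qpcr_fold_enrichment <- function(qpcr) {
  pi <- qpcr_percent_input(qpcr)
  rows <- lapply(unique(pi$amplicon), function(a) {
    ch <- pi$percent_input[pi$amplicon == a & pi$role == "chip"]
    ct <- pi$percent_input[pi$amplicon == a & pi$role == "control_chip"]
    if (!length(ch) || !length(ct)) return(NULL)
    fe <- fold_enrichment(ch, ct)
    data.table::data.table(amplicon = a, chip_mean = mean(ch),
                           control_mean = mean(ct), fold = fe$ratio,
                           sem = fe$sem, p_value = fe$p_value)
  })
  data.table::rbindlist(rows)
}
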