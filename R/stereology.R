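#' Optical-dissector total cell count
#'
#' Estimates the total number of cells in a structure from systematically
#' sampled sections: `N = RQ_sum / (ssf * asf * tsf)`, where `RQ_sum` is the
#' raw count of cells observed, and `ssf`, `asf`, `tsf` are the section,
#' area and thickness sampling fractions. Vectorized with the usual
#' recycling rules; the estimate is returned unrounded.
#'
#' @param rq_sum total counted cells (non-negative).
#' @param ssf section sampling fraction, in (0, 1].
#' @param asf area sampling fraction, in (0, 1].
#' @param tsf thickness sampling fraction, in (0, 1].
#' @return estimated total cell number.
#' @export
#' @examples
#' estimate_total_count(50, 1 / 6, 0.5, 0.5)  # 1200
estimate_total_count <- function(rq_sum, ssf, asf, tsf) {
  if (any(rq_sum < 0)) abort("rq_sum must be non-negative")
  for (nm in c("ssf", "asf", "tsf")) {
    f <- get(nm)
    if (any(f <= 0 | f > 1)) abort("%s must lie in (0, 1]", nm)
  }
  rq_sum / (ssf * asf * tsf)
}

#' Batch stereology estimates from a TSV
#'
#' Reads a table with columns `rq_sum, ssf, asf, tsf` (extra columns are
#' carried through) and appends the estimated total `n_total`.
#'
#' @param path input TSV.
#' @return data.frame with the input columns plus `n_total`.
#' @export
stereology_batch <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("rq_sum", "ssf", "asf", "tsf")
  miss <- setdiff(req, names(dt))
  if (length(miss)) abort("stereology TSV missing columns: %s",
                          paste(miss, collapse = ", "))
  dt$n_total <- estimate_total_count(dt$rq_sum, dt$ssf, dt$asf, dt$tsf)
  dt
}
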