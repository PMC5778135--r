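# Documentation for packaged reference files.

#' Path to a packaged reference table
#'
#' Convenience accessor for files under `inst/extdata`.  The packaged
#' `published_burden_table.csv` transcribes a published national decadal
#' burden table (central estimates, millions of premature deaths per
#' year, per emission pathway and SSP combination); the reporting
#' statistics are checked for consistency against the ranges derivable
#' from it.
#'
#' @param file file name under `extdata`.
#' @return absolute path.
#' @export
pm25burden_extdata <- function(file) {
  p <- system.file("extdata", file, package = "pm25burden", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged file '", file, "'")
  p
}
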