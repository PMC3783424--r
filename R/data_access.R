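# Bundled reference table.

#' Per-animal deployment and trip summary of the tracked cohort
#'
#' Published per-animal summary statistics for seven adult male Australian
#' sea lions instrumented with CTD-SRDL tags along the South Australian
#' coast (one animal per breeding colony, austral summer 2009/10): tracking
#' duration, trip counts, per-trip distance/duration/speed means and SDs,
#' and dive depths. This is the input for the cohort-level aggregates
#' ([cohort_summary()]): grand means and their standard errors across
#' animals.
#'
#' @return data.frame, one row per animal.
#' @export
colony_trip_summary <- function() {
  utils::read.csv(system.file("extdata", "colony_trip_summary.csv",
                              package = "aslforage", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
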