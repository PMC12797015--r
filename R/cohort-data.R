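#' Published nine-case tongue OSCC cohort measurements
#'
#' The per-case measurements of the nine-patient tongue squamous cell
#' carcinoma cohort the method was evaluated on: MRI-model and
#' histopathological-model tumor volumes (cm^3, two decimals), the
#' anterior-posterior / cranial-caudal / left-right model dimensions (cm,
#' one decimal) and the number of histopathological slides per case. These
#' are inputs for the table-ingestion report path ([reportFromTable()]);
#' the derived comparison columns (differences, ratios, cohort summary) are
#' recomputed from them.
#'
#' @return data.frame with one row per case.
#' @examples
#' rep <- reportFromTable(cohortVolumeTable())
#' reportSummary(rep)
#' @export
cohortVolumeTable <- function() {
  path <- system.file("extdata", "oscc_cohort_volumes.csv",
                      package = "TumorFusion3D", mustWork = TRUE)
  utils::read.csv(path)
}
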