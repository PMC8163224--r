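#' The customized brain- and vasculature-injury miRNA panel
#'
#' Returns the packaged definition of the custom RT-qPCR low-density-array
#' panel: the analyzable human miRNAs selected for their association with
#' CNS injury, cerebrovascular damage, or prior biomarker studies, plus one
#' rodent-specific miRNA that serves as an assay control and is excluded from
#' all statistics (`analyzable = FALSE`). The mandatory U6 control of the
#' array chemistry is not part of the definition at all.
#'
#' @param analyzable_only If `TRUE`, return only the analyzable entries.
#'
#' @return A tibble with columns `assay_id`, `mirna_id`, `sequence`
#'   (RNA alphabet), `annotation`, and `analyzable`.
#' @examples
#' dcv_panel()
#' nrow(dcv_panel(analyzable_only = TRUE))
#' @export
dcv_panel <- function(analyzable_only = FALSE) {
  path <- system.file("extdata", "panel_mirnas.csv", package = "dcvmir")
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      assay_id = readr::col_character(),
      mirna_id = readr::col_character(),
      sequence = readr::col_character(),
      annotation = readr::col_character(),
      analyzable = readr::col_logical()
    ),
    progress = FALSE
  )
  stopifnot(
    !anyDuplicated(panel$mirna_id),
    all(grepl("^[ACGU]+$", panel$sequence))
  )
  if (analyzable_only) panel <- dplyr::filter(panel, .data$analyzable)
  panel
}

#' miRNA identifiers of the analyzable panel
#'
#' @return Character vector of the analyzable miRNA ids, in panel order.
#' @export
panel_mirnas <- function() {
  dcv_panel(analyzable_only = TRUE)$mirna_id
}
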