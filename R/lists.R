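#' Targets of the MARS Hu-14 immunodepletion column
#'
#' The 14 abundant plasma proteins removed by the Multiple Affinity Removal
#' System (human 14) column. Proteins with affinity to the depletion
#' antibodies cannot be quantified reliably in depleted plasma and are
#' excluded from downstream statistics.
#'
#' @return character vector of 14 protein names.
#' @export
default_mars_target_list <- function() {
  c("albumin", "IgG", "antitrypsin", "IgA", "transferrin", "haptoglobin",
    "fibrinogen", "alpha-2-macroglobulin", "alpha-1-acid glycoprotein",
    "IgM", "apolipoprotein AI", "apolipoprotein AII", "complement C3",
    "transthyretin")
}

#' Standard contaminant protein list
#'
#' A short list of ubiquitous sample-handling contaminants (keratins,
#' trypsin) in the naming convention used by the synthetic generator.
#' Real analyses would substitute the cRAP-style list matching their
#' search database.
#'
#' @return character vector of contaminant identifiers.
#' @export
default_contaminant_list <- function() {
  c("CONTAM_KRT1", "CONTAM_KRT2", "CONTAM_KRT5", "CONTAM_KRT9",
    "CONTAM_KRT10", "CONTAM_KRT14", "CONTAM_KRT16", "CONTAM_KRT17",
    "CONTAM_TRYP_PIG", "CONTAM_TRYP_BOVIN", "CONTAM_ALBU_BOVIN",
    "CONTAM_CAS1_BOVIN")
}
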