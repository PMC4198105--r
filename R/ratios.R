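#' Per-PSM, per-donor log2 ratios
#'
#' For every PSM and every donor multiplexed in that PSM's experiment,
#' computes log2(intensity in the donor's RIPC channel / intensity in the
#' donor's baseline channel) from the design's channel assignment. The
#' ratio is missing (NA) when either intensity is non-positive.
#'
#' @param psm_table normalized PSM table (targets only).
#' @param design design table (see \code{\link{default_design}}).
#' @return long data.frame: \code{spectrum_id}, \code{experiment_id},
#'   \code{peptide_sequence}, \code{protein_accession}, \code{donor_id},
#'   \code{log2_ratio}.
#' @export
psm_log2_ratios <- function(psm_table, design) {
  validate_design(design)
  missing_exps <- setdiff(unique(psm_table$experiment_id),
                          unique(design$experiment_id))
  if (length(missing_exps) > 0L) {
    stop(sprintf("psm_log2_ratios: experiment id(s) absent from design: %s",
                 paste(missing_exps, collapse = ", ")))
  }
  pieces <- list()
  for (exp_id in unique(psm_table$experiment_id)) {
    rows <- psm_table[psm_table$experiment_id == exp_id, , drop = FALSE]
    d <- design[design$experiment_id == exp_id, ]
    for (donor in unique(d$donor_id)) {
      ch_ripc <- d$channel[d$donor_id == donor & d$condition == "ripc"]
      ch_base <- d$channel[d$donor_id == donor & d$condition == "baseline"]
      i_ripc <- rows[[paste0("intensity_", ch_ripc)]]
      i_base <- rows[[paste0("intensity_", ch_base)]]
      ok <- i_ripc > 0 & i_base > 0
      pieces[[length(pieces) + 1L]] <- data.frame(
        spectrum_id = rows$spectrum_id,
        experiment_id = rows$experiment_id,
        peptide_sequence = rows$peptide_sequence,
        protein_accession = rows$protein_accession,
        donor_id = donor,
        log2_ratio = ifelse(ok, log2(i_ripc / i_base), NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Peptide-level per-donor ratio estimates
#'
#' Aggregates PSM-level log2 ratios to one estimate per (protein, peptide,
#' donor) with \code{\link{ml_ratio_estimate}}; groups with no valid PSM
#' ratio are dropped.
#'
#' @param psm_ratios output of \code{\link{psm_log2_ratios}}.
#' @return data.frame: \code{protein_accession}, \code{peptide_sequence},
#'   \code{donor_id}, \code{log2_ratio}, \code{n_psms} (contributing PSMs).
#' @export
peptide_quants <- function(psm_ratios) {
  ok <- !is.na(psm_ratios$log2_ratio)
  x <- psm_ratios[ok, , drop = FALSE]
  if (nrow(x) == 0L) {
    return(data.frame(protein_accession = character(0),
                      peptide_sequence = character(0),
                      donor_id = integer(0), log2_ratio = numeric(0),
                      n_psms = integer(0)))
  }
  key <- paste(x$protein_accession, x$peptide_sequence, x$donor_id,
               sep = "\r")
  groups <- split(x$log2_ratio, key)
  # split() orders groups by sorted key; align the metadata rows the same way
  meta <- x[!duplicated(key), , drop = FALSE]
  meta <- meta[match(names(groups), key[!duplicated(key)]), ]
  data.frame(
    protein_accession = meta$protein_accession,
    peptide_sequence = meta$peptide_sequence,
    donor_id = meta$donor_id,
    log2_ratio = vapply(groups, ml_ratio_estimate, numeric(1),
                        USE.NAMES = FALSE),
    n_psms = vapply(groups, length, integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Protein-level per-donor and combined log2 ratios
#'
#' For each protein and donor, the protein log2 ratio is the
#' \code{\link{ml_ratio_estimate}} over that donor's peptide-level ratios.
#' Per donor, protein ratios are then centered by subtracting the median
#' across retained proteins (two or more unique quantified peptides, not a
#' contaminant, not a depletion target) to remove inter-sample bias.
#' The combined log2 ratio is the \code{\link{ml_ratio_estimate}} over the
#' protein's centered donor-level values.
#'
#' @param pep_quants output of \code{\link{peptide_quants}}.
#' @param design design table (fixes the donor set).
#' @param mars_list,contaminant_list identifier lists used to flag
#'   excluded proteins.
#' @param min_unique_peptides retention threshold on unique quantified
#'   peptides (default 2).
#' @return data.frame: \code{protein_accession}, one \code{log2_d<donor>}
#'   column per donor, \code{combined_log2}, \code{n_peptides},
#'   \code{n_donors}, \code{contaminant}, \code{mars_target},
#'   \code{retained}.
#' @export
aggregate_protein_ratios <- function(pep_quants, design,
                                     mars_list = default_mars_target_list(),
                                     contaminant_list = default_contaminant_list(),
                                     min_unique_peptides = 2L) {
  donors <- sort(unique(design$donor_id))
  prots <- unique(pep_quants$protein_accession)
  ratio <- matrix(NA_real_, nrow = length(prots), ncol = length(donors),
                  dimnames = list(prots, paste0("log2_d", donors)))
  for (j in seq_along(donors)) {
    sub <- pep_quants[pep_quants$donor_id == donors[j], , drop = FALSE]
    if (nrow(sub) == 0L) next
    vals <- split(sub$log2_ratio, sub$protein_accession)
    est <- vapply(vals, ml_ratio_estimate, numeric(1))
    ratio[names(est), j] <- est
  }
  n_peptides <- vapply(split(pep_quants$peptide_sequence,
                             pep_quants$protein_accession),
                       function(p) length(unique(p)), integer(1))[prots]
  contaminant <- prots %in% contaminant_list
  mars_target <- prots %in% mars_list
  retained <- n_peptides >= min_unique_peptides & !contaminant & !mars_target

  # per-donor median centering on the retained set
  for (j in seq_along(donors)) {
    med <- stats::median(ratio[retained, j], na.rm = TRUE)
    if (is.finite(med)) {
      ratio[, j] <- ratio[, j] - med
    }
  }
  combined <- apply(ratio, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) NA_real_ else ml_ratio_estimate(r)
  })
  out <- data.frame(protein_accession = prots, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ratio, row.names = seq_along(prots)))
  out$combined_log2 <- unname(combined)
  out$n_peptides <- unname(n_peptides)
  out$n_donors <- rowSums(!is.na(ratio))
  out$contaminant <- unname(contaminant)
  out$mars_target <- unname(mars_target)
  out$retained <- unname(retained)
  rownames(out) <- NULL
  out
}

#' Filter to the quantifiable protein set
#'
#' Retains proteins with at least \code{min_unique_peptides} unique
#' quantified peptides that are neither standard contaminants nor
#' depletion-column targets, and reports the count at each filter stage.
#'
#' @param protein_quants output of \code{\link{aggregate_protein_ratios}}.
#' @param min_unique_peptides retention threshold (default 2).
#' @return list: \code{retained} (subset data.frame) and \code{counts}
#'   (named integer vector: quantified_any, min_peptides,
#'   after_exclusions).
#' @export
filter_quantifiable <- function(protein_quants, min_unique_peptides = 2L) {
  has_pept <- protein_quants$n_peptides >= min_unique_peptides
  kept <- has_pept & !protein_quants$contaminant & !protein_quants$mars_target
  list(
    retained = protein_quants[kept, , drop = FALSE],
    counts = c(quantified_any = nrow(protein_quants),
               min_peptides = sum(has_pept),
               after_exclusions = sum(kept))
  )
}
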