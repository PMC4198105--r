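#' Median-normalize reporter channels within each experiment
#'
#' Within each multiplex experiment, rescales every channel so that the
#' four channel medians all equal the grand median of the experiment's
#' channel medians. Channels are only comparable within a multiplex, so
#' normalization is never applied across experiments. Scaling is
#' monotone, so the rank order of intensities within a channel is
#' preserved.
#'
#' @param psm_table data.frame with \code{experiment_id} and
#'   \code{intensity_114} .. \code{intensity_117} columns (validated,
#'   impurity-corrected PSMs).
#' @return the table with normalized intensities.
#' @export
normalize_channel_intensities <- function(psm_table) {
  cols <- paste0("intensity_", 114:117)
  stopifnot(all(c("experiment_id", cols) %in% names(psm_table)))
  if (nrow(psm_table) == 0L) {
    stop("normalize_channel_intensities: empty PSM table")
  }
  for (exp_id in unique(psm_table$experiment_id)) {
    rows <- psm_table$experiment_id == exp_id
    meds <- vapply(cols, function(cc) stats::median(psm_table[[cc]][rows]),
                   numeric(1))
    bad <- which(meds <= 0)
    if (length(bad) > 0L) {
      stop(sprintf(
        "normalize_channel_intensities: experiment '%s', channel %s: channel median is zero",
        exp_id, sub("intensity_", "", cols[bad[[1L]]])))
    }
    grand <- stats::median(meds)
    for (k in seq_along(cols)) {
      psm_table[[cols[k]]][rows] <-
        psm_table[[cols[k]]][rows] * (grand / meds[[k]])
    }
  }
  psm_table
}
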