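# Tab-separated readers/writers for the pipeline's external interfaces.
# All files are UTF-8 TSV with a header row.

.psm_columns <- c("spectrum_id", "experiment_id", "peptide_sequence",
                  "protein_accession", "is_decoy", "score",
                  "intensity_114", "intensity_115", "intensity_116",
                  "intensity_117")
.psm_numeric <- c("score", paste0("intensity_", 114:117))

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write / read a PSM table
#'
#' The PSM table is tab-separated UTF-8 with a header and columns
#' \code{spectrum_id}, \code{experiment_id}, \code{peptide_sequence},
#' \code{protein_accession}, \code{is_decoy} (0/1), \code{score} (higher is
#' better) and \code{intensity_114} .. \code{intensity_117}. Reading a
#' written table restores every field; malformed rows are reported with
#' their line number.
#'
#' @param psm_table data.frame with the columns above.
#' @param path file path.
#' @return \code{read_psm_table} returns the data.frame;
#'   \code{write_psm_table} returns \code{path} invisibly.
#' @export
write_psm_table <- function(psm_table, path) {
  stopifnot(all(.psm_columns %in% names(psm_table)))
  .write_tsv(psm_table[, .psm_columns, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.psm_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("read_psm_table: '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  out <- raw[, .psm_columns, drop = FALSE]
  for (cc in c(.psm_numeric, "is_decoy")) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    bad <- which(is.na(v) & !is.na(out[[cc]]))
    if (length(bad) > 0L) {
      stop(sprintf("read_psm_table: non-numeric value '%s' in column '%s' at line %d of '%s'",
                   out[[cc]][bad[[1L]]], cc, bad[[1L]] + 1L, path))
    }
    out[[cc]] <- if (cc == "is_decoy") as.integer(v) else v
  }
  if (nrow(out) > 0L && !all(out$is_decoy %in% c(0L, 1L))) {
    bad <- which(!out$is_decoy %in% c(0L, 1L))[[1L]]
    stop(sprintf("read_psm_table: is_decoy must be 0 or 1 at line %d of '%s'",
                 bad + 1L, path))
  }
  out
}

#' Write / read an experiment design table
#'
#' Tab-separated with columns \code{experiment_id}, \code{channel},
#' \code{donor_id}, \code{condition}; validated structurally on read.
#'
#' @param design design data.frame (see \code{\link{default_design}}).
#' @param path file path.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  .write_tsv(design[, c("experiment_id", "channel", "donor_id", "condition")],
             path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  d$experiment_id <- as.character(d$experiment_id)
  d$channel <- as.integer(d$channel)
  validate_design(d)
  d
}

#' Write / read a purity matrix file
#'
#' Certificate convention: one row per channel with the percentage of
#' signal at the -2, -1, +1 and +2 mass offsets.
#'
#' @param pm a \code{purity_matrix}.
#' @param path file path.
#' @export
write_purity_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "purity_matrix"))
  .write_tsv(as.data.frame(pm), path)
  invisible(path)
}

#' @rdname write_purity_matrix
#' @export
read_purity_matrix <- function(path) {
  d <- utils::read.delim(path, fileEncoding = "UTF-8")
  need <- c("channel", "pct_minus2", "pct_minus1", "pct_plus1", "pct_plus2")
  if (!all(need %in% names(d))) {
    stop(sprintf("read_purity_matrix: '%s' must have columns %s",
                 path, paste(need, collapse = ", ")))
  }
  d <- d[order(d$channel), ]
  if (!identical(as.integer(d$channel), c(114L, 115L, 116L, 117L))) {
    stop(sprintf("read_purity_matrix: '%s' must list channels 114-117", path))
  }
  purity_matrix(d$pct_minus2, d$pct_minus1, d$pct_plus1, d$pct_plus2)
}

#' Write / read a ground-truth sidecar table
#'
#' Per-protein ground truth emitted by the synthetic generator, keyed by
#' protein accession.
#'
#' @param truth data.frame as returned in \code{generate_dataset()$truth$proteins}.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  .write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
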