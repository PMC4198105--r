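#' Isotope purity matrix constructor
#'
#' Builds the per-channel isotopic spillover table for 4-plex reporter ions
#' (channels 114-117) in the reagent-certificate convention: for each
#' channel, the percentage of its signal appearing at -2, -1, +1 and +2
#' mass offsets. The diagonal purity of a channel is 100 minus the sum of
#' its listed offsets.
#'
#' @param pct_minus2,pct_minus1,pct_plus1,pct_plus2 numeric vectors of
#'   length 4 (channels 114, 115, 116, 117), percentages >= 0.
#' @return data.frame of class \code{purity_matrix} with columns
#'   \code{channel}, \code{pct_minus2}, \code{pct_minus1},
#'   \code{pct_plus1}, \code{pct_plus2}.
#' @export
purity_matrix <- function(pct_minus2, pct_minus1, pct_plus1, pct_plus2) {
  stopifnot(length(pct_minus2) == 4L, length(pct_minus1) == 4L,
            length(pct_plus1) == 4L, length(pct_plus2) == 4L)
  pm <- data.frame(channel = c(114L, 115L, 116L, 117L),
                   pct_minus2 = as.numeric(pct_minus2),
                   pct_minus1 = as.numeric(pct_minus1),
                   pct_plus1 = as.numeric(pct_plus1),
                   pct_plus2 = as.numeric(pct_plus2))
  offs <- as.matrix(pm[, -1L])
  if (any(offs < 0)) stop("purity_matrix: negative spillover percentage")
  diagonal <- 100 - rowSums(offs)
  if (any(diagonal < 0)) {
    stop("purity_matrix: channel offsets exceed 100% (negative diagonal purity)")
  }
  class(pm) <- c("purity_matrix", "data.frame")
  pm
}

#' Identity purity matrix (no isotopic spillover)
#' @return a \code{purity_matrix} with 0% at every offset.
#' @export
identity_purity_matrix <- function() {
  purity_matrix(rep(0, 4), rep(0, 4), rep(0, 4), rep(0, 4))
}

#' Example 4-plex purity matrix
#'
#' Synthetic purity values of typical magnitude for 4-plex reagent lots
#' (roughly 1-6% at the +/-1 offsets). These are illustrative defaults for
#' simulation and examples, not certificate values for any real reagent
#' lot; real analyses must use the lot-specific certificate.
#'
#' @return a \code{purity_matrix}.
#' @export
example_purity_matrix <- function() {
  purity_matrix(pct_minus2 = c(0.0, 0.0, 0.0, 0.1),
                pct_minus1 = c(1.0, 2.0, 3.0, 4.0),
                pct_plus1  = c(5.9, 5.6, 4.5, 3.5),
                pct_plus2  = c(0.2, 0.1, 0.1, 0.1))
}

#' Mixing matrix of a purity specification
#'
#' Converts the certificate-style purity table into the 4x4 linear mixing
#' matrix M such that observed = M \%*\% true, restricted to the 114-117
#' window. Spillover falling outside the window (e.g. 114 at -1, 117 at +1)
#' is discarded mass, so column sums may be below 1.
#'
#' @param pm a \code{purity_matrix}.
#' @return 4x4 numeric matrix, rows/cols in channel order 114..117.
#' @export
purity_mixing_matrix <- function(pm) {
  stopifnot(inherits(pm, "purity_matrix"))
  m <- matrix(0, 4L, 4L,
              dimnames = list(paste0("obs", 114:117), paste0("src", 114:117)))
  offsets <- c(pct_minus2 = -2L, pct_minus1 = -1L, pct_plus1 = 1L,
               pct_plus2 = 2L)
  for (i in 1:4) {
    diag_pct <- 100 - sum(as.numeric(pm[i, names(offsets)]))
    m[i, i] <- diag_pct / 100
    for (off in names(offsets)) {
      j <- i + offsets[[off]]
      if (j >= 1L && j <= 4L) {
        m[j, i] <- m[j, i] + pm[[off]][i] / 100
      }
    }
  }
  m
}

#' Correct reporter intensities for isotopic impurities
#'
#' Solves the 4x4 linear system observed = M x true for the true reporter
#' intensities, where M is the mixing matrix of the supplied purity table.
#' Any negative solution component (a noise artifact) is clipped to zero.
#'
#' @param raw numeric vector of 4 raw intensities (channels 114..117), or a
#'   matrix with 4 columns (one row per PSM).
#' @param pm a \code{purity_matrix}.
#' @return corrected intensities in the same shape as \code{raw}, with
#'   attribute \code{clipped}: logical, TRUE where a negative component was
#'   clipped (per row for matrix input).
#' @export
correct_isotope_impurities <- function(raw, pm) {
  m <- purity_mixing_matrix(pm)
  if (abs(det(m)) < 1e-12) {
    stop(paste0("correct_isotope_impurities: singular mixing matrix:\n",
                paste(utils::capture.output(print(m)), collapse = "\n")))
  }
  vec_in <- is.null(dim(raw))
  x <- if (vec_in) matrix(as.numeric(raw), nrow = 1L) else as.matrix(raw)
  stopifnot(ncol(x) == 4L)
  if (any(x < 0)) stop("correct_isotope_impurities: negative raw intensity")
  sol <- t(solve(m, t(x)))
  clipped <- apply(sol < -1e-12, 1L, any)
  sol[sol < 0] <- 0
  if (vec_in) {
    out <- as.numeric(sol[1L, ])
    attr(out, "clipped") <- clipped[[1L]]
  } else {
    out <- sol
    dimnames(out) <- dimnames(x)
    attr(out, "clipped") <- unname(clipped)
  }
  out
}

#' Apply isotope-impurity correction to a PSM table
#'
#' Corrects the four \code{intensity_*} columns of a PSM table in place and
#' records, per PSM, whether a negative component was clipped to zero.
#'
#' @param psm_table data.frame with columns \code{intensity_114} ..
#'   \code{intensity_117}.
#' @param pm a \code{purity_matrix}.
#' @return the table with corrected intensities and an added logical
#'   column \code{isotope_clipped}.
#' @export
correct_psm_table <- function(psm_table, pm) {
  cols <- paste0("intensity_", 114:117)
  stopifnot(all(cols %in% names(psm_table)))
  if (nrow(psm_table) == 0L) {
    psm_table$isotope_clipped <- logical(0)
    return(psm_table)
  }
  corrected <- correct_isotope_impurities(as.matrix(psm_table[, cols]), pm)
  psm_table[, cols] <- corrected
  psm_table$isotope_clipped <- attr(corrected, "clipped")
  psm_table
}
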