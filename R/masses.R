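# Average (not monoisotopic) residue masses in Da for the 20 standard amino
# acids; a peptide/protein mass is the residue sum plus one water.
.aa_average_masses <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.water_mass <- 18.01528

#' Molecular weight of a protein or peptide sequence
#'
#' Computes the average-mass molecular weight in kDa from a plain amino-acid
#' sequence (residue masses plus one water).
#'
#' @param sequence character vector of amino-acid sequences (one-letter code).
#' @return numeric vector of molecular weights in kDa.
#' @export
molecular_weight_kda <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) {
      stop("molecular_weight_kda: empty sequence")
    }
    aa <- strsplit(s, "")[[1L]]
    m <- .aa_average_masses[aa]
    if (anyNA(m)) {
      stop(sprintf("molecular_weight_kda: unknown residue(s) '%s'",
                   paste(unique(aa[is.na(m)]), collapse = "")))
    }
    (sum(m) + .water_mass) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}
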