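#' Paired two-sided t-test of donor log2 ratios against zero
#'
#' One-sample two-sided t-test of the per-donor protein log2 ratios
#' against 0, equivalent to a paired t-test on the log intensities of the
#' two conditions (n - 1 degrees of freedom). Fewer than two non-missing
#' donor ratios yield a missing p-value (the protein then falls on the
#' "t-test failed" branch of the classification); a zero-variance sample
#' returns p = 1 (no evidence of regulation) rather than an error.
#'
#' @param per_donor_log2_ratios numeric vector (up to 6 values, NAs
#'   allowed).
#' @return two-sided p-value, or NA if fewer than 2 values.
#' @export
paired_t_test <- function(per_donor_log2_ratios) {
  x <- per_donor_log2_ratios[!is.na(per_donor_log2_ratios)]
  if (length(x) < 2L) {
    return(NA_real_)
  }
  if (stats::sd(x) == 0) {
    return(1)
  }
  stats::t.test(x, mu = 0, alternative = "two.sided")$p.value
}

#' Fit the asymmetric-normal background model
#'
#' Models the background distribution of combined log2 ratios of
#' unregulated proteins as a two-piece (asymmetric) normal calibrated on
#' the empirical median and the 15.9th/84.1th percentiles (the +/- 1 sigma
#' quantiles of a normal): m is the 50th percentile, sigma_low = m - 15.9th
#' percentile, sigma_high = 84.1th percentile - m, all with the
#' linear-interpolation percentile convention.
#'
#' @param combined_log2_ratios numeric vector of combined log2 ratios of
#'   all retained proteins (>= 10 values).
#' @return object of class \code{background_model}: list with \code{m},
#'   \code{sigma_low}, \code{sigma_high}, \code{n}.
#' @export
fit_background <- function(combined_log2_ratios) {
  x <- combined_log2_ratios[!is.na(combined_log2_ratios)]
  if (length(x) < 10L) {
    stop("fit_background: need at least 10 retained protein ratios")
  }
  q <- stats::quantile(x, probs = c(0.159, 0.5, 0.841), type = 7,
                       names = FALSE)
  model <- list(m = q[[2L]], sigma_low = q[[2L]] - q[[1L]],
                sigma_high = q[[3L]] - q[[2L]], n = length(x))
  if (model$sigma_low <= 0 || model$sigma_high <= 0) {
    stop("fit_background: degenerate input (zero spread on one side)")
  }
  class(model) <- "background_model"
  model
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "Asymmetric-normal background model (n = %d)\n  m = %.4f, sigma_low = %.4f, sigma_high = %.4f\n",
    x$n, x$m, x$sigma_low, x$sigma_high))
  invisible(x)
}

#' Probability of a ratio under the background model
#'
#' One-sided tail probability of a combined log2 ratio under the
#' side-specific normal: for x >= m, P = 1 - Phi((x - m)/sigma_high); for
#' x < m, P = Phi((x - m)/sigma_low). A protein is confidently regulated
#' relative to the background when P < 0.01. The two-sided variant
#' (2 x min(tail, 1 - tail)) is available via \code{two_sided = TRUE}.
#'
#' @param x numeric vector of combined log2 ratios.
#' @param model a \code{\link{fit_background}} model.
#' @param two_sided logical, default FALSE (one-sided on the observed
#'   side).
#' @return probabilities in [0, 1], vectorized over \code{x}.
#' @export
background_probability <- function(x, model, two_sided = FALSE) {
  stopifnot(inherits(model, "background_model"))
  upper <- x >= model$m
  p <- ifelse(upper,
              stats::pnorm((x - model$m) / model$sigma_high,
                           lower.tail = FALSE),
              stats::pnorm((x - model$m) / model$sigma_low))
  if (two_sided) {
    p <- pmin(2 * pmin(p, 1 - p), 1)
  }
  p
}

#' Cross-classify proteins by the two regulation tests
#'
#' Category A: donor-consistent (t-test p below threshold) AND confidently
#' regulated relative to the background; B: donor-consistent only; C:
#' background-regulated only; D: neither. A missing t-test p-value counts
#' as a failed t-test.
#'
#' @param t_pvalue,background_probability numeric vectors (recycled).
#' @param t_threshold,bg_threshold decision thresholds, default 0.01.
#' @return character vector of "A", "B", "C" or "D".
#' @export
classify_regulation <- function(t_pvalue, background_probability,
                                t_threshold = 0.01, bg_threshold = 0.01) {
  t_pass <- !is.na(t_pvalue) & t_pvalue < t_threshold
  bg_pass <- !is.na(background_probability) &
    background_probability < bg_threshold
  ifelse(t_pass & bg_pass, "A",
         ifelse(t_pass, "B",
                ifelse(bg_pass, "C", "D")))
}

#' Spectral-counting abundance index
#'
#' Number of validated PSMs divided by the protein molecular weight in
#' kDa: a simple relative abundance proxy (larger proteins yield more
#' peptides, hence the weight normalization).
#'
#' @param n_validated_psms non-negative PSM counts.
#' @param molecular_weight_kda positive weights in kDa.
#' @return numeric abundance indexes.
#' @export
abundance_index <- function(n_validated_psms, molecular_weight_kda) {
  if (any(molecular_weight_kda <= 0)) {
    stop("abundance_index: molecular weight must be positive")
  }
  if (any(n_validated_psms < 0)) {
    stop("abundance_index: negative PSM count")
  }
  n_validated_psms / molecular_weight_kda
}

#' Per-peptide spectral enrichment within a protein
#'
#' Each peptide's PSM count divided by the median PSM count across the
#' protein's peptides. Flags peptides recorded far more often than the
#' protein's typical peptide, e.g. stable degradation products.
#'
#' @param peptide_psm_counts numeric vector of PSM counts (>= 1 peptide).
#' @return enrichment ratios relative to the median peptide.
#' @export
peptide_spectral_enrichment <- function(peptide_psm_counts) {
  if (length(peptide_psm_counts) == 0L) {
    stop("peptide_spectral_enrichment: need at least one peptide")
  }
  peptide_psm_counts / stats::median(peptide_psm_counts)
}

#' Biological-relevance flag on the fold change
#'
#' TRUE when the fold change reflects at least a \code{relevance_pct}
#' percent change in either direction (default 20%, i.e. fold change
#' >= 1.2 or <= 1/1.2); smaller changes are within the technical
#' variability of the isobaric workflow.
#'
#' @param fold_change positive fold changes (2^combined log2 ratio).
#' @param relevance_pct percent-change threshold, default 20.
#' @return logical vector.
#' @export
relevance_flag <- function(fold_change, relevance_pct = 20) {
  if (any(fold_change <= 0)) {
    stop("relevance_flag: fold change must be positive")
  }
  lim <- 1 + relevance_pct / 100
  fold_change >= lim | fold_change <= 1 / lim
}
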