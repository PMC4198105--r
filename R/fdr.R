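#' Validate PSMs at a target/decoy false discovery rate
#'
#' Estimates the FDR by decoy counting: for a candidate score threshold s,
#' FDR(s) = #\{decoys with score >= s\} / #\{targets with score >= s\}.
#' The retained threshold s* is the lowest score at which the estimate is
#' at or below \code{level}; all target PSMs scoring >= s* are returned and
#' decoy PSMs are dropped from the validated set. No +1 pseudo-count or
#' posterior error model is applied.
#'
#' @param psm_table data.frame with at least \code{score} and
#'   \code{is_decoy} (0/1) columns.
#' @param level FDR level in (0, 1); default 0.01.
#' @return the validated subset of \code{psm_table} (targets only). If no
#'   threshold achieves the level, a zero-row subset.
#' @export
validate_at_fdr <- function(psm_table, level = 0.01) {
  stopifnot(is.data.frame(psm_table),
            all(c("score", "is_decoy") %in% names(psm_table)))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("validate_at_fdr: 'level' must be a single number strictly between 0 and 1")
  }
  decoy <- psm_table$is_decoy != 0
  if (!any(!decoy)) {
    stop("validate_at_fdr: table contains zero target records")
  }
  score <- psm_table$score
  if (anyNA(score)) stop("validate_at_fdr: missing scores")

  # counts of targets/decoys at or above each candidate threshold,
  # candidates being the distinct observed scores in ascending order;
  # findInterval(left.open = TRUE) counts elements strictly below s
  s <- sort(unique(score))
  targ_sorted <- sort(score[!decoy])
  dec_sorted <- sort(score[decoy])
  n_target_ge <- length(targ_sorted) -
    findInterval(s, targ_sorted, left.open = TRUE)
  n_decoy_ge <- length(dec_sorted) -
    findInterval(s, dec_sorted, left.open = TRUE)
  fdr <- ifelse(n_target_ge == 0,
                ifelse(n_decoy_ge == 0, 0, Inf),
                n_decoy_ge / n_target_ge)
  ok <- which(fdr <= level & n_target_ge > 0)
  if (length(ok) == 0L) {
    return(psm_table[integer(0), , drop = FALSE])
  }
  s_star <- s[min(ok)]
  psm_table[!decoy & score >= s_star, , drop = FALSE]
}
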