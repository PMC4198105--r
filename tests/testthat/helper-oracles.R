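# Independent oracles used by both the unit and the acceptance tests.

# Brute-force argmax of the Gaussian KDE on a very fine grid, written
# directly from the kernel definition.
kde_mode_oracle <- function(x, n_grid = 200001L) {
  h <- stats::bw.nrd0(x)
  grid <- seq(min(x), max(x), length.out = n_grid)
  dens <- vapply(grid, function(t) sum(exp(-0.5 * ((t - x) / h)^2)),
                 numeric(1))
  grid[which.max(dens)]
}

# Minimal PSM table holding only what FDR validation needs.
fdr_table <- function(target_scores, decoy_scores) {
  n_t <- length(target_scores); n_d <- length(decoy_scores)
  data.frame(
    spectrum_id = sprintf("s%04d", seq_len(n_t + n_d)),
    experiment_id = "exp1",
    peptide_sequence = "AAAAAAK",
    protein_accession = c(rep("T", n_t), rep("DECOY_T", n_d)),
    is_decoy = c(rep(0L, n_t), rep(1L, n_d)),
    score = c(target_scores, decoy_scores),
    intensity_114 = 1, intensity_115 = 1, intensity_116 = 1,
    intensity_117 = 1,
    stringsAsFactors = FALSE
  )
}

# Exhaustive FDR oracle: scan every distinct score as a candidate threshold.
validate_oracle <- function(tab, level) {
  best <- NULL
  for (s in sort(unique(tab$score))) {
    n_t <- sum(tab$score >= s & tab$is_decoy == 0)
    n_d <- sum(tab$score >= s & tab$is_decoy == 1)
    if (n_t > 0 && n_d / n_t <= level) {
      best <- s
      break
    }
  }
  if (is.null(best)) return(tab[integer(0), ])
  tab[tab$is_decoy == 0 & tab$score >= best, ]
}
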