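# Shared fixtures: all synthetic, built in code at test time.

# A small, fast generator configuration for structural tests.
small_config <- function(seed = 1L, ...) {
  generator_config(n_proteins = 60L,
                   peptides_per_protein = list(mean = 4, dispersion = 3),
                   psms_per_peptide = list(mean = 3, dispersion = 3),
                   seed = seed, ...)
}

# Fully noiseless configuration: zero biological spread, zero PSM noise,
# unit channel bias. Combined with the identity purity matrix, every
# pipeline stage is exact.
noiseless_config <- function(seed = 1L, n_proteins = 60L, ...) {
  generator_config(n_proteins = n_proteins,
                   peptides_per_protein = list(mean = 4, dispersion = 3),
                   psms_per_peptide = list(mean = 3, dispersion = 3),
                   protein_log2_ratio_sd = 0,
                   psm_log2_noise_sd_at_median_abundance = 0,
                   channel_bias_factors = list(rep(1, 4), rep(1, 4), rep(1, 4)),
                   fraction_decoy_psms = 0,
                   seed = seed, ...)
}

# Hand-built 2-PSM toy table on experiment 1 (donor 1: base 114 / ripc 115;
# donor 2: base 116 / ripc 117).
toy_psm_table <- function(i114 = c(100, 100), i115 = c(100, 200),
                          i116 = c(50, 80), i117 = c(50, 80),
                          experiment_id = "exp1") {
  n <- max(length(i114), length(i115), length(i116), length(i117))
  i114 <- rep_len(i114, n); i115 <- rep_len(i115, n)
  i116 <- rep_len(i116, n); i117 <- rep_len(i117, n)
  data.frame(
    spectrum_id = sprintf("t%03d", seq_len(n)),
    experiment_id = rep_len(experiment_id, n),
    peptide_sequence = sprintf("PEPTIDEAAK%d", seq_len(n)),
    protein_accession = rep_len("SYNP0001", n),
    is_decoy = 0L,
    score = rep_len(5, n),
    intensity_114 = i114, intensity_115 = i115,
    intensity_116 = i116, intensity_117 = i117,
    stringsAsFactors = FALSE
  )
}

# Cache for the ten default null-pipeline runs shared by the acceptance
# tests (fold-change stability, type-I calibration, recovery error).
.null_cache <- new.env(parent = emptyenv())

null_run_metrics <- function(seeds = 1:10) {
  key <- paste0("s", paste(seeds, collapse = "_"))
  if (!is.null(.null_cache[[key]])) {
    return(.null_cache[[key]])
  }
  rows <- lapply(seeds, function(s) {
    ds <- generate_dataset(generator_config(seed = s))
    res <- run_quantify(
      ds$psms, ds$design,
      protein_info = ds$truth$proteins[, c("protein_accession",
                                           "molecular_weight_kda")])
    st <- res$stats
    tr <- ds$truth$proteins
    m <- match(st$protein_accession, tr$protein_accession)
    data.frame(
      seed = s,
      n_retained = nrow(st),
      pct_in_band = 100 * mean(st$fold_change >= 0.91 &
                                 st$fold_change <= 1.1),
      t_flagged = sum(st$t_pvalue < 0.01, na.rm = TRUE),
      bg_flag_high = sum(st$background_probability < 0.01 &
                           st$combined_log2 >= res$background$m),
      bg_flag_low = sum(st$background_probability < 0.01 &
                          st$combined_log2 < res$background$m),
      n_tested = sum(!is.na(st$t_pvalue)),
      mae = stats::median(abs(st$combined_log2 - tr$true_median_log2[m]))
    )
  })
  out <- do.call(rbind, rows)
  .null_cache[[key]] <- out
  out
}
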