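#' Configuration for the synthetic PSM generator
#'
#' Parameters of the synthetic data generator that emulates the paired
#' six-donor, three-experiment 4-plex iTRAQ plasma design. Defaults encode
#' the study conditions the pipeline is validated under: ~400 quantifiable
#' proteins whose unregulated per-donor log2 ratios spread with sd 0.055
#' (the technical + biological stability of plasma iTRAQ ratios), PSM-level
#' multiplicative noise of 0.15 log2 units at median abundance inflating at
#' low abundance as (median/abundance)^0.5, plus decoys, contaminants and
#' immunodepletion (MARS) targets.
#'
#' @param n_proteins number of target proteins (default 400).
#' @param peptides_per_protein list(mean, dispersion) of the shifted
#'   negative-binomial peptide count per protein (minimum 1).
#' @param psms_per_peptide list(mean, dispersion) of the negative-binomial
#'   PSM count per peptide per experiment (0 allowed: peptide missed in
#'   that run).
#' @param protein_log2_ratio_sd sd of the true per-donor log2 RIPC/baseline
#'   ratios of unregulated proteins (default 0.055).
#' @param psm_log2_noise_sd_at_median_abundance per-channel log2 noise sd
#'   for a protein at median abundance (default 0.15).
#' @param abundance_noise_exponent exponent of the low-abundance noise
#'   inflation (default 0.5).
#' @param fraction_regulated fraction of proteins given a true regulation
#'   (default 0: null dataset).
#' @param regulated_effect_log2 absolute true log2 effect of regulated
#'   proteins; signs alternate up/down (default 1).
#' @param fraction_decoy_psms fraction of all PSMs that are decoy matches
#'   (default 0.05).
#' @param fraction_contaminant_proteins fraction of proteins that are
#'   standard contaminants (default 0.02).
#' @param fraction_mars_target_proteins fraction of proteins that are MARS
#'   depletion targets (default 0.02, at most the 14 known targets).
#' @param channel_bias_factors list of three numeric(4) multiplicative
#'   channel biases (one per experiment), removed later by median
#'   normalization.
#' @param abundance_log2_sd sd (log2) of the protein abundance
#'   distribution around the population median (default 0.5, the spread of
#'   the accurately quantified core of the depleted plasma proteome; see
#'   the methods vignette for how this and the count distributions were
#'   fixed by the fold-change stability calibration).
#' @param peptide_response_log2_sd sd (log2) of per-peptide ionization
#'   efficiency (default 1).
#' @param psm_scan_log2_sd sd (log2) of the per-spectrum total-signal
#'   factor, common to all four channels of a PSM (default 0.5).
#' @param base_intensity reporter intensity scale of a median-abundance
#'   protein (default 1e4).
#' @param target_score_mean,decoy_score_mean,score_sd parameters of the
#'   generic monotone search-score model (normal).
#' @param protein_length_mean_aa,protein_length_log2_sd length distribution
#'   of the full (partly unobserved) protein sequences used for molecular
#'   weights.
#' @param seed integer RNG seed; a fixed seed reproduces the dataset
#'   byte-identically.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(n_proteins = 400L,
                             peptides_per_protein = list(mean = 8, dispersion = 5),
                             psms_per_peptide = list(mean = 12, dispersion = 5),
                             protein_log2_ratio_sd = 0.055,
                             psm_log2_noise_sd_at_median_abundance = 0.15,
                             abundance_noise_exponent = 0.5,
                             fraction_regulated = 0,
                             regulated_effect_log2 = 1,
                             fraction_decoy_psms = 0.05,
                             fraction_contaminant_proteins = 0.02,
                             fraction_mars_target_proteins = 0.02,
                             channel_bias_factors = list(
                               c(1.00, 0.94, 1.07, 0.96),
                               c(0.97, 1.05, 1.00, 0.92),
                               c(1.04, 0.98, 0.95, 1.02)),
                             abundance_log2_sd = 0.5,
                             peptide_response_log2_sd = 1,
                             psm_scan_log2_sd = 0.5,
                             base_intensity = 1e4,
                             target_score_mean = 3.5,
                             decoy_score_mean = 0,
                             score_sd = 1,
                             protein_length_mean_aa = 450,
                             protein_length_log2_sd = 0.5,
                             seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = peptides_per_protein,
    psms_per_peptide = psms_per_peptide,
    protein_log2_ratio_sd = protein_log2_ratio_sd,
    psm_log2_noise_sd_at_median_abundance = psm_log2_noise_sd_at_median_abundance,
    abundance_noise_exponent = abundance_noise_exponent,
    fraction_regulated = fraction_regulated,
    regulated_effect_log2 = regulated_effect_log2,
    fraction_decoy_psms = fraction_decoy_psms,
    fraction_contaminant_proteins = fraction_contaminant_proteins,
    fraction_mars_target_proteins = fraction_mars_target_proteins,
    channel_bias_factors = channel_bias_factors,
    abundance_log2_sd = abundance_log2_sd,
    peptide_response_log2_sd = peptide_response_log2_sd,
    psm_scan_log2_sd = psm_scan_log2_sd,
    base_intensity = base_intensity,
    target_score_mean = target_score_mean,
    decoy_score_mean = decoy_score_mean,
    score_sd = score_sd,
    protein_length_mean_aa = protein_length_mean_aa,
    protein_length_log2_sd = protein_length_log2_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_proteins < 1L) stop("generator_config: n_proteins must be positive")
  fr <- c(cfg$fraction_regulated, cfg$fraction_decoy_psms,
          cfg$fraction_contaminant_proteins, cfg$fraction_mars_target_proteins)
  if (any(fr < 0 | fr > 1)) {
    stop("generator_config: all fractions must lie in [0, 1]")
  }
  if (cfg$protein_log2_ratio_sd < 0 ||
      cfg$psm_log2_noise_sd_at_median_abundance < 0) {
    stop("generator_config: spreads must be non-negative")
  }
  if (cfg$peptides_per_protein$mean < 1 ||
      cfg$peptides_per_protein$dispersion <= 0 ||
      cfg$psms_per_peptide$mean <= 0 ||
      cfg$psms_per_peptide$dispersion <= 0) {
    stop("generator_config: count distribution parameters must be positive")
  }
  if (cfg$base_intensity <= 0) {
    stop("generator_config: base_intensity must be positive")
  }
  if (length(cfg$channel_bias_factors) != 3L ||
      !all(vapply(cfg$channel_bias_factors,
                  function(b) length(b) == 4L && all(b > 0), logical(1)))) {
    stop("generator_config: channel_bias_factors must be three positive 4-vectors")
  }
  invisible(cfg)
}

# Deterministic random tryptic-like peptide: random residues ending in K/R.
.random_peptides <- function(n, min_len = 7L, max_len = 18L) {
  body_aas <- setdiff(names(.aa_average_masses), c("K", "R"))
  out <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  i <- 1L
  while (i <= n) {
    len <- sample(min_len:max_len, 1L)
    pep <- paste0(paste(sample(body_aas, len - 1L, replace = TRUE),
                        collapse = ""),
                  sample(c("K", "R"), 1L))
    if (is.null(seen[[pep]])) {
      seen[[pep]] <- TRUE
      out[i] <- pep
      i <- i + 1L
    }
  }
  out
}

#' Generate a synthetic PSM-level dataset with ground truth
#'
#' Simulates the full paired multiplex design: three 4-plex experiments of
#' two donors each (\code{\link{default_design}}), target proteins with
#' log-normal abundances, tryptic peptides with per-peptide response
#' factors, per-experiment PSM counts, true per-donor log2 RIPC/baseline
#' ratios (iid zero-centered for unregulated proteins), per-channel
#' multiplicative log-normal noise whose log2 sd scales as
#' (median_abundance/abundance)^exponent, isotopic spillover through the
#' example purity matrix, per-experiment channel bias, plus decoy PSMs,
#' contaminant proteins and MARS depletion targets.
#'
#' @param config a \code{\link{generator_config}}.
#' @param purity a \code{\link{purity_matrix}} used to mix the true
#'   intensities into observed reporter intensities (default
#'   \code{\link{example_purity_matrix}()}).
#' @return list with elements \code{psms} (PSM table, see
#'   \code{\link{write_psm_table}}), \code{design}, \code{truth} (list:
#'   \code{proteins} per-protein truth table, \code{psm_true_intensities}
#'   per-PSM true intensities before impurity mixing, \code{config}).
#' @export
generate_dataset <- function(config = generator_config(),
                             purity = example_purity_matrix()) {
  validate_generator_config(config)
  stopifnot(inherits(purity, "purity_matrix"))
  set.seed(config$seed)
  design <- default_design()
  exp_ids <- unique(design$experiment_id)
  n <- config$n_proteins

  # --- protein-level truth ---------------------------------------------
  n_mars <- min(round(config$fraction_mars_target_proteins * n), 14L)
  n_contam <- min(round(config$fraction_contaminant_proteins * n),
                  length(default_contaminant_list()))
  n_plain <- n - n_mars - n_contam
  accession <- c(sprintf("SYNP%04d", seq_len(n_plain)),
                 default_mars_target_list()[seq_len(n_mars)],
                 default_contaminant_list()[seq_len(n_contam)])
  is_mars <- c(rep(FALSE, n_plain), rep(TRUE, n_mars), rep(FALSE, n_contam))
  is_contam <- c(rep(FALSE, n_plain + n_mars), rep(TRUE, n_contam))

  abundance <- config$base_intensity *
    2^stats::rnorm(n, 0, config$abundance_log2_sd)

  # regulated proteins are picked among plain targets; effects alternate sign
  regulated <- rep(FALSE, n)
  effect <- rep(0, n)
  n_reg <- round(config$fraction_regulated * n)
  if (n_reg > 0L) {
    idx <- sample(which(!is_mars & !is_contam), min(n_reg, n_plain))
    regulated[idx] <- TRUE
    effect[idx] <- config$regulated_effect_log2 *
      rep_len(c(1, -1), length(idx))
  }

  # true per-donor log2 ratios: iid zero-centered around the effect
  true_ratios <- matrix(stats::rnorm(n * 6L, 0, config$protein_log2_ratio_sd),
                        nrow = n, ncol = 6L) + effect
  colnames(true_ratios) <- paste0("true_log2_d", 1:6)

  # peptide counts (>=1) and full-length sequences for molecular weight
  ppp <- config$peptides_per_protein
  n_pep <- 1L + stats::rnbinom(n, size = ppp$dispersion, mu = ppp$mean - 1)
  total_len_aa <- round(config$protein_length_mean_aa *
                          2^stats::rnorm(n, 0, config$protein_length_log2_sd))

  peptide_seqs <- .random_peptides(sum(n_pep))
  pep_protein <- rep(seq_len(n), n_pep)
  pep_response <- 2^stats::rnorm(sum(n_pep), 0,
                                 config$peptide_response_log2_sd)

  # molecular weight: observed peptides plus unobserved filler residues up
  # to the drawn protein length (average residue mass for the filler)
  obs_len <- vapply(split(nchar(peptide_seqs), pep_protein), sum,
                    numeric(1))[as.character(seq_len(n))]
  obs_mass <- vapply(split(peptide_seqs, pep_protein),
                     function(pp) sum(molecular_weight_kda(pp)) -
                       (length(pp) - 1L) * .water_mass / 1000,
                     numeric(1))[as.character(seq_len(n))]
  filler_aa <- pmax(0, total_len_aa - obs_len)
  mw_kda <- obs_mass + filler_aa * mean(.aa_average_masses) / 1000

  truth_proteins <- data.frame(
    protein_accession = accession,
    is_contaminant = as.integer(is_contam),
    is_mars_target = as.integer(is_mars),
    regulated = as.integer(regulated),
    effect_log2 = effect,
    abundance = abundance,
    molecular_weight_kda = mw_kda,
    n_peptides = n_pep,
    stringsAsFactors = FALSE
  )
  truth_proteins <- cbind(truth_proteins, as.data.frame(true_ratios))
  truth_proteins$true_median_log2 <- apply(true_ratios, 1L, stats::median)
  rownames(truth_proteins) <- NULL

  # --- target PSMs ------------------------------------------------------
  ppsm <- config$psms_per_peptide
  n_peptides_total <- sum(n_pep)
  # PSM count per peptide per experiment
  psm_counts <- matrix(stats::rnbinom(n_peptides_total * 3L,
                                      size = ppsm$dispersion, mu = ppsm$mean),
                       nrow = n_peptides_total, ncol = 3L)
  # every protein appears in the PSM table at least once (the truth sidecar
  # joins 1:1 with the observed accessions)
  psms_per_protein <- rowsum(rowSums(psm_counts), pep_protein)
  orphan <- as.integer(rownames(psms_per_protein))[psms_per_protein[, 1L] == 0]
  if (length(orphan) > 0L) {
    first_pep <- match(orphan, pep_protein)
    psm_counts[first_pep, 1L] <- 1L
  }
  pep_idx <- rep(rep(seq_len(n_peptides_total), 3L), as.vector(psm_counts))
  exp_idx <- rep(rep(1:3, each = n_peptides_total), as.vector(psm_counts))
  m <- length(pep_idx)
  prot_idx <- pep_protein[pep_idx]

  # per-PSM noise sd from protein abundance (population median = base)
  noise_sd <- config$psm_log2_noise_sd_at_median_abundance *
    (config$base_intensity / abundance[prot_idx])^config$abundance_noise_exponent

  scan_factor <- 2^stats::rnorm(m, 0, config$psm_scan_log2_sd)
  base_level <- abundance[prot_idx] * pep_response[pep_idx] * scan_factor

  # channel conditions/donors per experiment from the design
  ch_cols <- paste0("intensity_", 114:117)
  true_int <- matrix(0, nrow = m, ncol = 4L, dimnames = list(NULL, ch_cols))
  for (e in 1:3) {
    rows <- exp_idx == e
    if (!any(rows)) next
    d <- design[design$experiment_id == exp_ids[e], ]
    d <- d[order(d$channel), ]
    for (k in 1:4) {
      fold <- if (d$condition[k] == "ripc") {
        2^true_ratios[prot_idx[rows], d$donor_id[k]]
      } else 1
      true_int[rows, k] <- base_level[rows] * fold
    }
  }
  # multiplicative log-normal noise, per channel
  if (config$psm_log2_noise_sd_at_median_abundance > 0) {
    true_int <- true_int *
      2^(matrix(stats::rnorm(m * 4L), nrow = m, ncol = 4L) * noise_sd)
  }
  true_int <- pmax(true_int, 0)

  # mix through the purity matrix, apply channel bias, floor at zero
  mix <- purity_mixing_matrix(purity)
  obs_int <- true_int %*% t(mix)
  colnames(obs_int) <- ch_cols
  for (e in 1:3) {
    rows <- exp_idx == e
    obs_int[rows, ] <- sweep(obs_int[rows, , drop = FALSE], 2L,
                             config$channel_bias_factors[[e]], `*`)
  }
  obs_int <- pmax(obs_int, 0)

  target_psms <- data.frame(
    spectrum_id = sprintf("e%d_s%06d", exp_idx, seq_len(m)),
    experiment_id = exp_ids[exp_idx],
    peptide_sequence = peptide_seqs[pep_idx],
    protein_accession = accession[prot_idx],
    is_decoy = 0L,
    score = stats::rnorm(m, config$target_score_mean, config$score_sd),
    stringsAsFactors = FALSE
  )
  target_psms <- cbind(target_psms, as.data.frame(obs_int))

  # --- decoy PSMs -------------------------------------------------------
  f <- config$fraction_decoy_psms
  n_decoy <- if (f > 0) round(f / (1 - f) * m) else 0L
  if (n_decoy > 0L) {
    decoy_exp <- sample(1:3, n_decoy, replace = TRUE)
    decoy_int <- matrix(config$base_intensity * 0.05 *
                          2^stats::rnorm(n_decoy * 4L, 0, 1),
                        nrow = n_decoy, ncol = 4L,
                        dimnames = list(NULL, ch_cols))
    decoy_psms <- data.frame(
      spectrum_id = sprintf("e%d_d%06d", decoy_exp, seq_len(n_decoy)),
      experiment_id = exp_ids[decoy_exp],
      peptide_sequence = .random_peptides(n_decoy),
      protein_accession = paste0("DECOY_",
                                 sample(accession, n_decoy, replace = TRUE)),
      is_decoy = 1L,
      score = stats::rnorm(n_decoy, config$decoy_score_mean, config$score_sd),
      stringsAsFactors = FALSE
    )
    decoy_psms <- cbind(decoy_psms, as.data.frame(decoy_int))
    psms <- rbind(target_psms, decoy_psms)
  } else {
    psms <- target_psms
  }
  rownames(psms) <- NULL

  truth <- list(
    proteins = truth_proteins,
    psm_true_intensities = data.frame(
      spectrum_id = target_psms$spectrum_id,
      true_114 = true_int[, 1L], true_115 = true_int[, 2L],
      true_116 = true_int[, 3L], true_117 = true_int[, 4L],
      stringsAsFactors = FALSE),
    config = config
  )
  list(psms = psms, design = design, truth = truth)
}
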