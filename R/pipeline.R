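#' Run the full quantification and regulation analysis
#'
#' Orchestrates validate (decoy FDR) -> isotope-impurity correction ->
#' per-experiment median normalization -> PSM/peptide/protein ratio
#' estimation with per-donor median centering -> paired t-test +
#' asymmetric-normal background test -> A-D categories, abundance indexes
#' and relevance flags, with a stage-count summary (identified ->
#' >=2-peptide quantified -> after exclusions -> per category).
#'
#' @param psms PSM table (data.frame, see \code{\link{write_psm_table}}
#'   for columns) or path to one.
#' @param design design table or path (see \code{\link{default_design}}).
#' @param purity a \code{\link{purity_matrix}} or path to one.
#' @param protein_info optional data.frame with columns
#'   \code{protein_accession} and \code{molecular_weight_kda} (sequence
#'   database knowledge). When absent, molecular weights are approximated
#'   from the observed peptide sequences (a lower bound; flagged in the
#'   log).
#' @param fdr_level PSM validation FDR (default 0.01).
#' @param t_p_threshold,bg_p_threshold classification thresholds (default
#'   0.01 each).
#' @param relevance_pct relevance bound on the percent change (default 20).
#' @param min_unique_peptides retention threshold (default 2).
#' @param mars_list,contaminant_list exclusion lists.
#' @param two_sided_background use the two-sided background probability
#'   (default FALSE: one-sided on the observed side).
#' @param out_dir optional output directory for the result tables
#'   (\code{protein_quants.tsv}, \code{regulation_stats.tsv},
#'   \code{summary.tsv}, \code{run_log.txt}).
#' @param overwrite allow overwriting existing outputs (default FALSE).
#' @param verbose emit log lines as messages.
#' @return object of class \code{ripc_quant_result}: list with
#'   \code{protein_quants} (all quantified proteins), \code{stats}
#'   (retained proteins with tests, categories, abundance index),
#'   \code{background}, \code{summary}, \code{log}.
#' @export
run_quantify <- function(psms, design, purity = example_purity_matrix(),
                         protein_info = NULL,
                         fdr_level = 0.01,
                         t_p_threshold = 0.01,
                         bg_p_threshold = 0.01,
                         relevance_pct = 20,
                         min_unique_peptides = 2L,
                         mars_list = default_mars_target_list(),
                         contaminant_list = default_contaminant_list(),
                         two_sided_background = FALSE,
                         out_dir = NULL, overwrite = FALSE,
                         verbose = FALSE) {
  if (is.character(psms)) psms <- read_psm_table(psms)
  if (is.character(design)) design <- read_design(design)
  if (is.character(purity)) purity <- read_purity_matrix(purity)
  validate_design(design)
  stopifnot(fdr_level > 0, fdr_level < 1,
            t_p_threshold > 0, t_p_threshold < 1,
            bg_p_threshold > 0, bg_p_threshold < 1,
            relevance_pct > 0, min_unique_peptides >= 1L)

  # consistency before any computation
  extra <- setdiff(unique(psms$experiment_id), unique(design$experiment_id))
  if (length(extra) > 0L) {
    stop(sprintf("run_quantify: PSM table uses experiment(s) not in design: %s",
                 paste(extra, collapse = ", ")))
  }
  out_paths <- NULL
  if (!is.null(out_dir)) {
    out_paths <- file.path(out_dir, c("protein_quants.tsv",
                                      "regulation_stats.tsv",
                                      "summary.tsv", "run_log.txt"))
    if (!overwrite && any(file.exists(out_paths))) {
      stop(sprintf("run_quantify: output(s) already exist in '%s' (use overwrite = TRUE)",
                   out_dir))
    }
  }

  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
    invisible(NULL)
  }
  note("input: %d PSMs (%d decoys), %d experiments", nrow(psms),
       sum(psms$is_decoy != 0), length(unique(psms$experiment_id)))

  validated <- validate_at_fdr(psms, level = fdr_level)
  note("validated at %.3g FDR: %d target PSMs", fdr_level, nrow(validated))
  if (nrow(validated) == 0L) {
    stop("run_quantify: no PSMs validated at the requested FDR")
  }
  n_identified <- length(unique(validated$protein_accession))
  note("identified proteins: %d", n_identified)

  corrected <- correct_psm_table(validated, purity)
  note("isotope correction: %d PSM(s) had a negative component clipped",
       sum(corrected$isotope_clipped))
  normalized <- normalize_channel_intensities(corrected)
  note("median normalization applied per experiment")

  ratios <- psm_log2_ratios(normalized, design)
  pq <- peptide_quants(ratios)
  prot <- aggregate_protein_ratios(pq, design, mars_list = mars_list,
                                   contaminant_list = contaminant_list,
                                   min_unique_peptides = min_unique_peptides)

  # validated PSM counts and molecular weights
  psm_counts <- table(validated$protein_accession)
  prot$n_psms <- as.integer(psm_counts[prot$protein_accession])
  if (!is.null(protein_info)) {
    stopifnot(all(c("protein_accession", "molecular_weight_kda")
                  %in% names(protein_info)))
    mw <- protein_info$molecular_weight_kda[
      match(prot$protein_accession, protein_info$protein_accession)]
    note("molecular weights from supplied protein_info (%d matched)",
         sum(!is.na(mw)))
  } else {
    pep_by_prot <- split(unique(validated[, c("protein_accession",
                                              "peptide_sequence")])$peptide_sequence,
                         unique(validated[, c("protein_accession",
                                              "peptide_sequence")])$protein_accession)
    mw <- vapply(pep_by_prot, function(pp) {
      sum(molecular_weight_kda(pp)) - (length(pp) - 1L) * .water_mass / 1000
    }, numeric(1))[prot$protein_accession]
    note("molecular weights approximated from observed peptides (lower bound)")
  }
  prot$molecular_weight_kda <- unname(mw)

  filt <- filter_quantifiable(prot, min_unique_peptides)
  retained <- filt$retained
  note("quantified with >=%d unique peptides: %d; retained after contaminant/depletion exclusion: %d",
       min_unique_peptides, filt$counts[["min_peptides"]],
       filt$counts[["after_exclusions"]])

  donor_cols <- grep("^log2_d", names(prot), value = TRUE)
  t_p <- apply(as.matrix(retained[, donor_cols]), 1L, paired_t_test)
  bg_model <- fit_background(retained$combined_log2)
  bg_p <- background_probability(retained$combined_log2, bg_model,
                                 two_sided = two_sided_background)
  category <- classify_regulation(t_p, bg_p, t_p_threshold, bg_p_threshold)
  fold_change <- 2^retained$combined_log2
  mw_ok <- !is.na(retained$molecular_weight_kda) &
    retained$molecular_weight_kda > 0
  abund <- rep(NA_real_, nrow(retained))
  abund[mw_ok] <- abundance_index(retained$n_psms[mw_ok],
                                  retained$molecular_weight_kda[mw_ok])

  stats_tab <- data.frame(
    protein_accession = retained$protein_accession,
    combined_log2 = retained$combined_log2,
    fold_change = fold_change,
    t_pvalue = unname(t_p),
    background_probability = unname(bg_p),
    category = category,
    abundance_index = abund,
    relevance = relevance_flag(fold_change, relevance_pct),
    n_peptides = retained$n_peptides,
    n_psms = retained$n_psms,
    stringsAsFactors = FALSE
  )
  cat_counts <- vapply(c("A", "B", "C", "D"),
                       function(k) sum(category == k), integer(1))
  note("background model: m = %.4f, sigma_low = %.4f, sigma_high = %.4f",
       bg_model$m, bg_model$sigma_low, bg_model$sigma_high)
  note("categories: A = %d, B = %d, C = %d, D = %d",
       cat_counts[["A"]], cat_counts[["B"]], cat_counts[["C"]],
       cat_counts[["D"]])
  note("thresholds: fdr = %g, t_p = %g, bg_p = %g, relevance = %g%%, min_peptides = %d",
       fdr_level, t_p_threshold, bg_p_threshold, relevance_pct,
       as.integer(min_unique_peptides))
  note("exclusion lists: %d depletion targets, %d contaminants",
       length(mars_list), length(contaminant_list))

  summary_row <- data.frame(
    n_identified = n_identified,
    n_quantified = unname(filt$counts[["min_peptides"]]),
    n_retained = unname(filt$counts[["after_exclusions"]]),
    n_category_A = cat_counts[["A"]], n_category_B = cat_counts[["B"]],
    n_category_C = cat_counts[["C"]], n_category_D = cat_counts[["D"]]
  )

  result <- list(protein_quants = prot, stats = stats_tab,
                 background = bg_model, summary = summary_row,
                 log = log_lines)
  class(result) <- "ripc_quant_result"

  if (!is.null(out_paths)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(prot, out_paths[[1L]])
    .write_tsv(stats_tab, out_paths[[2L]])
    .write_tsv(summary_row, out_paths[[3L]])
    writeLines(log_lines, out_paths[[4L]])
  }
  result
}

#' @export
print.ripc_quant_result <- function(x, ...) {
  s <- x$summary
  cat("iTRAQ quantification result\n")
  cat(sprintf("  identified proteins:        %d\n", s$n_identified))
  cat(sprintf("  quantified (>=2 peptides):  %d\n", s$n_quantified))
  cat(sprintf("  retained after exclusions:  %d\n", s$n_retained))
  cat(sprintf("  categories A/B/C/D:         %d / %d / %d / %d\n",
              s$n_category_A, s$n_category_B, s$n_category_C,
              s$n_category_D))
  invisible(x)
}

#' Regenerate summary and figure-coordinate tables from stored outputs
#'
#' Re-derives reporting tables from a \code{\link{run_quantify}} output
#' directory without recomputing anything: a volcano table (combined log2
#' ratio vs -log10 t-test p-value, with category and background
#' probability) and a regulation-vs-abundance table (abundance index vs
#' combined log2 ratio), both written as TSV.
#'
#' @param in_dir directory containing \code{regulation_stats.tsv} (and
#'   optionally \code{summary.tsv}) from a previous run.
#' @param out_dir output directory (default \code{in_dir}).
#' @param overwrite allow overwriting existing report tables.
#' @return (invisibly) list with the two coordinate data.frames and the
#'   stage summary (if present).
#' @export
run_report <- function(in_dir, out_dir = in_dir, overwrite = FALSE) {
  stats_path <- file.path(in_dir, "regulation_stats.tsv")
  if (!file.exists(stats_path)) {
    stop(sprintf("run_report: no regulation_stats.tsv in '%s'", in_dir))
  }
  st <- utils::read.delim(stats_path, stringsAsFactors = FALSE)
  paths <- file.path(out_dir, c("volcano_coordinates.tsv",
                                "abundance_coordinates.tsv"))
  if (!overwrite && any(file.exists(paths))) {
    stop(sprintf("run_report: report table(s) already exist in '%s' (use overwrite = TRUE)",
                 out_dir))
  }
  volcano <- data.frame(
    protein_accession = st$protein_accession,
    combined_log2 = st$combined_log2,
    neg_log10_t_pvalue = -log10(st$t_pvalue),
    background_probability = st$background_probability,
    category = st$category,
    stringsAsFactors = FALSE
  )
  abundance <- data.frame(
    protein_accession = st$protein_accession,
    abundance_index = st$abundance_index,
    combined_log2 = st$combined_log2,
    category = st$category,
    stringsAsFactors = FALSE
  )
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  .write_tsv(volcano, paths[[1L]])
  .write_tsv(abundance, paths[[2L]])
  summary_path <- file.path(in_dir, "summary.tsv")
  smry <- if (file.exists(summary_path)) {
    utils::read.delim(summary_path)
  }
  invisible(list(volcano = volcano, abundance = abundance, summary = smry))
}

#' Simulate a dataset and write it to disk
#'
#' Runs \code{\link{generate_dataset}} and writes the PSM table, design
#' and per-protein ground-truth sidecar as tab-separated files, plus the
#' purity matrix used for mixing and a log of the effective configuration.
#' Refuses to overwrite existing outputs unless \code{overwrite = TRUE}.
#'
#' @param config a \code{\link{generator_config}}.
#' @param out_dir output directory (created if missing).
#' @param purity mixing purity matrix (default
#'   \code{\link{example_purity_matrix}()}).
#' @param overwrite allow overwriting existing outputs.
#' @return (invisibly) the \code{\link{generate_dataset}} result with an
#'   added \code{paths} element.
#' @export
run_simulate <- function(config = generator_config(), out_dir,
                         purity = example_purity_matrix(),
                         overwrite = FALSE) {
  paths <- file.path(out_dir, c("psm_table.tsv", "design.tsv", "truth.tsv",
                                "purity_matrix.tsv", "simulate_log.txt"))
  names(paths) <- c("psms", "design", "truth", "purity", "log")
  if (!overwrite && any(file.exists(paths))) {
    stop(sprintf("run_simulate: output(s) already exist in '%s' (use overwrite = TRUE)",
                 out_dir))
  }
  ds <- generate_dataset(config, purity = purity)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_psm_table(ds$psms, paths[["psms"]])
  write_design(ds$design, paths[["design"]])
  write_truth(ds$truth$proteins, paths[["truth"]])
  write_purity_matrix(purity, paths[["purity"]])
  cfg <- ds$truth$config
  writeLines(c("effective generator configuration:",
               vapply(names(cfg), function(nm) {
                 sprintf("  %s = %s", nm,
                         paste(format(unlist(cfg[[nm]]), digits = 10),
                               collapse = ", "))
               }, character(1))),
             paths[["log"]])
  ds$paths <- paths
  invisible(ds)
}
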