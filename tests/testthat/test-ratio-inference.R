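test_that("per-donor PSM ratios follow the design, including the exp2 swap", {
  # donor 1 (exp1): ripc in 115, baseline in 114
  tab <- toy_psm_table(i114 = c(100, 100), i115 = c(100, 200),
                       i116 = c(50, 50), i117 = c(50, 100))
  r <- psm_log2_ratios(tab, default_design())
  d1 <- r[r$donor_id == 1, ]
  expect_equal(d1$log2_ratio, c(0, 1))
  d2 <- r[r$donor_id == 2, ]
  expect_equal(d2$log2_ratio, c(0, 1))

  # donor 3 (exp2): ripc in 114, baseline in 115 - the label swap
  tab2 <- toy_psm_table(i114 = 200, i115 = 100, i116 = 80, i117 = 80,
                        experiment_id = "exp2")
  r2 <- psm_log2_ratios(tab2, default_design())
  expect_equal(r2$log2_ratio[r2$donor_id == 3], 1)

  # non-positive intensity -> missing ratio
  tab3 <- toy_psm_table(i114 = 0, i115 = 100, i116 = 50, i117 = 50)
  r3 <- psm_log2_ratios(tab3, default_design())
  expect_true(is.na(r3$log2_ratio[r3$donor_id == 1]))

  tab4 <- toy_psm_table(experiment_id = "exp9")
  expect_error(psm_log2_ratios(tab4, default_design()), "exp9")
})

test_that("peptide quantification aggregates PSM ratios per donor", {
  tab <- toy_psm_table(i114 = c(100, 100), i115 = c(200, 200),
                       i116 = c(50, 50), i117 = c(50, 50))
  pq <- peptide_quants(psm_log2_ratios(tab, default_design()))
  expect_equal(nrow(pq), 4)  # 2 peptides x 2 donors
  expect_equal(pq$log2_ratio[pq$donor_id == 1], c(1, 1))
  expect_equal(pq$log2_ratio[pq$donor_id == 2], c(0, 0))
  expect_true(all(pq$n_psms == 1))
})

test_that("centering removes a global shift for a single protein", {
  pq <- data.frame(protein_accession = "P1",
                   peptide_sequence = c("A", "B", "C"),
                   donor_id = 1L, log2_ratio = c(0.2, 0.2, 0.2),
                   n_psms = 1L)
  out <- aggregate_protein_ratios(pq, default_design(),
                                  mars_list = character(0),
                                  contaminant_list = character(0))
  expect_equal(out$log2_d1, 0)       # median across the single protein is 0.2
  expect_equal(out$combined_log2, 0)
  expect_true(out$retained)
})

test_that("a symmetric pair of proteins is unchanged by centering", {
  pq <- data.frame(
    protein_accession = rep(c("P1", "P2"), each = 2),
    peptide_sequence = c("A", "B", "C", "D"),
    donor_id = 1L,
    log2_ratio = c(0.1, 0.1, -0.1, -0.1),
    n_psms = 1L)
  out <- aggregate_protein_ratios(pq, default_design(),
                                  mars_list = character(0),
                                  contaminant_list = character(0))
  expect_equal(sort(out$log2_d1), c(-0.1, 0.1))
})

test_that("retention needs two unique quantified peptides and clean flags", {
  pq <- data.frame(
    protein_accession = c("P1", "P2", "P2", "albumin", "albumin",
                          "CONTAM_KRT1", "CONTAM_KRT1"),
    peptide_sequence = c("A", "B", "C", "D", "E", "F", "G"),
    donor_id = 1L,
    log2_ratio = 0.05 * (1:7),
    n_psms = 1L)
  out <- aggregate_protein_ratios(pq, default_design())
  filt <- filter_quantifiable(out)
  expect_setequal(filt$retained$protein_accession, "P2")
  expect_equal(unname(filt$counts), c(4, 3, 1))
  expect_true(out$mars_target[out$protein_accession == "albumin"])
  expect_true(out$contaminant[out$protein_accession == "CONTAM_KRT1"])
})

test_that("adding peptides to a protein never removes it from the retained set", {
  base <- data.frame(
    protein_accession = c("P1", "P1", "P2", "P2"),
    peptide_sequence = c("A", "B", "C", "D"),
    donor_id = 1L, log2_ratio = c(0, 0.1, -0.1, 0.05), n_psms = 1L)
  before <- filter_quantifiable(
    aggregate_protein_ratios(base, default_design()))$retained
  extra <- rbind(base, data.frame(protein_accession = "P1",
                                  peptide_sequence = "E", donor_id = 1L,
                                  log2_ratio = 0.02, n_psms = 1L))
  after <- filter_quantifiable(
    aggregate_protein_ratios(extra, default_design()))$retained
  expect_true(all(before$protein_accession %in% after$protein_accession))
})

test_that("per-donor medians over retained proteins are exactly zero (odd counts)", {
  ds <- generate_dataset(small_config(seed = 8))
  res <- run_quantify(ds$psms, ds$design)
  prot <- res$protein_quants
  kept <- prot[prot$retained, ]
  for (dcol in paste0("log2_d", 1:6)) {
    v <- kept[[dcol]][!is.na(kept[[dcol]])]
    if (length(v) %% 2 == 1) {
      expect_identical(median(v), 0)
    } else {
      expect_lt(abs(median(v)), diff(range(v)) + 1e-15)
    }
  }
})

test_that("the noiseless limit reproduces ground truth exactly through aggregation", {
  cfg <- noiseless_config(seed = 9, fraction_regulated = 0.05,
                          regulated_effect_log2 = 1)
  ds <- generate_dataset(cfg, purity = identity_purity_matrix())
  validated <- validate_at_fdr(ds$psms)
  corrected <- correct_psm_table(validated, identity_purity_matrix())
  normalized <- normalize_channel_intensities(corrected)
  pq <- peptide_quants(psm_log2_ratios(normalized, ds$design))
  prot <- aggregate_protein_ratios(pq, ds$design)
  tr <- ds$truth$proteins
  m <- match(prot$protein_accession, tr$protein_accession)
  expect_equal(prot$combined_log2, tr$effect_log2[m], tolerance = 1e-12)
  for (d in 1:6) {
    have <- !is.na(prot[[paste0("log2_d", d)]])
    expect_equal(prot[[paste0("log2_d", d)]][have],
                 tr[[paste0("true_log2_d", d)]][m][have], tolerance = 1e-12)
  }
})

test_that("a spiked protein is recovered close to its true ratio", {
  cfg <- generator_config(n_proteins = 150L,
                          peptides_per_protein = list(mean = 6, dispersion = 4),
                          psms_per_peptide = list(mean = 6, dispersion = 4),
                          fraction_regulated = 1 / 150,
                          regulated_effect_log2 = 1, seed = 10)
  ds <- generate_dataset(cfg)
  res <- run_quantify(ds$psms, ds$design)
  tr <- ds$truth$proteins
  spiked <- tr$protein_accession[tr$regulated == 1]
  expect_length(spiked, 1)
  est <- res$stats$combined_log2[res$stats$protein_accession == spiked]
  expect_lt(abs(est - 1), 0.1)
})

test_that("spiked ratios keep the correct sign across twenty seeded runs", {
  for (s in 1:20) {
    cfg <- generator_config(n_proteins = 60L,
                            peptides_per_protein = list(mean = 4, dispersion = 3),
                            psms_per_peptide = list(mean = 4, dispersion = 3),
                            fraction_regulated = 0.1,
                            regulated_effect_log2 = 1, seed = 100 + s)
    ds <- generate_dataset(cfg)
    res <- run_quantify(ds$psms, ds$design)
    tr <- ds$truth$proteins
    reg <- tr[tr$regulated == 1, ]
    st <- res$stats
    m <- match(reg$protein_accession, st$protein_accession)
    est <- st$combined_log2[m[!is.na(m)]]
    eff <- reg$effect_log2[!is.na(m)]
    expect_true(all(sign(est) == sign(eff)))
  }
})
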