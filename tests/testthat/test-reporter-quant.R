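# --- decoy FDR validation -------------------------------------------------

test_that("FDR boundary arithmetic: 10 decoys under 1000 targets all pass at 1%", {
  tab <- fdr_table(target_scores = 100 + seq_len(1000), decoy_scores = 1:10)
  out <- validate_at_fdr(tab, level = 0.01)
  expect_equal(nrow(out), 1000)
  expect_true(all(out$is_decoy == 0))
})

test_that("all decoys above all targets yields an empty validated set", {
  tab <- fdr_table(target_scores = 1:20, decoy_scores = 100 + (1:5))
  expect_equal(nrow(validate_at_fdr(tab, level = 0.01)), 0)
})

test_that("threshold matches the exhaustive scan on random interleaved tables", {
  set.seed(11)
  for (i in 1:200) {
    n_t <- sample(5:60, 1)
    n_d <- sample(1:20, 1)
    tab <- fdr_table(rnorm(n_t, mean = runif(1, 0, 2)), rnorm(n_d))
    level <- sample(c(0.01, 0.05, 0.2, 0.5), 1)
    got <- validate_at_fdr(tab, level)
    want <- validate_oracle(tab, level)
    expect_identical(sort(got$spectrum_id), sort(want$spectrum_id))
    # at the retained threshold the decoy/target ratio respects the level
    if (nrow(got) > 0) {
      s_star <- min(got$score)
      expect_lte(sum(tab$is_decoy == 1 & tab$score >= s_star) /
                   sum(tab$is_decoy == 0 & tab$score >= s_star), level)
    }
  }
})

test_that("degenerate FDR inputs are rejected", {
  tab <- fdr_table(numeric(0), decoy_scores = 1:3)
  expect_error(validate_at_fdr(tab, 0.01), "zero target")
  tab2 <- fdr_table(1:3, 1)
  expect_error(validate_at_fdr(tab2, 0), "between 0 and 1")
  expect_error(validate_at_fdr(tab2, 1), "between 0 and 1")
})

# --- isotope-impurity correction -----------------------------------------

test_that("identity purity leaves intensities untouched", {
  raw <- c(100, 200, 300, 400)
  out <- correct_isotope_impurities(raw, identity_purity_matrix())
  expect_equal(as.numeric(out), raw)
  expect_false(attr(out, "clipped"))
})

test_that("forward mixing followed by correction recovers the true vector", {
  # 2% of channel 114's signal spills to +1: true (1000,0,0,0) is observed
  # as (980,20,0,0)
  pm <- purity_matrix(pct_minus2 = rep(0, 4),
                      pct_minus1 = rep(0, 4),
                      pct_plus1 = c(2, 0, 0, 0),
                      pct_plus2 = rep(0, 4))
  true <- c(1000, 0, 0, 0)
  observed <- as.numeric(purity_mixing_matrix(pm) %*% true)
  expect_equal(observed, c(980, 20, 0, 0))
  expect_equal(as.numeric(correct_isotope_impurities(observed, pm)), true,
               tolerance = 1e-12)
})

test_that("forward-mix then correct is the identity on random vectors", {
  set.seed(5)
  pm <- example_purity_matrix()
  m <- purity_mixing_matrix(pm)
  for (i in 1:50) {
    true <- runif(4, 0, 1000)
    observed <- as.numeric(m %*% true)
    got <- correct_isotope_impurities(observed, pm)
    expect_equal(as.numeric(got), true, tolerance = 1e-9)
    expect_false(attr(got, "clipped"))
  }
})

test_that("negative solution components are clipped to zero and flagged", {
  pm <- purity_matrix(pct_minus2 = rep(0, 4), pct_minus1 = rep(0, 4),
                      pct_plus1 = c(5, 0, 0, 0), pct_plus2 = rep(0, 4))
  # observed 115 smaller than the spillover from 114 forces true_115 < 0
  out <- correct_isotope_impurities(c(950, 10, 0, 0), pm)
  expect_equal(out[[2]], 0)
  expect_true(attr(out, "clipped"))
  expect_gt(out[[1]], 999)
})

test_that("a singular mixing matrix is reported by name", {
  pm <- purity_matrix(pct_minus2 = rep(0, 4),
                      pct_minus1 = c(0, 100, 0, 0),
                      pct_plus1 = rep(0, 4), pct_plus2 = rep(0, 4))
  expect_error(correct_isotope_impurities(c(1, 1, 1, 1), pm),
               "singular mixing matrix")
})

test_that("table-level correction handles all PSMs at once", {
  tab <- toy_psm_table()
  out <- correct_psm_table(tab, example_purity_matrix())
  expect_true("isotope_clipped" %in% names(out))
  one <- correct_isotope_impurities(
    as.numeric(tab[1, paste0("intensity_", 114:117)]),
    example_purity_matrix())
  expect_equal(as.numeric(out[1, paste0("intensity_", 114:117)]),
               as.numeric(one))
})

# --- median normalization -------------------------------------------------

test_that("already-equal channel medians are left unchanged", {
  tab <- toy_psm_table(i114 = c(1, 3), i115 = c(2, 2), i116 = c(3, 1),
                       i117 = c(2, 2))
  expect_equal(normalize_channel_intensities(tab), tab)
})

test_that("a doubled channel median is scaled back onto the grand median", {
  tab <- toy_psm_table(i114 = c(90, 110), i115 = c(180, 220),
                       i116 = c(95, 105), i117 = c(99, 101))
  out <- normalize_channel_intensities(tab)
  meds <- vapply(paste0("intensity_", 114:117),
                 function(cc) median(out[[cc]]), numeric(1))
  expect_equal(unname(diff(range(meds))), 0, tolerance = 1e-12)
  # channel 115 was scaled by grand_median / 200
  expect_equal(out$intensity_115, c(180, 220) * (100 / 200))
})

test_that("single-PSM channels are equalized exactly", {
  tab <- toy_psm_table(i114 = 10, i115 = 20, i116 = 40, i117 = 80)
  out <- normalize_channel_intensities(tab)
  vals <- as.numeric(out[1, paste0("intensity_", 114:117)])
  expect_equal(vals, rep(30, 4))  # grand median of {10,20,40,80} medians
})

test_that("normalization equalizes medians and preserves ranks per experiment", {
  set.seed(3)
  n <- 40
  tab <- toy_psm_table(i114 = rlnorm(n, 1), i115 = 3 * rlnorm(n, 1),
                       i116 = rlnorm(n, 2), i117 = 0.5 * rlnorm(n, 1),
                       experiment_id = rep(c("exp1", "exp2"), each = n / 2))
  out <- normalize_channel_intensities(tab)
  for (e in c("exp1", "exp2")) {
    rows <- out$experiment_id == e
    meds <- vapply(paste0("intensity_", 114:117),
                   function(cc) median(out[[cc]][rows]), numeric(1))
    expect_lt(diff(range(meds)) / meds[[1]], 1e-12)
    for (cc in paste0("intensity_", 114:117)) {
      expect_identical(order(out[[cc]][rows]), order(tab[[cc]][rows]))
    }
  }
})

test_that("an all-zero channel is reported with experiment and channel", {
  tab <- toy_psm_table(i115 = c(0, 0))
  expect_error(normalize_channel_intensities(tab),
               "experiment 'exp1', channel 115")
})
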