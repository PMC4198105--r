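# ripcquant

Quantification and regulation analysis for paired 4-plex iTRAQ plasma
proteomics, plus a synthetic PSM-level data generator that makes every
stage of the pipeline verifiable against known ground truth.

## The problem

Isobaric (iTRAQ 4-plex) labeling puts four samples into one LC-MS/MS run,
with per-sample signal carried by reporter ions at m/z 114–117. The design
this package targets compares plasma from six donors at baseline and after
remote ischemic preconditioning (RIPC): three experiments, each
multiplexing two donors × two conditions, with the labels swapped in
experiment 2 so that RIPC sits in channels 114/116. Plasma is unforgiving
for this question — after immunodepletion of the 14 most abundant
proteins, candidate regulations are small, donor variability is large, and
apparent fold changes at low abundance are dominated by technical noise.

The pipeline therefore asks two separate questions of every protein and
only trusts proteins that answer both:

- **Donor consistency** — a paired two-sided t-test of the per-donor log2
  ratios `r_d = log2(I_RIPC,d / I_baseline,d)` against 0 (df = n − 1).
- **Effect size against the background** — the combined log2 ratio is
  referred to an asymmetric normal fitted to all retained proteins'
  combined ratios, calibrated on the median m and the 15.9th/84.1th
  percentiles (σ_low = m − P15.9, σ_high = P84.1 − m); the one-sided tail
  probability on the observed side must fall below 1%.

Cross-classification gives the categories **A** (both passed), **B**
(t-test only), **C** (background only), **D** (neither). Upstream of the
tests: PSM validation at 1% decoy-estimated FDR, reporter isotope-impurity
correction by solving the 4×4 purity mixing system, per-experiment median
normalization, and ratio aggregation (PSM → peptide → protein → donor →
combined) with a Gaussian-KDE-mode estimator (Silverman bandwidth,
1000-point grid + golden-section refinement) and per-donor median
centering. Spectral-counting abundance indexes (validated PSMs / kDa) and
a ≥20%-change relevance flag complete the per-protein report.

## Worked example

Simulate the full six-donor design under null conditions (no regulated
proteins) and run the pipeline:

```r
library(ripcquant)

ds  <- generate_dataset(generator_config(seed = 1))
res <- run_quantify(ds$psms, ds$design,
                    protein_info = ds$truth$proteins[, c("protein_accession",
                                                         "molecular_weight_kda")])
res
#> iTRAQ quantification result
#>   identified proteins:        400
#>   quantified (>=2 peptides):  393
#>   retained after exclusions:  378
#>   categories A/B/C/D:         0 / 1 / 8 / 369
```

Reading the counts: all 400 simulated proteins are identified at 1% FDR;
393 carry at least two unique quantified peptides; 378 survive the
contaminant/depletion-target exclusion. On null data the t-test flags ~1%
of proteins (category B) and the one-sided background test ~1% per side
(category C); category A — the only claim the design would call a
regulation — stays empty, as it should when nothing is regulated.

```r
st <- res$stats
mean(st$fold_change >= 0.91 & st$fold_change <= 1.1)
#> [1] 0.9761905
res$background
#> Asymmetric-normal background model (n = 378)
#>   m = -0.0017, sigma_low = 0.0528, sigma_high = 0.0624
```

97.6% of this run's retained proteins sit within a fold change of
0.91–1.10 (98.4% averaged over ten seeds) — the stability the generator
is calibrated to reproduce (see the methods vignette,
`vignettes/itraq-quantification-methods.Rmd`).

The numbered scripts under `analysis/` run the same steps as a workflow:
`01_simulate.R` (dataset → `scratch/`), `02_quantify.R` (full pipeline,
summary → `results/`), `03_null_calibration.R` (ten-seed stability and
type-I rates → `results/null_calibration.tsv`), `04_spike_recovery.R`
(sensitivity to spiked two-fold changes →
`results/spike_recovery.tsv`).

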