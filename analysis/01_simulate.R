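#!/usr/bin/env Rscript
# Step 1: simulate the paired six-donor, three-experiment 4-plex iTRAQ
# plasma dataset under the default (null) study conditions: 400 proteins,
# per-donor log2 ratio spread 0.055, PSM noise 0.15 at median abundance,
# decoys, contaminants and depletion targets included.
#
# The PSM-level dataset is large, so it is written under scratch/ (a
# working area); downstream steps read it from there.

suppressPackageStartupMessages(library(ripcquant))

out_dir <- "scratch/simulation"
cfg <- generator_config(seed = 1L)
ds <- run_simulate(cfg, out_dir = out_dir, overwrite = TRUE)

cat(sprintf("simulated %d PSMs (%d decoys) for %d proteins -> %s\n",
            nrow(ds$psms), sum(ds$psms$is_decoy == 1),
            nrow(ds$truth$proteins), out_dir))
cat(sprintf("regulated proteins in truth: %d (null dataset)\n",
            sum(ds$truth$proteins$regulated)))
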