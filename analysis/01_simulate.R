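#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-wave cohort and write phenotypes,
# per-participant connectivity matrices and the manifest.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- run_pipeline(cfg, stages = "simulate")
tab <- res$simulate$table
cat(sprintf("cohort: %d baseline, %d at 6 months, %d at 12 months\n",
            sum(tab$wave == 1), sum(tab$wave == 2), sum(tab$wave == 3)))
cat(sprintf("wave-level missing fractions: %.1f%% / %.1f%%\n",
            100 * cohort_missing_fraction(tab, 2),
            100 * cohort_missing_fraction(tab, 3)))
cat("artifacts: results/pipeline/phenotypes.tsv, connectivity/, conn_manifest.tsv\n")
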