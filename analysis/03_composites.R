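#!/usr/bin/env Rscript
# Stage 3: reliability-weighted EF composites and median-split 12-month
# outcome labels (never imputed).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- run_pipeline(cfg, stages = "composites")
lab <- res$composites
cat(sprintf("labeled participants: motor %d (class-1 %.1f%%), EF %d (class-1 %.1f%%)\n",
            sum(!is.na(lab$motor_class)), 100 * mean(lab$motor_class, na.rm = TRUE),
            sum(!is.na(lab$ef_class)), 100 * mean(lab$ef_class, na.rm = TRUE)))
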