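#!/usr/bin/env Rscript
# Stage 5: grouped permutation importance with cross-fold concordance.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- suppressWarnings(run_pipeline(cfg, stages = c("cv", "importance")))
tab <- res$importance$table
tab <- tab[order(-tab$importance), ]
cat("top feature groups by mean accuracy drop (points):\n")
print(head(tab, 6), digits = 3)
cat(sprintf("cross-fold ranking concordance, Kendall's W = %.3f\n",
            res$importance$kendalls_w))
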