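#!/usr/bin/env Rscript
# Stage 2: connectivity vectors and the 12 graph-theory metrics per
# participant (baseline wave feeds the classifier).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- suppressWarnings(run_pipeline(cfg, stages = "features"))
g <- res$features$bundle$graph
cat(sprintf("feature bundles for %d participants; connectivity vector length %d\n",
            nrow(g), ncol(res$features$bundle$conn)))
cat("graph metric means:\n")
print(round(colMeans(g), 3))
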