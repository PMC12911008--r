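#!/usr/bin/env Rscript
# Stage 4: stratified 5-fold cross-validation of the multimodal model and
# its connectivity-only / behavioral-only ablations, for both outcomes.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- suppressWarnings(run_pipeline(cfg, stages = "cv"))
ov <- res$cv[res$cv$stratum == "overall", ]
agg <- aggregate(cbind(accuracy, auc) ~ outcome + variant, ov, mean)
cat("mean cross-validated performance (overall stratum):\n")
print(agg, digits = 3)
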