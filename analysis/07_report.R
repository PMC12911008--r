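#!/usr/bin/env Rscript
# Stage 7: assemble the run report from the stage artifacts.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- run_pipeline(cfg, stages = "report")
cat(paste(res$report, collapse = "\n"), "\n")
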