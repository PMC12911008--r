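#!/usr/bin/env Rscript
# Stage 6: growth slopes and subgroups, network change contrasts, and the
# spline-versus-linear age model comparison.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()
res <- suppressWarnings(run_pipeline(cfg, stages = "trajectories"))
gr <- res$trajectories$growth
cat(sprintf("growth classes: %s\n",
            paste(names(table(gr$growth_class)), table(gr$growth_class),
                  collapse = ", ", sep = "=")))
cc <- res$trajectories$contrasts
cat("within-network 12-month deltas:\n")
print(cc[cc$type == "within", c("block", "delta_mean", "t", "p_bh")], digits = 3)
cat(sprintf("spline vs linear: delta AIC = %.1f, preferred = %s\n",
            res$trajectories$spline$delta_aic, res$trajectories$spline$preferred))
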