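# Shared configuration for the numbered analysis drivers. Each driver runs
# one pipeline stage against this config and narrates what it finds; stage
# artifacts and provenance records land in results/pipeline.
library(devfuse)

analysis_config <- function() {
  # demonstration cohort: 220 children with a strong latent brain-behavior
  # coupling, so the stage outputs show the pipeline doing its job at a
  # desk-scale runtime; generator defaults elsewhere are untouched
  run_config(cohort = cohort_spec(n_baseline = 220, effect_size = 0.8,
                                  seed = 11L),
             profile = "desk", seed = 20260920L,
             out_dir = "results/pipeline")
}
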