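#!/usr/bin/env Rscript

# One-command end-to-end run of the whole screen analysis (equivalent to
# sourcing scripts 01-06 in order), via the package orchestrator. Set
# SCREEN_SEED to change the root seed; all stage seeds derive from it.

suppressPackageStartupMessages(library(morphoscreen))

seed <- as.integer(Sys.getenv("SCREEN_SEED", "1"))
rep <- run_pipeline(pipeline_config(seed = seed), output_dir = "results/run")
print(rep)
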