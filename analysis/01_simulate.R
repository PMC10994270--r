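#!/usr/bin/env Rscript

# Simulate the default nine-plate screen with known ground truth and write
# the image-level feature table, ground truth and library manifest under
# results/run/.
#
# The screen: 3 knock-out sub-clones x 3 concentrations (100/300/1000 nM),
# 330 compounds (one well each per plate), 24 wild-type vehicle + 16
# knock-out vehicle + 6 untreated knock-out wells per plate, 4 image fields
# per well, 1100 correlated morphological features. Ten compounds are planted
# as true reverters (rho >= 0.8).

suppressPackageStartupMessages(library(morphoscreen))

seed <- as.integer(Sys.getenv("SCREEN_SEED", "1"))
out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- screen_design()
print(design)

params <- sim_params(seed = seed)
scr <- simulate_screen(design, params)
cat(sprintf("simulated %d image-level records x %d features\n",
            nrow(scr$table), length(setdiff(names(scr$table),
                                            names(scr$table)[1:7]))))
cat(sprintf("planted reverters: %s\n",
            paste(scr$truth$compound_id[scr$truth$true_hit], collapse = ", ")))

write_feature_table(scr$table, file.path(out, "feature_table.csv"))
write_ground_truth(scr$truth, file.path(out, "ground_truth.json"))
write_manifest(default_library_manifest(), file.path(out, "manifest.csv"))
cat("wrote feature_table.csv, ground_truth.json, manifest.csv to ", out, "\n")
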