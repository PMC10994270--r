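#!/usr/bin/env Rscript

# Feature QC: aggregate image fields to well-level medians, robust-z
# normalise each plate against its knock-out vehicle wells, remove degenerate
# (singular) and redundant (|r| >= 0.95) variables, and test every retained
# feature across the control classes by one-way ANOVA with BH correction.

suppressPackageStartupMessages(library(morphoscreen))

out <- "results/run"
tab <- read_feature_table(file.path(out, "feature_table.csv"))

qc <- run_feature_qc(tab)
print(qc$report)
cat(sprintf("features: %d in -> %d retained (%d degenerate, %d redundant)\n",
            length(setdiff(names(tab), names(tab)[1:7])),
            length(qc$retained),
            length(qc$dropped$degenerate), length(qc$dropped$redundant)))

data.table::fwrite(qc$wells, file.path(out, "wells_qc.csv"))
writeLines(qc$dropped$degenerate, file.path(out, "dropped_degenerate.txt"))
writeLines(qc$dropped$redundant, file.path(out, "dropped_redundant.txt"))
jsonlite::write_json(
  list(n_tested = qc$report$n_tested, n_significant = qc$report$n_significant,
       alpha = qc$report$alpha, significant = qc$report$significant,
       untestable = qc$report$untestable),
  file.path(out, "qc_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(qc, file.path("scratch", "qc.rds"))  # intermediate for later steps
cat("wrote wells_qc.csv, qc_report.json\n")
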