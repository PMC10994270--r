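#!/usr/bin/env Rscript

# Control-anchored classification and compound scoring: project image-level
# records through the QC and reduction fitted at well level, train the
# three-layer neural network on the vehicle-treated control images (80/20
# well-stratified split, two-fold CV over the size x decay grid), report the
# confusion matrix on held-out controls, then score every compound-treated
# well's likelihood of classifying as wild-type.

suppressPackageStartupMessages(library(morphoscreen))

out <- "results/run"
tab <- read_feature_table(file.path(out, "feature_table.csv"))
qc <- readRDS("scratch/qc.rds")
red <- readRDS("scratch/reduction.rds")

img <- apply_feature_qc(qc, tab)
img_scores <- predict(red, img)

spec <- classifier_spec(algorithm = "nn", seed = 303)
controls <- img_scores[img_scores$treatment == "VEHICLE", ]
split <- split_controls(controls, spec)
model <- train_classifier(split$train, spec)
report <- evaluate_classifier(model, split$test)
print(report)
cat(sprintf("chosen nn: size %s, decay %s; mean WT-likelihood: WT %.4f / KO %.4f\n",
            report$chosen$size, report$chosen$decay,
            report$mean_focus_prob$WT, report$mean_focus_prob$KO))

treated <- img_scores[grepl("^CPD", img_scores$treatment), ]
scores <- score_treated(model, treated)

jsonlite::write_json(unclass(report), file.path(out, "classifier_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
data.table::fwrite(scores, file.path(out, "compound_scores.csv"))
cat("wrote classifier_report.json, compound_scores.csv\n")
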