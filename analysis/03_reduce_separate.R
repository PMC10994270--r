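#!/usr/bin/env Rscript

# Dimension reduction and control separation: correlation-matrix PCA of the
# QC'd well profiles, 50 components (fixed rule), oblimin rotation, ten Berge
# factor scores; then the Bray-Curtis between/within separation of the
# vehicle-treated wild-type vs knock-out wells with a 999-permutation test,
# and the min-max-scaled hierarchical clustering view of the control wells.

suppressPackageStartupMessages(library(morphoscreen))

out <- "results/run"
qc <- readRDS("scratch/qc.rds")

red <- reduce_profiles(qc$wells, rule = "fixed", k = 50)
print(red)
cat(sprintf("eigenvalues (head): %s\n",
            paste(round(head(red$eigenvalues, 6), 2), collapse = ", ")))

ctrl <- red$scores$treatment == "VEHICLE"
profiles <- as.matrix(red$scores[ctrl, grep("^PC", names(red$scores))])
sep <- permutation_test(profiles, red$scores$genotype[ctrl],
                        metric = "bray_curtis", n_perm = 999, seed = 202)
print(sep)

cv <- cluster_view(profiles)
data.table::fwrite(red$scores, file.path(out, "component_scores.csv"))
data.table::fwrite(data.frame(leaf_order = cv$order),
                   file.path(out, "cluster_leaf_order.csv"))
data.table::fwrite(as.data.frame(cv$scaled),
                   file.path(out, "cluster_scaled_matrix.csv"))
jsonlite::write_json(sep[c("metric", "D", "p", "n_perm", "seed",
                           "group_sizes")],
                     file.path(out, "separation.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
saveRDS(red, "scratch/reduction.rds")
cat("wrote component_scores.csv, separation.json, cluster views\n")
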