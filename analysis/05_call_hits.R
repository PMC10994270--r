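#!/usr/bin/env Rscript

# Hit calling: a compound is a hit when every knock-out sub-clone scores
# > 0.505 wild-type similarity at one or more concentrations. Salt forms of
# the same parent drug are collapsed, hits grouped by mechanism class, and
# the calls compared against the simulation ground truth.

suppressPackageStartupMessages(library(morphoscreen))

out <- "results/run"
scores <- as.data.frame(data.table::fread(file.path(out, "compound_scores.csv")))
manifest <- read_manifest(file.path(out, "manifest.csv"))
truth <- read_ground_truth(file.path(out, "ground_truth.json"))

hits <- call_hits(scores, tau = 0.505, mode = "any_conc",
                  subclones = sort(unique(scores$subclone_id)))
collapsed <- collapse_salt_forms(hits, manifest)
mech <- summarize_by_mechanism(collapsed$drugs)
rec <- hit_recovery(hits, truth)

cat(sprintf("%d compound hits -> %d unique drugs\n",
            collapsed$n_compound_hits, collapsed$n_drug_hits))
print(mech)
cat(sprintf("ground truth: %d/%d true reverters recovered, %d false positives\n",
            rec$recovered, rec$n_true_reverters, rec$false_positives))

data.table::fwrite(as.data.frame(hits), file.path(out, "hit_table.csv"))
data.table::fwrite(collapsed$drugs, file.path(out, "hit_drugs.csv"))
data.table::fwrite(mech, file.path(out, "mechanism_summary.csv"))
jsonlite::write_json(rec, file.path(out, "hit_recovery.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote hit_table.csv, hit_drugs.csv, mechanism_summary.csv, hit_recovery.json\n")
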