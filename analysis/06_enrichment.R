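#!/usr/bin/env Rscript

# Gene-set over-representation of the hit drugs' annotated targets:
# hypergeometric upper-tail test against the expressed-gene background with
# BH correction and log10(observed/expected) enrichment strength. Uses the
# packaged synthetic gene-set, expressed-gene and drug-target fixtures.

suppressPackageStartupMessages(library(morphoscreen))

out <- "results/run"
drugs <- as.data.frame(data.table::fread(file.path(out, "hit_drugs.csv")))

gmt <- system.file("extdata", "synthetic_gene_sets.gmt",
                   package = "morphoscreen")
expressed <- readLines(system.file("extdata", "synthetic_expressed_genes.txt",
                                   package = "morphoscreen"))
targets <- read_drug_targets(system.file(
  "extdata", "synthetic_drug_targets.tsv", package = "morphoscreen"))

collection <- read_gmt(gmt)
query <- filter_by_expression(
  unique(unlist(targets[drugs$parent_drug], use.names = FALSE)), expressed)
cat(sprintf("query: %d expressed target genes of %d hit drugs; background %d genes\n",
            length(query), nrow(drugs), length(unique(toupper(expressed)))))

rows <- hypergeometric_enrichment(query, collection, expressed)
print(head(rows, 10))
cat(sprintf("%d/%d sets at BH q < 0.05\n", sum(rows$q < 0.05), nrow(rows)))
write_enrichment(rows, file.path(out, "enrichment.tsv"))
cat("wrote enrichment.tsv\n")
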