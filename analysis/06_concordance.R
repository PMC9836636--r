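#!/usr/bin/env Rscript
# Compare the delimitation methods: pairwise match ratio and taxonomic index
# of congruence (C_tax), per-method resolving power (R_tax) on the shared
# NJ guide tree, and the consensus count of taxa every method recovers.

library(motulib)

lib <- read_library("results/sim/library_passing.fasta",
                    "results/sim/library_passing.tsv")
dm <- build_matrix(lib)
parts_tab <- read.delim("results/partitions.tsv")
parts <- lapply(split(parts_tab, parts_tab$method), function(df)
  motu_partition(df$method[1], setNames(df$motu_label, df$specimen_id)))

guide <- phangorn::midpoint(newick_read(file = "results/nj.nwk"))
tab <- concordance_table(parts, guide)
print(tab)
write_concordance_tsv(tab, "results/concordance.tsv")

taxon <- setNames(ifelse(is.na(lib$records$species),
                         paste(lib$records$genus, "sp."),
                         lib$records$species),
                  lib$records$specimen_id)
cons <- consensus_count(unname(parts), taxon)
cat("\ntaxa recovered identically by all", length(parts), "methods:",
    cons$count, "of", length(unique(taxon)), "\n")
writeLines(cons$taxa, "results/consensus_taxa.txt")
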