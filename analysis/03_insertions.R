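#!/usr/bin/env Rscript
# Call TE insertion polymorphisms from the simulated genomic reads:
# CIGAR walking, clustering with the "more than 4 supporting reads" rule,
# TE family and truncation typing, and the 5-20 bp TSD filter.

suppressPackageStartupMessages(library(eccsv))
state <- readRDS("results/sim/state.rds")

paf <- read_paf("results/sim/truth.paf")
ev <- walk_cigar_paf(paf, min_len = 50L, reads = state$reads)
message(nrow(ev), " breakpoint evidence records (INS ",
        sum(ev$kind == "INS"), ", DEL ", sum(ev$kind == "DEL"), ")")

clusters <- cluster_breakpoints(ev, window = 10L, min_support = 4L)
message(nrow(clusters), " clusters pass support > 4")
write_clusters_bed(clusters, "results/breakpoint_clusters.bed")

calls <- call_insertions(clusters, list(state$te), state$genome,
                         annotation = NULL)
kept <- tsd_filter(calls, min = 5L, max = 20L)
message(nrow(kept), " insertion call(s) with a 5-20 bp TSD:")
print(kept[, c("chrom", "pos", "family", "tsd_seq", "tsd_len",
               "truncated", "support")])

write.table(calls, "results/insertions_all.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(kept, "results/insertions_tsd_filtered.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
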