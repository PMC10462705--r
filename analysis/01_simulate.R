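#!/usr/bin/env Rscript
# Build the synthetic study system: an LTR-retrotransposon model, a
# reference chromosome, implanted variants (a TE insertion with a 9-bp
# TSD, a 13.3 kb deletion, a 55,220 bp tandem duplication), genomic long
# reads and ground-truth PAF alignments. Everything downstream (02-05)
# reruns the callers on these files.

suppressPackageStartupMessages(library(eccsv))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

te <- synthetic_te_model(seed = 7)
message("TE model: ", nchar(te$sequence), " bp, LTRs ",
        diff(domain_span(te, "LTR5")), " bp, identity ", te$ltr_identity)

genome <- stats::setNames(random_dna(200000, seed = 11), "chr1")
specs <- rbind(
  variant_spec("INSERTION", "chr1", 40000L, payload = te$sequence,
               tsd_len = 9L),
  variant_spec("DELETION", "chr1", 90000L, length = 13300L),
  variant_spec("TANDEM_DUP", "chr1", 130000L, length = 55220L))
imp <- implant_variants(genome, specs)
message("mutated chromosome: ", nchar(imp$genome[["chr1"]]), " bp (",
        nchar(genome[["chr1"]]), " bp reference)")

cfg <- read_sim_config(0.03, 0.015, 0.015, seed = 13)
mp <- imp$truth$variants$mut_pos
reads <- c(
  simulate_spanning_reads(imp$genome[["chr1"]], c(mp[1], mp[1] + 5309L), 8L,
                          cfg, read_len = 12000L, id_prefix = "ins"),
  simulate_spanning_reads(imp$genome[["chr1"]], c(mp[2], mp[2]), 15L,
                          cfg, read_len = 20000L, id_prefix = "del"),
  simulate_spanning_reads(imp$genome[["chr1"]], c(mp[3], mp[3]), 20L,
                          error_free_config(17), read_len = 60000L,
                          id_prefix = "dupj"))
paf <- emit_truth_alignments(reads, imp$truth)
validate_paf(paf)
message(length(reads), " reads, ", nrow(paf), " truth alignment records")

write_genome_fasta(genome, "results/sim/reference.fa")
write_genome_fasta(imp$genome, "results/sim/mutated.fa")
write_reads_fastq(reads, "results/sim/reads.fq")
write_paf(paf, "results/sim/truth.paf")
write_truth_tsv(imp$truth, "results/sim/truth_variants.tsv")
saveRDS(list(te = te, genome = genome, imp = imp, reads = reads),
        "results/sim/state.rds")
message("wrote results/sim/{reference.fa,mutated.fa,reads.fq,truth.paf,truth_variants.tsv}")
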