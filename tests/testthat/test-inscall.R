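test_that("CIGAR walking emits events at the correct reference cursor", {
  rec <- mk_paf("r1", 100L, 190L, cigar = "50=10I40=", qlen = 100L)
  rec$qend <- 100L; rec$alnlen <- 100L; rec$nmatch <- 90L
  ev <- walk_cigar(rec, min_len = 10L)
  expect_equal(ev$kind, "INS")
  expect_equal(ev$ref_pos, 150L)
  expect_equal(ev$length, 10L)

  rec2 <- mk_paf("r2", 0L, 75L, cigar = "30=15D30=", qlen = 60L)
  rec2$qend <- 60L; rec2$alnlen <- 75L; rec2$nmatch <- 60L
  ev2 <- walk_cigar(rec2, min_len = 10L)
  expect_equal(ev2$kind, "DEL")
  expect_equal(ev2$ref_pos, 30L)
  expect_equal(ev2$length, 15L)

  rec3 <- mk_paf("r3", 0L, 100L, cigar = "100=")
  expect_equal(nrow(walk_cigar(rec3, min_len = 10L)), 0L)
  # events below min_len are ignored
  expect_equal(nrow(walk_cigar(rec, min_len = 11L)), 0L)
})

test_that("CIGAR walking agrees with the truth-bookkeeping oracle", {
  g <- fixture_genome(80000, seed = 41)
  specs <- rbind(
    variant_spec("INSERTION", "chr1", 20000L,
                 payload = random_dna(3000, seed = 42), tsd_len = 8L),
    variant_spec("DELETION", "chr1", 40000L, length = 700L),
    variant_spec("INSERTION", "chr1", 60000L,
                 payload = random_dna(150, seed = 43), tsd_len = 5L))
  imp <- implant_variants(g, specs)
  reads <- simulate_spanning_reads(imp$genome[["chr1"]], c(15000L, 65000L),
                                   10L, error_free_config(44),
                                   read_len = 60000L, flank = 500L)
  paf <- emit_truth_alignments(reads, imp$truth)
  got <- walk_cigar_paf(paf, min_len = 50L)
  want <- do.call(rbind, lapply(reads, breakpoint_oracle,
                                truth = imp$truth, min_len = 50L))
  o <- function(d) d[order(d$read_id, d$ref_pos),
                     c("read_id", "kind", "ref_pos", "length")]
  got <- o(got); want <- o(want)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("breakpoint clustering is single-linkage with strict support", {
  ev <- function(ids, pos)
    data.frame(read_id = ids, kind = "INS", chrom = "chr1", ref_pos = pos,
               length = 5000L, inserted_seq = NA_character_,
               stringsAsFactors = FALSE)
  # positions {1000,1004,1009,1050}, window 10 -> groups of 3 and 1
  e <- ev(paste0("r", 1:4), c(1000L, 1004L, 1009L, 1050L))
  cl0 <- cluster_breakpoints(e, window = 10L, min_support = 0L)
  expect_equal(nrow(cl0), 2L)
  expect_equal(sort(cl0$support), c(1L, 3L))
  # 5 identical positions retained, 4 rejected (strictly more than 4)
  expect_equal(nrow(cluster_breakpoints(ev(paste0("r", 1:5), rep(2000L, 5)))), 1L)
  expect_equal(nrow(cluster_breakpoints(ev(paste0("r", 1:4), rep(2000L, 4)))), 0L)
  # duplicated PAF records of one read do not inflate support
  expect_equal(nrow(cluster_breakpoints(ev(rep("r1", 6), rep(2000L, 6)))), 0L)
})

test_that("TSD detection recovers the implanted duplication from sequence evidence", {
  g <- fixture_genome(30000, seed = 45)
  payload <- random_dna(2000, seed = 46)
  # guard base so the constructed 9-bp TSD cannot extend by coincidence
  gs <- g[["chr1"]]
  substr(gs, 12000L - 9L, 12000L - 9L) <-
    setdiff(c("A", "C", "G", "T"), substr(payload, 2000L, 2000L))[1]
  g <- stats::setNames(gs, "chr1")
  imp <- implant_variants(g, variant_spec("INSERTION", "chr1", 12000L,
                                          payload = payload, tsd_len = 9L))
  reads <- simulate_spanning_reads(imp$genome[["chr1"]], c(12000L, 14009L), 6L,
                                   error_free_config(47), read_len = 8000L)
  paf <- emit_truth_alignments(reads, imp$truth)
  ev <- walk_cigar_paf(paf, min_len = 50L, reads = reads)
  cl <- cluster_breakpoints(ev)
  tsd <- detect_tsd(cl[1, ], attr(cl, "members")[[1]], g[["chr1"]])
  expect_equal(tsd$tsd_len, 9L)
  expect_equal(tsd$tsd_seq, substr(g[["chr1"]], 12000L - 8L, 12000L))
  expect_false(tsd$ambiguous)
})

test_that("TSD detection reconciles sequence and split-read evidence", {
  g <- fixture_genome(30000, seed = 48)
  # construct an insertion whose flanking alignments clip at the site
  cluster <- data.frame(cluster_id = 1L, chrom = "chr1", kind = "INS",
                        start = 12000L, end = 12001L, pos = 12000L,
                        length = 2000L, support = 5L)
  body <- random_dna(1994, seed = 49)
  guard <- setdiff(c("A", "C", "G", "T"), substr(g[["chr1"]], 11995L, 11995L))[1]
  ins <- paste0(body, guard,
                substr(g[["chr1"]], 11996L, 12000L)) # exactly 5-bp TSD copy
  members <- data.frame(read_id = paste0("r", 1:5), kind = "INS",
                        chrom = "chr1", ref_pos = 12000L, length = 2000L,
                        inserted_seq = ins, stringsAsFactors = FALSE)
  flanks <- rbind(mk_paf(paste0("u", 1:3), 9000L, 12000L),
                  mk_paf(paste0("d", 1:3), 11995L, 15000L))
  tsd <- detect_tsd(cluster, members, g[["chr1"]], flank_alignments = flanks)
  expect_equal(tsd$tsd_len, 5L)
  expect_equal(tsd$method, "both")
  expect_false(tsd$ambiguous)
  # zero-length construction is undetectable from sequence or flanks
  none <- detect_tsd(cluster,
                     transform(members, inserted_seq = NA_character_),
                     g[["chr1"]])
  expect_true(is.na(none$tsd_len))
})

test_that("TSD filter keeps the inclusive 5-20 bp window", {
  calls <- data.frame(chrom = "chr1", pos = 1:5 * 1000L,
                      tsd_len = c(3L, 5L, 12L, 20L, 25L))
  kept <- tsd_filter(calls)
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$tsd_len, c(5L, 12L, 20L))
  rem <- attr(kept, "removed")
  expect_setequal(rem$reason, c("TSD too short", "TSD too long"))
  # boundary: 4 and 21 removed
  expect_equal(nrow(tsd_filter(data.frame(chrom = "chr1", pos = 1L,
                                          tsd_len = 4L))), 0L)
  expect_equal(nrow(tsd_filter(data.frame(chrom = "chr1", pos = 1L,
                                          tsd_len = 21L))), 0L)
})

test_that("insertion typing assigns family, truncation and target annotation", {
  te <- fixture_te()
  g <- fixture_genome(80000, seed = 51)
  trunc_payload <- make_circle_template(te, "NO_IN_RT")$sequence
  # guard bases so the constructed TSDs cannot extend by coincidence
  gs <- g[["chr1"]]
  gb <- function(payload) setdiff(c("A", "C", "G", "T"),
                                  substr(payload, nchar(payload), nchar(payload)))[1]
  substr(gs, 20000L - 5L, 20000L - 5L) <- gb(te$sequence)
  substr(gs, 50000L - 9L, 50000L - 9L) <- gb(trunc_payload)
  g <- stats::setNames(gs, "chr1")
  specs <- rbind(
    variant_spec("INSERTION", "chr1", 20000L, payload = te$sequence,
                 tsd_len = 5L),
    variant_spec("INSERTION", "chr1", 50000L, payload = trunc_payload,
                 tsd_len = 9L))
  imp <- implant_variants(g, specs)
  mut <- imp$genome[["chr1"]]
  reads <- c(
    simulate_spanning_reads(mut, c(20000L, 20000L + nchar(te$sequence) + 5L),
                            6L, error_free_config(52), read_len = 9000L,
                            id_prefix = "a"),
    simulate_spanning_reads(mut, c(imp$truth$variants$mut_pos[2],
                                   imp$truth$variants$mut_pos[2] +
                                     nchar(trunc_payload) + 9L),
                            6L, error_free_config(53), read_len = 7000L,
                            id_prefix = "b"))
  paf <- emit_truth_alignments(reads, imp$truth)
  ev <- walk_cigar_paf(paf, min_len = 50L, reads = reads)
  cl <- cluster_breakpoints(ev)
  gff <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(19001, 19001, 48001), c(22000, 21000, 49000)),
    type = c("gene", "exon", "gene"))
  calls <- suppressWarnings(call_insertions(cl, list(te), g, annotation = gff))
  calls <- calls[order(calls$pos), ]
  expect_equal(calls$family, c("synthTE", "synthTE"))
  expect_false(calls$truncated[1])
  expect_true(calls$truncated[2])
  expect_setequal(strsplit(calls$missing_domains[2], ",")[[1]], c("IN", "RT"))
  expect_equal(calls$target_annotation[1], "exon")
  expect_match(calls$target_annotation[2], "intergenic")
  expect_equal(calls$tsd_len, c(5L, 9L))
  filtered <- tsd_filter(calls)
  expect_equal(nrow(filtered), 2L)
})

test_that("end-to-end: implanted TSD insertions are recalled, none on clean genome", {
  te <- fixture_te()
  g <- fixture_genome(90000, seed = 61)
  positions <- c(15000L, 40000L, 70000L)
  tsds <- c(5L, 12L, 20L)
  gs <- g[["chr1"]]
  gb <- setdiff(c("A", "C", "G", "T"),
                substr(te$sequence, nchar(te$sequence), nchar(te$sequence)))[1]
  for (i in seq_along(positions))
    substr(gs, positions[i] - tsds[i], positions[i] - tsds[i]) <- gb
  g <- stats::setNames(gs, "chr1")
  specs <- do.call(rbind, lapply(seq_along(positions), function(i)
    variant_spec("INSERTION", "chr1", positions[i], payload = te$sequence,
                 tsd_len = tsds[i])))
  imp <- implant_variants(g, specs)
  cfg <- read_sim_config(0.02, 0.01, 0.01, seed = 62)
  reads <- unlist(lapply(seq_along(positions), function(i)
    simulate_spanning_reads(imp$genome[["chr1"]],
                            c(imp$truth$variants$mut_pos[i],
                              imp$truth$variants$mut_pos[i] + 5310L),
                            6L, cfg, read_len = 9000L,
                            id_prefix = paste0("L", i))),
    recursive = FALSE)
  paf <- emit_truth_alignments(reads, imp$truth)
  ev <- walk_cigar_paf(paf, min_len = 50L, reads = reads)
  cl <- cluster_breakpoints(ev)
  calls <- suppressWarnings(call_insertions(cl, list(te), g))
  kept <- tsd_filter(calls)
  expect_equal(nrow(kept), 3L)
  expect_true(all(abs(sort(kept$pos) - positions) <= 10L))
  expect_equal(sort(kept$tsd_len), sort(tsds))
  # variant-free genome: no calls at all
  imp0 <- implant_variants(g, variant_spec("DELETION", "chr1", 89000L,
                                           length = 10L)[0, ])
  reads0 <- simulate_spanning_reads(imp0$genome[["chr1"]], c(30000L, 31000L),
                                    10L, cfg, read_len = 9000L)
  paf0 <- emit_truth_alignments(reads0, imp0$truth)
  ev0 <- walk_cigar_paf(paf0, min_len = 50L, reads = reads0)
  expect_equal(nrow(cluster_breakpoints(ev0)), 0L)
})
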