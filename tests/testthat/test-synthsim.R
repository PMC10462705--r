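test_that("insertion implanting adds payload plus TSD and flanks it with identical copies", {
  g <- fixture_genome(20000, seed = 3)
  payload <- random_dna(5000, seed = 4)
  p <- 8000L
  imp <- implant_variants(g, variant_spec("INSERTION", "chr1", p,
                                          payload = payload, tsd_len = 5L))
  mut <- imp$genome[["chr1"]]
  expect_equal(nchar(mut), 20000L + 5000L + 5L)
  mp <- imp$truth$variants$mut_pos[1]
  pre <- substr(mut, mp - 4L, mp)
  post <- substr(mut, mp + 5001L, mp + 5005L)
  expect_equal(pre, post)
  expect_equal(pre, substr(g[["chr1"]], p - 4L, p))
})

test_that("tandem duplication doubles its interval head-to-tail", {
  g <- fixture_genome(20000, seed = 5)
  imp <- implant_variants(g, variant_spec("TANDEM_DUP", "chr1", 6000L,
                                          length = 2500L))
  mut <- imp$genome[["chr1"]]
  expect_equal(nchar(mut), 22500L)
  expect_equal(substr(mut, 6001L, 8500L), substr(mut, 8501L, 11000L))
})

test_that("deletion removes its interval and overlapping specs error", {
  g <- fixture_genome(30000, seed = 6)
  imp <- implant_variants(g, variant_spec("DELETION", "chr1", 9000L,
                                          length = 13300L))
  expect_equal(nchar(imp$genome[["chr1"]]), 30000L - 13300L)
  bad <- rbind(variant_spec("DELETION", "chr1", 1000L, length = 500L),
               variant_spec("TANDEM_DUP", "chr1", 1400L, length = 1000L))
  expect_error(implant_variants(g, bad), "overlap")
})

test_that("TSD construction invariant holds across random insertion configs", {
  for (seed in 1:5) {
    set.seed(seed * 100)
    g <- stats::setNames(random_dna(15000), "chr1")
    tsd <- sample(0:20, 1)
    p <- sample(3000:12000, 1)
    payload <- random_dna(sample(200:3000, 1))
    imp <- implant_variants(g, variant_spec("INSERTION", "chr1", p,
                                            payload = payload, tsd_len = tsd))
    mut <- imp$genome[["chr1"]]
    mp <- imp$truth$variants$mut_pos[1]
    lp <- nchar(payload)
    if (tsd > 0) {
      expect_equal(substr(mut, mp - tsd + 1L, mp),
                   substr(mut, mp + lp + 1L, mp + lp + tsd))
    }
    expect_equal(nchar(mut), 15000L + lp + tsd)
  }
})

test_that("circle templates have class-consistent lengths and segments", {
  te <- fixture_te()
  n <- nchar(te$sequence)
  expect_equal(make_circle_template(te, "FULL_2LTR")$total_len, n)
  expect_equal(make_circle_template(te, "FULL_1LTR")$total_len,
               n - diff(domain_span(te, "LTR5")))
  no_inrt <- make_circle_template(te, "NO_IN_RT")
  expect_equal(no_inrt$total_len,
               n - diff(domain_span(te, "IN")) - diff(domain_span(te, "RT")))
  g <- fixture_genome()
  chim <- make_circle_template(te, "CHIMERIC",
    chimera_partner = list(chrom = "chr1", start = 30000L, end = 30708L),
    genome = g, te_frag_len = 701L)
  expect_equal(chim$total_len, 1409L)
  expect_equal(chim$segments$length, c(701L, 708L))
  expect_error(make_circle_template(te, "CHIMERIC"), "partner")
})

test_that("RCA reads roll the circle with the expected copy count", {
  te <- fixture_te()
  g <- fixture_genome()
  chim <- make_circle_template(te, "CHIMERIC",
    chimera_partner = list(chrom = "chr1", start = 30000L, end = 30708L),
    genome = g, te_frag_len = 701L)
  r <- simulate_rca_read(chim, 10000L, start_phase = 0L,
                         config = error_free_config(1))
  expect_equal(nchar(r$seq), 10000L)
  expect_equal(r$copies, 7L) # 10000 = 7 * 1409 + 137
  expect_equal(substr(r$seq, 1L, 1409L), chim$sequence)
  expect_false(r$sub_monomer)
  sub <- simulate_rca_read(chim, 900L, start_phase = 0L,
                           config = error_free_config(1))
  expect_true(sub$sub_monomer)
  expect_equal(sub$copies, 0L)
})

test_that("spanning reads cover the locus with flanks and seeds reproduce them", {
  g <- fixture_genome(40000, seed = 9)[[1]]
  cfg <- read_sim_config(seed = 77)
  reads <- simulate_spanning_reads(g, c(20000L, 21000L), 15L, cfg,
                                   read_len = 8000L)
  expect_length(reads, 15L)
  for (r in reads) {
    expect_lte(r$mut_start, 19000L)
    expect_gte(r$mut_end, 22000L)
  }
  again <- simulate_spanning_reads(g, c(20000L, 21000L), 15L, cfg,
                                   read_len = 8000L)
  expect_identical(reads, again)
  expect_length(simulate_spanning_reads(g, c(20000L, 21000L), 0L, cfg), 0L)
  expect_error(simulate_spanning_reads(g, c(39000L, 41000L), 3L, cfg),
               "outside")
})

test_that("truth alignments satisfy CIGAR length conservation at all error rates", {
  g <- fixture_genome(60000, seed = 13)
  specs <- rbind(
    variant_spec("INSERTION", "chr1", 15000L,
                 payload = random_dna(2000, seed = 14), tsd_len = 7L),
    variant_spec("DELETION", "chr1", 30000L, length = 400L),
    variant_spec("TANDEM_DUP", "chr1", 40000L, length = 5000L))
  imp <- implant_variants(g, specs)
  for (cfg in list(error_free_config(3),
                   read_sim_config(0.05, 0.02, 0.02, seed = 3))) {
    reads <- simulate_spanning_reads(imp$genome[["chr1"]], c(10000L, 50000L),
                                     8L, cfg, read_len = 48000L, flank = 500L)
    paf <- emit_truth_alignments(reads, imp$truth)
    expect_true(validate_paf(paf))
    expect_true(all(paf$strand == "+"))
    expect_true(all(paf$tend <= imp$truth$ref_len[["chr1"]]))
  }
})

test_that("a read inside an unmutated region aligns as one full-length match", {
  g <- fixture_genome(30000, seed = 17)
  imp <- implant_variants(g, variant_spec("DELETION", "chr1", 25000L,
                                          length = 100L))
  reads <- simulate_spanning_reads(imp$genome[["chr1"]], c(5000L, 6000L), 1L,
                                   error_free_config(4), read_len = 3000L)
  paf <- emit_truth_alignments(reads, imp$truth)
  expect_equal(nrow(paf), 1L)
  expect_equal(paf$cigar, "3000=")
  expect_equal(paf$nmatch, 3000L)
})

test_that("a read spanning a deletion reports the D op at the right offset", {
  # deletion of 15 bp at reference 10030; read starts at mutated 10000
  g <- fixture_genome(20000, seed = 18)
  imp <- implant_variants(g, variant_spec("DELETION", "chr1", 10030L,
                                          length = 15L))
  read <- structure(list(id = "r", seq = substr(imp$genome[["chr1"]],
                                                10001L, 11000L),
                         chrom = "chr1", mut_start = 10000L, mut_end = 11000L,
                         ops = data.frame(len = 1000L, op = "=")),
                    class = "sim_read")
  paf <- emit_truth_alignments(list(read), imp$truth)
  expect_equal(paf$cigar, "30=15D970=")
  expect_equal(paf$tstart, 10000L)
})

test_that("a read spanning a duplication junction yields two overlapping records", {
  g <- fixture_genome(50000, seed = 19)
  dup_len <- 6000L
  imp <- implant_variants(g, variant_spec("TANDEM_DUP", "chr1", 20000L,
                                          length = dup_len))
  j <- imp$truth$variants$mut_pos[1]
  reads <- simulate_spanning_reads(imp$genome[["chr1"]], c(j, j), 3L,
                                   error_free_config(5), read_len = 8000L)
  paf <- emit_truth_alignments(reads, imp$truth)
  for (qn in unique(paf$qname)) {
    rec <- paf[paf$qname == qn, ]
    expect_equal(nrow(rec), 2L)
    rec <- rec[order(rec$qstart), ]
    ov <- min(rec$tend) - max(rec$tstart)
    expect_gt(ov, 0L)
    expect_equal(rec$tend[1], 26000L)  # first segment ends at dup end
    expect_equal(rec$tstart[2], 20000L) # second restarts at dup start
    expect_equal(sum(rec$tp == "P"), 1L)
  }
})

test_that("identical seeds give byte-identical FASTA/FASTQ/PAF output", {
  build <- function() {
    g <- stats::setNames(random_dna(20000, seed = 23), "chr1")
    imp <- implant_variants(g, variant_spec("INSERTION", "chr1", 9000L,
                                            payload = random_dna(800, seed = 24),
                                            tsd_len = 6L))
    reads <- simulate_spanning_reads(imp$genome[["chr1"]], c(9000L, 9806L), 5L,
                                     read_sim_config(seed = 25),
                                     read_len = 6000L)
    paf <- emit_truth_alignments(reads, imp$truth)
    fa <- tempfile(fileext = ".fa"); fq <- tempfile(fileext = ".fq")
    pf <- tempfile(fileext = ".paf")
    write_genome_fasta(imp$genome, fa)
    write_reads_fastq(reads, fq)
    write_paf(paf, pf)
    out <- list(fa = readLines(fa), fq = readLines(fq), paf = readLines(pf))
    unlink(c(fa, fq, pf))
    out
  }
  expect_identical(build(), build())
})
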