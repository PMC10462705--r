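# Shared fixtures and independent oracles, built in code at test time.

fixture_te <- function() synthetic_te_model(seed = 7)

fixture_genome <- function(n = 50000L, seed = 21L, chrom = "chr1") {
  stats::setNames(random_dna(n, seed = seed), chrom)
}

# Hand-built PAF rows for interval-level tests.
mk_paf <- function(qname, tstart, tend, qstart = 0L, qlen = NULL,
                   tname = "chr1", tlen = 100000L, nmatch = NULL,
                   cigar = NULL, strand = "+", tp = "P") {
  span <- tend - tstart
  if (is.null(qlen)) qlen <- qstart + span
  if (is.null(nmatch)) nmatch <- span
  if (is.null(cigar)) cigar <- paste0(span, "=")
  data.frame(qname = qname, qlen = qlen, qstart = qstart,
             qend = qstart + span, strand = strand, tname = tname,
             tlen = tlen, tstart = tstart, tend = tend, nmatch = nmatch,
             alnlen = span, mapq = 60L, cigar = cigar, tp = tp,
             stringsAsFactors = FALSE)
}

# Brute-force period oracle: best Hamming-similarity shift.
period_oracle <- function(seq, min_p = 200L) {
  x <- utf8ToInt(seq)
  n <- length(x)
  shifts <- min_p:(n %/% 2L)
  score <- vapply(shifts, function(s) mean(x[1:(n - s)] == x[(s + 1):n]),
                  numeric(1))
  shifts[which.max(score)]
}

# Brute-force breakpoint oracle for error-free reads: events derived from
# the truth table's bookkeeping alone (no CIGAR arithmetic). A read on the
# mutated genome reports every implanted insertion/deletion whose mutated
# coordinate it covers strictly inside its span.
breakpoint_oracle <- function(read, truth, min_len = 50L) {
  v <- truth$variants[truth$variants$chrom == read$chrom, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(v))) {
    vi <- v[i, ]
    if (vi$kind == "INSERTION") {
      ins_len <- vi$length + vi$tsd_len
      if (ins_len < min_len) next
      if (vi$mut_pos > read$mut_start && vi$mut_pos + ins_len < read$mut_end)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read$id, kind = "INS", chrom = vi$chrom,
          ref_pos = vi$position, length = ins_len,
          stringsAsFactors = FALSE)
    } else if (vi$kind == "DELETION") {
      if (vi$length < min_len) next
      if (vi$mut_pos > read$mut_start && vi$mut_pos < read$mut_end)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read$id, kind = "DEL", chrom = vi$chrom,
          ref_pos = vi$position, length = vi$length,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(read_id = character(), kind = character(),
                      chrom = character(), ref_pos = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Genome with the 9-bp CRK19-like target-site motif written at `pos` and a
# guard base so the constructed TSD is exactly the motif.
genome_with_motif <- function(n, pos, motif, payload, seed, chrom = "chr1") {
  g <- random_dna(n, seed = seed)
  k <- nchar(motif)
  substr(g, pos - k + 1L, pos) <- motif
  last <- substr(payload, nchar(payload), nchar(payload))
  guard <- setdiff(c("A", "C", "G", "T"), last)[1]
  substr(g, pos - k, pos - k) <- guard
  first <- substr(payload, 1L, 1L)
  guard2 <- setdiff(c("A", "C", "G", "T"), first)[1]
  substr(g, pos + 1L, pos + 1L) <- guard2
  stats::setNames(g, chrom)
}
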