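# Split-read tandem-duplication detection, small-deletion calling with
# control subtraction, and read-depth profiles.

#' Detect tandem duplications from split alignments
#'
#' A read spanning the head-to-tail junction of a tandem duplication is
#' split into two alignments on the same chromosome and strand whose
#' query intervals are adjacent and whose reference intervals overlap
#' (the later query segment jumps back to the duplication start). Each
#' such pair yields a candidate spanning the junction-consistent outer
#' interval (second segment's reference start to first segment's
#' reference end). Candidates are merged within `merge_window` bp and the
#' length filter is strict (`length > min_dup_len`).
#'
#' @param paf PAF data.frame (records grouped by read id internally).
#' @param min_dup_len Strict minimum duplication length (bp); default
#'   1000, i.e. duplications larger than 1 kb.
#' @param min_support Minimum distinct junction reads per call.
#' @param query_gap Maximum gap between the two query intervals (bp).
#' @param merge_window Candidate merge distance (bp).
#' @return data.frame: chrom, start, end, length, support, junction_reads
#'   (comma-separated read ids).
#' @export
detect_tandem_duplications <- function(paf, min_dup_len = 1000L,
                                       min_support = 1L, query_gap = 100L,
                                       merge_window = 50L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      support = integer(), junction_reads = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(paf)) return(empty)
  cand <- list()
  for (qn in unique(paf$qname)) {
    rec <- paf[paf$qname == qn, , drop = FALSE]
    if (nrow(rec) < 2L) next
    rec <- rec[order(rec$qstart), , drop = FALSE]
    for (i in seq_len(nrow(rec) - 1L)) {
      a <- rec[i, ]; b <- rec[i + 1L, ]
      if (a$tname != b$tname || a$strand != b$strand) next
      if (abs(b$qstart - a$qend) > query_gap) next
      # reference intervals must overlap: the later query segment jumps
      # back to (at most) the duplication start
      if (b$tstart >= a$tend || a$tstart >= b$tend) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = a$tname, start = b$tstart, end = a$tend,
        read = qn, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cd <- do.call(rbind, cand)
  out <- empty
  for (chrom in unique(cd$chrom)) {
    cc <- cd[cd$chrom == chrom, , drop = FALSE]
    cc <- cc[order(cc$start, cc$end), , drop = FALSE]
    g1 <- cumsum(c(TRUE, diff(cc$start) > merge_window))
    for (g in unique(g1)) {
      cg <- cc[g1 == g, , drop = FALSE]
      g2 <- cumsum(c(TRUE, diff(sort(cg$end)) > merge_window))
      cg <- cg[order(cg$end), , drop = FALSE]
      for (h in unique(g2)) {
        ch <- cg[g2 == h, , drop = FALSE]
        s <- as.integer(round(median(ch$start)))
        e <- as.integer(round(median(ch$end)))
        reads <- unique(ch$read)
        if (e - s <= min_dup_len) next
        if (length(reads) < min_support) next
        out <- rbind(out, data.frame(
          chrom = chrom, start = s, end = e, length = e - s,
          support = length(reads),
          junction_reads = paste(reads, collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Call small deletions from CIGAR D operations
#'
#' Deletion evidence of at least `min_del_len` bases is extracted with
#' [walk_cigar_paf()] and clustered positionally like the insertion
#' pipeline; calls report the median deletion length.
#'
#' @param paf PAF data.frame with CIGARs.
#' @param min_del_len Minimum deletion length (bp; default 20, the small-
#'   deletion recovery setting).
#' @param window Clustering window (bp).
#' @param min_support Strict support threshold (cluster kept when support
#'   exceeds `min_support`).
#' @return data.frame: chrom, start, end, length, support.
#' @export
call_small_deletions <- function(paf, min_del_len = 20L, window = 10L,
                                 min_support = 4L) {
  ev <- walk_cigar_paf(paf, min_len = min_del_len)
  ev <- ev[ev$kind == "DEL", , drop = FALSE]
  cl <- cluster_breakpoints(ev, window = window, min_support = min_support)
  out <- data.frame(chrom = cl$chrom, start = cl$pos,
                    end = cl$pos + cl$length, length = cl$length,
                    support = cl$support, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove mutant calls that overlap any control call
#'
#' A mutant call is removed when a control call overlaps it by at least
#' 1 bp (half-open intervals: abutting calls do not overlap). Both call
#' sets must be on the same reference.
#'
#' @param mutant,control Call data.frames with chrom/start/end columns.
#' @param ref_mutant,ref_control Optional reference genome names; an error
#'   is raised when both are given and differ.
#' @return The mutant-specific calls.
#' @export
subtract_control <- function(mutant, control,
                             ref_mutant = NULL, ref_control = NULL) {
  if (!is.null(ref_mutant) && !is.null(ref_control) &&
      ref_mutant != ref_control)
    stop("reference name mismatch: ", ref_mutant, " vs ", ref_control)
  if (!nrow(mutant) || !nrow(control)) return(mutant)
  gm <- GenomicRanges::GRanges(mutant$chrom,
                               IRanges::IRanges(mutant$start + 1L, mutant$end))
  gc <- GenomicRanges::GRanges(control$chrom,
                               IRanges::IRanges(control$start + 1L, control$end))
  hit <- GenomicRanges::countOverlaps(gm, gc, minoverlap = 1L) > 0L
  out <- mutant[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean read depth in bins across a region
#'
#' Per-base coverage from the reference spans of primary records, averaged
#' in `bin_size` windows tiling the region (the final bin may be shorter).
#'
#' @param paf PAF data.frame.
#' @param chrom Chromosome.
#' @param start,end Region (0-based half-open); must be non-empty.
#' @param bin_size Bin width (bp).
#' @return data.frame: chrom, bin_start, bin_size, depth.
#' @export
depth_profile <- function(paf, chrom, start, end, bin_size = 100L) {
  if (end <= start) stop("empty region")
  prim <- paf[paf$tname == chrom & (is.na(paf$tp) | paf$tp == "P"), ,
              drop = FALSE]
  cov <- IRanges::coverage(IRanges::IRanges(prim$tstart + 1L, prim$tend),
                           width = max(end, max(c(prim$tend, 0L))))
  bin_start <- seq.int(start, end - 1L, by = bin_size)
  bin_end <- pmin(bin_start + bin_size, end)
  v <- IRanges::Views(cov, bin_start + 1L, bin_end)
  data.frame(chrom = chrom, bin_start = bin_start,
             bin_size = bin_end - bin_start,
             depth = as.numeric(IRanges::viewMeans(v)),
             stringsAsFactors = FALSE)
}

#' Flag reads with three or more split segments at two or more loci
#'
#' Complex chimeric ("3-hit") reads — e.g. a read running gene A, a TE,
#' then gene B megabases away — are reported descriptively, not typed.
#'
#' @param paf PAF data.frame.
#' @param distinct_dist Minimum separation (bp) for two segments to count
#'   as distinct loci on the same chromosome.
#' @return data.frame: read_id, n_segments, n_loci, loci (comma-separated
#'   chrom:start descriptors).
#' @export
flag_multihit_reads <- function(paf, distinct_dist = 50000L) {
  out <- data.frame(read_id = character(), n_segments = integer(),
                    n_loci = integer(), loci = character(),
                    stringsAsFactors = FALSE)
  for (qn in unique(paf$qname)) {
    rec <- paf[paf$qname == qn, , drop = FALSE]
    if (nrow(rec) < 3L) next
    rec <- rec[order(rec$tname, rec$tstart), , drop = FALSE]
    newloc <- c(TRUE, rec$tname[-1L] != rec$tname[-nrow(rec)] |
                  diff(rec$tstart) > distinct_dist)
    loci <- rec[newloc, , drop = FALSE]
    if (nrow(loci) < 2L) next
    out <- rbind(out, data.frame(
      read_id = qn, n_segments = nrow(rec), n_loci = nrow(loci),
      loci = paste(paste0(loci$tname, ":", loci$tstart), collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
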