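# CIGAR-walking TE insertion caller: breakpoint extraction from
# CIGAR-bearing alignments, positional clustering with read-support
# filtering, TSD detection/validation, and insertion typing.

#' Extract insertion/deletion breakpoints from one alignment's CIGAR
#'
#' Walks the CIGAR accumulating query and reference cursors; every `I`
#' operation of at least `min_len` bases yields an INS at the current
#' reference position (with the inserted query substring when the read
#' sequence is available), every such `D` a DEL spanning its reference
#' interval.
#'
#' @param record One PAF record (one-row data.frame).
#' @param min_len Minimum event length (bp). Default 50 targets
#'   TE-insertion-scale events; the small-deletion caller uses 20.
#' @param query_seq Optional full read sequence (plus strand) used to
#'   report inserted sequences.
#' @return data.frame: read_id, kind (INS/DEL), chrom, ref_pos, length,
#'   inserted_seq.
#' @export
walk_cigar <- function(record, min_len = 50L, query_seq = NULL) {
  validate_paf(record)
  ops <- cigar_ops(record$cigar)
  refc <- ops$op %in% c("M", "=", "X", "D", "N")
  qc <- ops$op %in% c("M", "=", "X", "I")
  ref_before <- record$tstart + cumsum(c(0L, (ops$len * refc)[-nrow(ops)]))
  q_before <- record$qstart + cumsum(c(0L, (ops$len * qc)[-nrow(ops)]))
  out <- data.frame(read_id = character(), kind = character(),
                    chrom = character(), ref_pos = integer(),
                    length = integer(), inserted_seq = character(),
                    stringsAsFactors = FALSE)
  sel <- which(ops$op %in% c("I", "D") & ops$len >= min_len)
  if (!length(sel)) return(out)
  ins <- ops$op[sel] == "I"
  seqs <- rep(NA_character_, length(sel))
  if (!is.null(query_seq) && any(ins)) {
    s <- q_before[sel[ins]]
    seqs[ins] <- substring(query_seq, s + 1L, s + ops$len[sel[ins]])
  }
  data.frame(read_id = record$qname,
             kind = ifelse(ins, "INS", "DEL"),
             chrom = record$tname,
             ref_pos = ref_before[sel],
             length = ops$len[sel],
             inserted_seq = seqs, stringsAsFactors = FALSE)
}

#' Extract breakpoints from all records of a PAF table
#'
#' @param paf PAF data.frame.
#' @param min_len Minimum event length (bp).
#' @param reads Optional named character vector (or list of `sim_read`)
#'   giving read sequences by id, for inserted-sequence reporting.
#' @return Combined breakpoint evidence data.frame (see [walk_cigar()]).
#' @export
walk_cigar_paf <- function(paf, min_len = 50L, reads = NULL) {
  if (!is.null(reads) && !is.character(reads)) {
    nm <- vapply(reads, `[[`, character(1), "id")
    reads <- stats::setNames(vapply(reads, `[[`, character(1), "seq"), nm)
  }
  rows <- lapply(seq_len(nrow(paf)), function(i) {
    qs <- if (is.null(reads)) NULL else unname(reads[paf$qname[i]])
    walk_cigar(paf[i, ], min_len, qs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(), kind = character(),
                      chrom = character(), ref_pos = integer(),
                      length = integer(), inserted_seq = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster breakpoint evidence by position
#'
#' Single-linkage grouping of same-kind, same-chromosome evidence within
#' `window` bp. Support counts distinct read ids (one read contributes
#' once per cluster); clusters are retained only with support strictly
#' greater than `min_support` (the "more than 4 supported reads" rule).
#'
#' @param evidence Breakpoint evidence ([walk_cigar_paf()]).
#' @param window Linking distance in bp (configurable down to 0).
#' @param min_support Strict lower bound on supporting reads.
#' @return data.frame: cluster_id, chrom, kind, start, end (footprint),
#'   pos (median breakpoint), length (median), support; member evidence in
#'   attribute `members` (list of data.frames, by cluster_id).
#' @export
cluster_breakpoints <- function(evidence, window = 10L, min_support = 4L) {
  out <- data.frame(cluster_id = integer(), chrom = character(),
                    kind = character(), start = integer(), end = integer(),
                    pos = integer(), length = integer(), support = integer(),
                    stringsAsFactors = FALSE)
  members <- list()
  if (!nrow(evidence)) {
    attr(out, "members") <- members
    return(out)
  }
  ev <- evidence[order(evidence$chrom, evidence$kind, evidence$ref_pos), ,
                 drop = FALSE]
  key <- paste(ev$chrom, ev$kind)
  newgrp <- c(TRUE, key[-1L] != key[-nrow(ev)] |
                diff(ev$ref_pos) > window)
  grp <- cumsum(newgrp)
  cid <- 0L
  for (g in unique(grp)) {
    eg <- ev[grp == g, , drop = FALSE]
    support <- length(unique(eg$read_id))
    if (support <= min_support) next
    cid <- cid + 1L
    foot_end <- max(eg$ref_pos + ifelse(eg$kind == "DEL", eg$length, 1L))
    out <- rbind(out, data.frame(
      cluster_id = cid, chrom = eg$chrom[1], kind = eg$kind[1],
      start = min(eg$ref_pos), end = foot_end,
      pos = as.integer(round(median(eg$ref_pos))),
      length = as.integer(round(median(eg$length))),
      support = support, stringsAsFactors = FALSE))
    members[[cid]] <- eg
  }
  attr(out, "members") <- members
  out
}

#' Export breakpoint clusters as BED6
#' @param clusters Result of [cluster_breakpoints()].
#' @param path Output BED file.
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                    paste0(clusters$kind, "_", clusters$cluster_id),
                    clusters$support, "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Longest exact terminal match (1..max_tsd) between the inserted sequence
# and the reference around the insertion point. The suffix of the insert
# is compared to the bases immediately 5' of the insertion point, and the
# prefix to the bases immediately 3' (the two equivalent alignment
# placements of a TSD-bearing insertion); the longer wins.
tsd_seq_method_ <- function(insert, ref_seq, pos, max_tsd = 30L) {
  li <- nchar(insert)
  suff <- 0L
  while (suff < min(max_tsd, li, pos) &&
         substr(insert, li - suff, li - suff) ==
         substr(ref_seq, pos - suff, pos - suff))
    suff <- suff + 1L
  pref <- 0L
  lr <- nchar(ref_seq)
  while (pref < min(max_tsd, li) && pos + pref + 1L <= lr &&
         substr(insert, pref + 1L, pref + 1L) ==
         substr(ref_seq, pos + pref + 1L, pos + pref + 1L))
    pref <- pref + 1L
  if (suff >= pref) {
    list(len = suff, seq = if (suff > 0) substr(ref_seq, pos - suff + 1L, pos) else "")
  } else {
    list(len = pref, seq = substr(ref_seq, pos + 1L, pos + pref))
  }
}

#' Detect the target-site duplication of an insertion cluster
#'
#' Two detectors, reconciled: (a) sequence method — the longest exact
#' terminal match between the inserted sequence and the adjacent reference
#' bases, taken per member read and summarized by its modal value; (b)
#' split-read method — the overlap between the reference end of alignments
#' stopping at the site and the reference start of alignments beginning
#' there. When both fire their lengths must agree, else the call is
#' flagged ambiguous.
#'
#' @param cluster One cluster row from [cluster_breakpoints()], with its
#'   member evidence (attribute or `members` argument).
#' @param members Member evidence data.frame for the cluster.
#' @param ref_seq Reference chromosome sequence.
#' @param flank_alignments Optional PAF records of reads clipped at the
#'   site (for the split-read method).
#' @param max_tsd Maximum TSD length considered.
#' @param window Positional window used by the split-read method.
#' @return List: tsd_seq, tsd_len (NA when undetectable), method,
#'   ambiguous flag.
#' @export
detect_tsd <- function(cluster, members, ref_seq, flank_alignments = NULL,
                       max_tsd = 30L, window = 20L) {
  seq_len_v <- integer(0)
  seq_seq_v <- character(0)
  with_seqs <- members[!is.na(members$inserted_seq), , drop = FALSE]
  for (i in seq_len(nrow(with_seqs))) {
    r <- tsd_seq_method_(with_seqs$inserted_seq[i], ref_seq,
                         with_seqs$ref_pos[i], max_tsd)
    seq_len_v <- c(seq_len_v, r$len)
    seq_seq_v <- c(seq_seq_v, r$seq)
  }
  seq_call <- NULL
  if (length(seq_len_v)) {
    tab <- sort(table(seq_len_v), decreasing = TRUE)
    modal <- as.integer(names(tab)[1])
    seq_call <- list(len = modal,
                     seq = seq_seq_v[match(modal, seq_len_v)])
  }
  split_call <- NULL
  if (!is.null(flank_alignments) && nrow(flank_alignments)) {
    fa <- flank_alignments
    ends <- fa$tend[abs(fa$tend - cluster$pos) <= window + max_tsd]
    starts <- fa$tstart[abs(fa$tstart - cluster$pos) <= window + max_tsd]
    if (length(ends) && length(starts)) {
      ov <- as.integer(round(median(ends)) - round(median(starts)))
      if (ov > 0L) split_call <- list(len = ov)
    }
  }
  if (is.null(seq_call) && is.null(split_call))
    return(list(tsd_seq = NA_character_, tsd_len = NA_integer_,
                method = "none", ambiguous = FALSE))
  if (!is.null(seq_call) && !is.null(split_call)) {
    amb <- seq_call$len != split_call$len
    return(list(tsd_seq = seq_call$seq, tsd_len = seq_call$len,
                method = "both", ambiguous = amb))
  }
  if (!is.null(seq_call))
    return(list(tsd_seq = seq_call$seq, tsd_len = seq_call$len,
                method = "sequence", ambiguous = FALSE))
  list(tsd_seq = NA_character_, tsd_len = split_call$len,
       method = "split_read", ambiguous = FALSE)
}

# Annotate an insertion point against gene features. Priority:
# exon > UTR > intron; otherwise intergenic with distance to nearest gene.
annotate_target_ <- function(chrom, pos, annotation) {
  if (is.null(annotation)) return("intergenic")
  p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  typ <- tolower(as.character(annotation$type))
  pick <- function(types) {
    sel <- annotation[typ %in% types]
    length(sel) && length(GenomicRanges::findOverlaps(p, sel))
  }
  if (pick("five_prime_utr")) return("5'UTR")
  if (pick("three_prime_utr")) return("3'UTR")
  if (pick("exon")) return("exon")
  genes <- annotation[typ == "gene"]
  if (length(genes) && length(GenomicRanges::findOverlaps(p, genes)))
    return("intron")
  if (!length(genes)) return("intergenic")
  d <- GenomicRanges::distanceToNearest(p, genes)
  if (!length(d)) return("intergenic")
  paste0("intergenic(", S4Vectors::mcols(d)$distance, ")")
}

#' Type insertion clusters by TE family, truncation and target site
#'
#' The representative inserted sequence (a majority-vote consensus of the
#' member inserts; the longest member when fewer than three carry
#' sequence) is matched to each TE model by exact shared k-mers (forward
#' and reverse complement):
#' the family whose model covers the most of the insert wins, provided at
#' least `min_family_cov` of the insert is covered; per-domain model
#' coverage then gives the truncation status. The insertion point is
#' annotated against gene features, and the TSD is detected per cluster.
#'
#' @param clusters INS clusters from [cluster_breakpoints()] (with
#'   `members` attribute).
#' @param te_library List of `te_model` objects.
#' @param reference Named character vector of reference sequences.
#' @param annotation Optional `GRanges` of gene features (GFF3 import);
#'   when absent, calls are annotated intergenic-only with a warning.
#' @param flank_alignments Optional PAF for the split-read TSD method.
#' @param min_family_cov Minimum insert coverage for family assignment.
#' @param presence_cov Domain-presence coverage threshold.
#' @param k K-mer size.
#' @return data.frame: chrom, pos, family, tsd_seq, tsd_len, truncated,
#'   missing_domains, target_annotation, support.
#' @export
call_insertions <- function(clusters, te_library, reference,
                            annotation = NULL, flank_alignments = NULL,
                            min_family_cov = 0.6, presence_cov = 0.8,
                            k = 15L) {
  if (is.null(annotation))
    warning("no gene annotation: target sites reported intergenic-only")
  members <- attr(clusters, "members")
  ins <- clusters[clusters$kind == "INS", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ins))) {
    cl <- ins[i, ]
    mem <- members[[cl$cluster_id]]
    seqs <- mem$inserted_seq[!is.na(mem$inserted_seq)]
    family <- "unassigned"; truncated <- FALSE; missing <- character(0)
    if (length(seqs)) {
      rep_seq <- if (length(seqs) >= 3L) consensus_from_seqs(seqs)
                 else seqs[which.max(nchar(seqs))]
      best_cov <- 0; best_model <- NULL; best_seq <- rep_seq
      for (m in te_library[order(vapply(te_library, `[[`, character(1), "name"))]) {
        for (s in c(rep_seq, revcomp(rep_seq))) {
          cov <- mean(kmer_cover(s, m$sequence, k))
          if (cov > best_cov) {
            best_cov <- cov; best_model <- m; best_seq <- s
          }
        }
      }
      if (!is.null(best_model) && best_cov >= min_family_cov) {
        family <- best_model$name
        dom <- best_model$domains
        mc <- kmer_cover(best_model$sequence, best_seq, k)
        domcov <- vapply(seq_len(nrow(dom)), function(j)
          mean(mc[(dom$start[j] + 1L):dom$end[j]]), numeric(1))
        missing <- dom$label[domcov < presence_cov]
        truncated <- length(missing) > 0L
      }
    }
    tsd <- detect_tsd(cl, mem, reference[[cl$chrom]], flank_alignments)
    rows[[i]] <- data.frame(
      chrom = cl$chrom, pos = cl$pos, family = family,
      tsd_seq = tsd$tsd_seq, tsd_len = tsd$tsd_len,
      tsd_ambiguous = tsd$ambiguous,
      truncated = truncated,
      missing_domains = paste(missing, collapse = ","),
      target_annotation = annotate_target_(cl$chrom, cl$pos, annotation),
      support = cl$support, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(list(data.frame()), rows))
  rownames(out) <- NULL
  out
}

#' Filter insertion calls by TSD length
#'
#' Keeps calls with `min <= tsd_len <= max` (bounds inclusive; the 5-20 bp
#' window marks bona fide integrase-mediated insertion). Removed calls are
#' logged with a reason in the `removed` attribute.
#'
#' @param calls data.frame from [call_insertions()].
#' @param min,max Inclusive TSD length bounds (bp).
#' @return The retained calls.
#' @export
tsd_filter <- function(calls, min = 5L, max = 20L) {
  if (!nrow(calls)) {
    attr(calls, "removed") <- data.frame(pos = integer(), reason = character())
    return(calls)
  }
  keep <- !is.na(calls$tsd_len) & calls$tsd_len >= min & calls$tsd_len <= max
  reason <- ifelse(is.na(calls$tsd_len), "TSD undetectable",
                   ifelse(calls$tsd_len < min, "TSD too short", "TSD too long"))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(pos = calls$pos[!keep],
                                     reason = reason[!keep])
  out
}
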