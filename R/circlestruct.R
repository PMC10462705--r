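# Decomposition of RCA concatemer reads into monomers and classification
# of circle structure (full-length / domain-truncated / chimeric).

#' Estimate the tandem repeat period of a concatemer read
#'
#' Collects offsets between repeated exact k-mers along the read, clusters
#' them (offsets jitter under indel errors), and takes the modal offset
#' after collapsing multiples: an offset near `m * p` for integer `m > 1`
#' votes for `p`. Returns `NULL` ("no period") when the read is shorter
#' than twice the minimum period or the strongest mode has fewer than
#' `min_votes` supporting k-mer pairs — as for a non-repetitive read.
#'
#' @param read_seq Read sequence.
#' @param k K-mer size.
#' @param min_period Minimum period considered (bp).
#' @param min_votes Minimum number of supporting k-mer pairs.
#' @param tol_frac Relative tolerance used to cluster offsets and match
#'   multiples.
#' @return Estimated period (numeric, refined as the median of first-order
#'   offsets) or `NULL`.
#' @export
detect_period <- function(read_seq, k = 15L, min_period = 200L,
                          min_votes = 5L, tol_frac = 0.01) {
  n <- nchar(read_seq)
  if (n < 2L * min_period) return(NULL)
  km <- seq_kmers(read_seq, k)
  o <- order(km)
  same <- km[o][-1L] == km[o][-length(o)]
  offs <- (o[-1L] - o[-length(o)])[same]
  offs <- offs[offs >= min_period]
  if (length(offs) < min_votes) return(NULL)
  tab <- table(offs)
  vals <- as.integer(names(tab))
  cnts <- as.integer(tab)
  # single-linkage clustering of offset values
  tol_of <- function(v) pmax(3, round(tol_frac * v))
  brk <- c(TRUE, diff(vals) > tol_of(vals[-length(vals)]))
  grp <- cumsum(brk)
  centre <- vapply(split(seq_along(vals), grp), function(ii) {
    w <- cnts[ii]
    vals[ii][which.max(cumsum(w) >= sum(w) / 2)] # weighted median
  }, numeric(1))
  count <- vapply(split(cnts, grp), sum, numeric(1))
  # collapse multiples: votes(p) = counts of clusters near m*p
  votes <- vapply(seq_along(centre), function(i) {
    p <- centre[i]
    m <- round(centre / p)
    sum(count[m >= 1 & abs(centre - m * p) <= tol_of(centre)])
  }, numeric(1))
  best <- which(votes == max(votes))[1] # ties -> smallest period
  if (votes[best] < min_votes) return(NULL)
  p <- centre[best]
  keep <- abs(offs - p) <= tol_of(p)
  if (!any(keep)) return(p)
  stats::median(offs[keep])
}

#' Decompose a concatemer read into monomer copies and a consensus
#'
#' The read is cut into consecutive period-length windows; the first
#' complete window seeds the consensus and the remaining full windows are
#' aligned to it with banded edit alignment (band = 10% of the period).
#' A window counts as a complete copy when its end-to-end identity to the
#' seed is at least `min_copy_identity`; the consensus is a column-wise
#' majority vote over the seed coordinates.
#'
#' @param read_seq Read sequence.
#' @param period Monomer period in bp (e.g. from [detect_period()]).
#' @param read_id Identifier carried into the result.
#' @param band_frac Band half-width as a fraction of the period.
#' @param min_copy_identity Identity threshold for counting a copy.
#' @return Object of class `monomer_decomposition` with `period`,
#'   `complete_copies`, `consensus`, `identities`, and a `sub_monomer`
#'   flag when the read is shorter than one period (no consensus).
#' @export
decompose_read <- function(read_seq, period, read_id = "read",
                           band_frac = 0.10, min_copy_identity = 0.80) {
  period <- as.integer(round(period))
  L <- nchar(read_seq)
  nw <- L %/% period
  if (nw < 1L)
    return(structure(list(read_id = read_id, period = period,
                          complete_copies = 0L, consensus = NULL,
                          identities = numeric(0), sub_monomer = TRUE),
                     class = "monomer_decomposition"))
  seed <- substr(read_seq, 1L, period)
  band <- max(10L, as.integer(round(band_frac * period)))
  idents <- 1.0
  aligns <- list()
  if (nw > 1L) {
    for (i in seq_len(nw - 1L)) {
      w <- substr(read_seq, i * period + 1L, (i + 1L) * period)
      al <- banded_edit_align(seed, w, band)
      idents <- c(idents, al$matches / al$alnlen)
      aligns[[i]] <- al
    }
  }
  complete <- idents >= min_copy_identity
  consensus <- vote_consensus_(seed, aligns[complete[-1L]])
  structure(list(read_id = read_id, period = period,
                 complete_copies = as.integer(sum(complete)),
                 consensus = consensus, identities = idents,
                 sub_monomer = FALSE),
            class = "monomer_decomposition")
}

#' Majority-vote consensus of similar-length sequences
#'
#' The longest sequence seeds the consensus; the others are aligned to it
#' with banded edit alignment and voted column-wise. Used to polish
#' inserted sequences across supporting reads before family assignment
#' (raw long-read inserts carry too many errors for exact k-mer matching).
#'
#' @param seqs Character vector of sequences.
#' @param band_frac Band half-width as a fraction of the seed length.
#' @return Consensus string.
#' @export
consensus_from_seqs <- function(seqs, band_frac = 0.15) {
  seqs <- seqs[!is.na(seqs) & nchar(seqs) > 0L]
  if (!length(seqs)) return(NA_character_)
  if (length(seqs) == 1L) return(seqs)
  seed_i <- which.max(nchar(seqs))
  seed <- seqs[seed_i]
  band <- max(20L, as.integer(round(band_frac * nchar(seed))))
  vote_consensus_(seed, lapply(seqs[-seed_i], function(s)
    banded_edit_align(seed, s, band)))
}

# Column-majority consensus over the seed's coordinates, with insertion
# recovery: where most aligned sequences carry the same bases inserted
# relative to the seed (e.g. a base the seed copy lost to a sequencing
# deletion), those bases are restored.
vote_consensus_ <- function(seed, aligns) {
  la <- nchar(seed)
  cols <- c(list(strsplit(seed, "", fixed = TRUE)[[1]]),
            lapply(aligns, function(a)
              strsplit(a$aligned, "", fixed = TRUE)[[1]]))
  mat <- do.call(cbind, cols)
  nc <- ncol(mat)
  counts <- vapply(c(BASES, "-"), function(b) rowSums(mat == b), numeric(la))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  pick <- max.col(counts, ties.method = "first")
  chars <- c(BASES, "-")[pick]
  ins_cons <- rep("", la + 1L)
  if (length(aligns)) {
    insmat <- do.call(cbind, c(list(rep("", la + 1L)),
                               lapply(aligns, `[[`, "ins_after")))
    for (i in which(rowSums(insmat != "") > nc / 2)) {
      tab <- sort(table(insmat[i, ]), decreasing = TRUE)
      if (names(tab)[1] != "" && tab[1] > nc / 2)
        ins_cons[i + 0L] <- names(tab)[1]
    }
  }
  parts <- character(2L * la + 1L)
  parts[seq(1L, 2L * la + 1L, by = 2L)] <- ins_cons
  parts[seq(2L, 2L * la, by = 2L)] <- ifelse(chars == "-", "", chars)
  paste(parts, collapse = "")
}

#' Classify a consensus monomer against a TE model (and genome)
#'
#' The monomer is compared to the TE model by exact shared 15-mers, with
#' the consensus doubled so circular rotation does not split matches. A
#' domain is PRESENT when at least `presence_cov` of its model span is
#' covered. Classification: all domains present and monomer length close
#' to the full element -> `FULL_2LTR` (or `FULL_1LTR` when only one LTR
#' unit fits the monomer length); GAG/AP/IN absent with the rest present
#' -> `NO_GAG`; IN/RT absent -> `NO_IN_RT`; LTR/GAG/AP absent -> `NO_LTR`;
#' any unmatched segment of at least `min_chim_seg` bases that maps to the
#' genome -> `CHIMERIC`; anything else -> `OTHER_TRUNCATED`; no match to
#' model or genome -> `unclassified`.
#'
#' @param consensus Consensus monomer sequence.
#' @param te_model A `te_model`.
#' @param genome Optional named character vector used to place unmatched
#'   segments (chimera partners).
#' @param k K-mer size.
#' @param presence_cov Coverage fraction above which a domain is present.
#' @param min_chim_seg Minimum unmatched segment length tested against the
#'   genome (bp).
#' @param genome_cov Coverage fraction of a segment by genome k-mers
#'   required to call its origin.
#' @return List with `class`, per-domain coverage `evidence`, and for
#'   chimeras `segments` (lengths) and `junction` (TE-side coordinate,
#'   partner chromosome and position).
#' @export
classify_monomer <- function(consensus, te_model, genome = NULL, k = 15L,
                             presence_cov = 0.80, min_chim_seg = 100L,
                             genome_cov = 0.80) {
  len <- nchar(consensus)
  dbl <- paste0(consensus, consensus)
  model_cov <- kmer_cover(te_model$sequence, dbl, k)
  dom <- te_model$domains
  evidence <- vapply(seq_len(nrow(dom)), function(i)
    mean(model_cov[(dom$start[i] + 1L):dom$end[i]]), numeric(1))
  names(evidence) <- dom$label
  present <- evidence >= presence_cov
  # consensus positions covered by model k-mers (folded over the doubling)
  cons_cov_dbl <- kmer_cover(dbl, te_model$sequence, k)
  cons_cov <- cons_cov_dbl[seq_len(len)] | cons_cov_dbl[len + seq_len(len)]
  segs <- uncovered_runs(cons_cov)
  segs <- segs[segs$end - segs$start >= min_chim_seg, , drop = FALSE]
  chim <- NULL
  if (!is.null(genome) && nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      sseq <- substr(consensus, segs$start[i] + 1L, segs$end[i])
      for (chrom in names(genome)) {
        cov <- mean(kmer_cover(sseq, genome[[chrom]], k))
        if (is.na(cov) || cov < genome_cov) next
        mp <- kmer_match_positions(sseq, genome[[chrom]], k)
        chim <- rbind(chim, data.frame(
          cons_start = segs$start[i], cons_end = segs$end[i],
          length = segs$end[i] - segs$start[i],
          chrom = chrom, genome_pos = as.integer(min(mp$spos)),
          stringsAsFactors = FALSE))
        break
      }
    }
  }
  if (!is.null(chim) && nrow(chim)) {
    te_len_part <- len - sum(chim$length)
    # phase-invariant junction anchors: the end of the first covered run
    # on the model, and the left edge of the partner's matched interval
    te_end <- if (any(model_cov)) {
      r <- rle(model_cov)
      as.integer(cumsum(r$lengths)[which(r$values)[1]])
    } else NA_integer_
    gchrom <- chim$chrom[1]
    return(list(class = "CHIMERIC", evidence = evidence,
                segments = c(te = te_len_part, partner = chim$length),
                junction = list(te_pos = te_end, chrom = gchrom,
                                genome_pos = min(chim$genome_pos[
                                  chim$chrom == gchrom]))))
  }
  if (!any(evidence > 0.1))
    return(list(class = "unclassified", evidence = evidence))
  te_len <- nchar(te_model$sequence)
  ltr_len <- diff(domain_span(te_model, "LTR5"))
  cls <- if (all(present)) {
    if (len >= te_len - ltr_len / 2) "FULL_2LTR" else "FULL_1LTR"
  } else {
    absent <- names(present)[!present]
    if (setequal(absent, c("GAG", "AP", "IN"))) "NO_GAG"
    else if (setequal(absent, c("IN", "RT"))) "NO_IN_RT"
    else if (setequal(absent, c("LTR5", "LTR3", "GAG", "AP"))) "NO_LTR"
    else "OTHER_TRUNCATED"
  }
  list(class = cls, evidence = evidence)
}

#' Decompose and classify a set of concatemer reads
#'
#' Convenience wrapper running [detect_period()], [decompose_read()] and
#' [classify_monomer()] per read.
#'
#' @param reads List of `rca_read` (or any objects with `id` and `seq`).
#' @param te_model A `te_model`.
#' @param genome Optional genome for chimera placement.
#' @param min_copies Minimum complete copies required to classify a read
#'   (reads below it are reported `unclassified`).
#' @param ... Passed to [classify_monomer()].
#' @return data.frame: read_id, period, complete_copies, class; the
#'   per-read classification details are attached as attribute `details`.
#' @export
classify_reads <- function(reads, te_model, genome = NULL, min_copies = 1L, ...) {
  rows <- lapply(reads, function(r) {
    p <- detect_period(r$seq)
    if (is.null(p))
      return(list(row = data.frame(read_id = r$id, period = NA_real_,
                                   complete_copies = 0L,
                                   class = "unclassified",
                                   stringsAsFactors = FALSE),
                  detail = NULL))
    dec <- decompose_read(r$seq, p, read_id = r$id)
    if (dec$sub_monomer || dec$complete_copies < min_copies)
      return(list(row = data.frame(read_id = r$id, period = as.numeric(p),
                                   complete_copies = dec$complete_copies,
                                   class = "unclassified",
                                   stringsAsFactors = FALSE),
                  detail = NULL))
    cl <- classify_monomer(dec$consensus, te_model, genome, ...)
    list(row = data.frame(read_id = r$id, period = as.numeric(p),
                          complete_copies = dec$complete_copies,
                          class = cl$class, stringsAsFactors = FALSE),
         detail = cl)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "details") <- stats::setNames(lapply(rows, `[[`, "detail"), out$read_id)
  out
}

#' Call chimeric circles from classified reads
#'
#' CHIMERIC reads are grouped by junction (both breakends within
#' `junction_tol` bp); groups supported by at least `min_support` distinct
#' reads are emitted. Partner loci must be distinct from the TE side —
#' for genomic pairs, on different chromosomes or more than
#' `distinct_dist` bp apart.
#'
#' @param classified Result of [classify_reads()] (with `details`
#'   attribute) or a list of per-read classification lists.
#' @param min_support Minimum distinct supporting reads (default 5).
#' @param junction_tol Breakend grouping tolerance (bp).
#' @param distinct_dist Minimum separation defining distinct genomic loci.
#' @return data.frame: chrom, genome_pos, te_pos, support, read_ids
#'   (comma-separated).
#' @export
call_chimeric_circles <- function(classified, min_support = 5L,
                                  junction_tol = 20L, distinct_dist = 50000L) {
  details <- if (is.data.frame(classified)) attr(classified, "details")
             else classified
  rows <- list()
  for (id in names(details)) {
    d <- details[[id]]
    if (is.null(d) || d$class != "CHIMERIC" || is.null(d$junction)) next
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = id, chrom = d$junction$chrom,
      genome_pos = d$junction$genome_pos,
      te_pos = if (is.null(d$junction$te_pos) || is.na(d$junction$te_pos))
        -1L else d$junction$te_pos,
      stringsAsFactors = FALSE)
  }
  out <- data.frame(chrom = character(), genome_pos = integer(),
                    te_pos = integer(), support = integer(),
                    read_ids = character(), stringsAsFactors = FALSE)
  if (!length(rows)) return(out)
  ev <- do.call(rbind, rows)
  for (chrom in unique(ev$chrom)) {
    e <- ev[ev$chrom == chrom, , drop = FALSE]
    e <- e[order(e$genome_pos, e$te_pos), , drop = FALSE]
    g1 <- cumsum(c(TRUE, diff(e$genome_pos) > junction_tol))
    for (g in unique(g1)) {
      eg <- e[g1 == g, , drop = FALSE]
      g2 <- cumsum(c(TRUE, diff(eg$te_pos) > junction_tol))
      for (h in unique(g2)) {
        eh <- eg[g2 == h, , drop = FALSE]
        support <- length(unique(eh$read_id))
        if (support < min_support) next
        out <- rbind(out, data.frame(
          chrom = chrom,
          genome_pos = as.integer(median(eh$genome_pos)),
          te_pos = as.integer(median(eh$te_pos)),
          support = support,
          read_ids = paste(unique(eh$read_id), collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarize circle-class composition
#'
#' Fractions over classified (non-`unclassified`) reads; errors when no
#' read was classified.
#'
#' @param classes Character vector of per-read classes (or the data.frame
#'   from [classify_reads()]).
#' @return data.frame: class, n, fraction (fractions sum to 1).
#' @export
summarize_composition <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  classes <- classes[classes != "unclassified"]
  if (!length(classes)) stop("no classified reads")
  tab <- table(classes)
  data.frame(class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
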