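# Synthetic data generator: references with implanted variants, circle
# templates, RCA concatemer reads, genomic spanning reads, and ground-truth
# PAF alignments. Coordinates are 0-based half-open throughout.

#' Describe a variant to implant in a synthetic reference
#'
#' @param kind One of `INSERTION`, `TANDEM_DUP`, `DELETION`.
#' @param chrom Chromosome name.
#' @param position 0-based reference coordinate (insertion point, or
#'   interval start for duplications/deletions).
#' @param length Interval length in bp (duplication/deletion only).
#' @param payload Inserted DNA string (insertion only).
#' @param tsd_len Target-site duplication length in bp, 0-30 (insertion
#'   only): on insertion the `tsd_len` reference bases preceding
#'   `position` are duplicated after the payload.
#' @return One-row data.frame.
#' @export
variant_spec <- function(kind, chrom, position, length = NA_integer_,
                         payload = NA_character_, tsd_len = 0L) {
  kind <- match.arg(kind, c("INSERTION", "TANDEM_DUP", "DELETION"))
  if (kind == "INSERTION") {
    if (is.na(payload) || nchar(payload) == 0L) stop("INSERTION needs a payload")
    if (tsd_len < 0L || tsd_len > 30L) stop("tsd_len must be in [0, 30]")
    length <- nchar(payload)
  } else if (is.na(length) || length < 1L) {
    stop(kind, " needs a positive length")
  }
  data.frame(kind = kind, chrom = chrom, position = as.integer(position),
             length = as.integer(length), payload = payload,
             tsd_len = as.integer(tsd_len), stringsAsFactors = FALSE)
}

#' Per-base read error model configuration
#'
#' Independent per-base substitution/insertion/deletion errors; defaults
#' approximate an ONT long-read profile. Identical seeds give bit-identical
#' simulated output.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities, each at most
#'   0.2.
#' @param seed Optional integer seed.
#' @return Object of class `read_sim_config`.
#' @export
read_sim_config <- function(sub_rate = 0.03, ins_rate = 0.015,
                            del_rate = 0.015, seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2)) stop("error rates must be in [0, 0.2]")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = seed),
            class = "read_sim_config")
}

#' Error-free read configuration
#' @param seed Optional integer seed (still used for read placement).
#' @return A `read_sim_config` with all error rates zero.
#' @export
error_free_config <- function(seed = NULL) {
  read_sim_config(0, 0, 0, seed = seed)
}

# Corrupt a template string with the configured error model, using the
# caller's RNG stream. Returns the read and its run-length alignment to
# the template (= match, X substitution, I read-only base, D template-only
# base).
sim_read_errors <- function(template, config) {
  n <- nchar(template)
  if (config$sub_rate == 0 && config$ins_rate == 0 && config$del_rate == 0)
    return(list(seq = template,
                ops = data.frame(len = n, op = "=", stringsAsFactors = FALSE)))
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  del <- runif(n) < config$del_rate
  sub <- !del & (runif(n) < config$sub_rate)
  ins <- runif(n) < config$ins_rate
  out <- chars
  if (any(sub)) {
    bi <- match(chars[sub], BASES)
    out[sub] <- BASES[((bi - 1L + sample.int(3L, sum(sub), replace = TRUE)) %% 4L) + 1L]
  }
  insbase <- character(n)
  if (any(ins)) insbase[ins] <- sample(BASES, sum(ins), replace = TRUE)
  piece <- ifelse(del, "", out)
  seqv <- paste(paste0(piece, insbase), collapse = "")
  mainop <- ifelse(del, "D", ifelse(sub, "X", "="))
  opm <- rbind(mainop, ifelse(ins, "I", NA))
  opv <- as.vector(opm)
  r <- rle(opv[!is.na(opv)])
  list(seq = seqv,
       ops = data.frame(len = r$lengths, op = r$values, stringsAsFactors = FALSE))
}

#' Implant variants into a reference genome
#'
#' Insertions add their payload plus one copy of the `tsd_len` bases
#' preceding the insertion point (so the site is flanked by identical TSD
#' copies on the mutated genome); tandem duplications double their interval
#' head-to-tail; deletions remove theirs. A liftover block map from mutated
#' to reference coordinates is recorded so ground-truth alignments against
#' the reference can be emitted for any simulated read.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param specs data.frame of [variant_spec()] rows, sorted by position and
#'   non-overlapping within each chromosome.
#' @return List with `genome` (mutated, same names) and `truth`
#'   (class `truth_table`: variants with mutated-genome coordinates, the
#'   liftover blocks, and a registry filled by the read simulators).
#' @export
implant_variants <- function(genome, specs) {
  stopifnot(!is.null(names(genome)))
  if (!all(specs$chrom %in% names(genome)))
    stop("spec chromosome not in genome")
  mutated <- genome
  blocks <- list()
  specs$mut_pos <- rep(NA_integer_, nrow(specs))
  for (chrom in names(genome)) {
    ref <- genome[[chrom]]
    L <- nchar(ref)
    idx <- which(specs$chrom == chrom)
    sp <- specs[idx, , drop = FALSE]
    if (nrow(sp) > 1L && is.unsorted(sp$position, strictly = FALSE))
      stop("specs must be sorted by position")
    foot_start <- ifelse(sp$kind == "INSERTION", sp$position - sp$tsd_len, sp$position)
    foot_end <- ifelse(sp$kind == "INSERTION", sp$position, sp$position + sp$length)
    if (nrow(sp) > 1L && any(foot_start[-1L] < foot_end[-nrow(sp)]))
      stop("overlapping variant specs on ", chrom)
    if (any(foot_start < 0L) || any(foot_end > L))
      stop("variant outside chromosome ", chrom)
    pieces <- character(0)
    blk <- list()
    r <- 0L; m <- 0L
    add_block <- function(type, mwidth, rstart, rend) {
      blk[[length(blk) + 1L]] <<- data.frame(
        type = type, mut_start = m, mut_end = m + mwidth,
        ref_start = rstart, ref_end = rend, stringsAsFactors = FALSE)
      m <<- m + mwidth
    }
    add_match <- function(upto) {
      if (upto > r) {
        pieces <<- c(pieces, substr(ref, r + 1L, upto))
        add_block("match", upto - r, r, upto)
        r <<- upto
      }
    }
    for (j in seq_len(nrow(sp))) {
      v <- sp[j, ]
      if (v$kind == "INSERTION") {
        add_match(v$position)
        ins_seq <- paste0(v$payload,
                          if (v$tsd_len > 0L)
                            substr(ref, v$position - v$tsd_len + 1L, v$position)
                          else "")
        specs$mut_pos[idx[j]] <- m
        pieces <- c(pieces, ins_seq)
        add_block("ins", nchar(ins_seq), NA_integer_, NA_integer_)
      } else if (v$kind == "DELETION") {
        add_match(v$position)
        specs$mut_pos[idx[j]] <- m
        add_block("del", 0L, v$position, v$position + v$length)
        r <- v$position + v$length
      } else { # TANDEM_DUP
        add_match(v$position + v$length)
        specs$mut_pos[idx[j]] <- m
        pieces <- c(pieces, substr(ref, v$position + 1L, v$position + v$length))
        add_block("dupback", v$length, v$position, v$position + v$length)
      }
    }
    add_match(L)
    mutated[[chrom]] <- paste(pieces, collapse = "")
    blocks[[chrom]] <- do.call(rbind, blk)
  }
  truth <- structure(list(variants = specs, blocks = blocks,
                          ref_len = vapply(genome, nchar, integer(1)),
                          mut_len = vapply(mutated, nchar, integer(1)),
                          circles = list()),
                     class = "truth_table")
  list(genome = mutated, truth = truth)
}

CIRCLE_CLASSES <- c("FULL_1LTR", "FULL_2LTR", "NO_GAG", "NO_IN_RT", "NO_LTR",
                    "CHIMERIC", "OTHER")

#' Build a circular eccDNA template of a given structural class
#'
#' Classes mirror the structures seen in TE-derived eccDNA: full-length
#' circles with 1 or 2 LTRs, internally truncated circles lacking
#' GAG/AP/IN (`NO_GAG`), lacking IN/RT (`NO_IN_RT`), or lacking
#' LTR/GAG/AP (`NO_LTR`), a residual truncated form (`OTHER`, lacking RT
#' only), and chimeric circles fusing a TE fragment with a genomic
#' (e.g. genic) fragment.
#'
#' @param te A `te_model`.
#' @param truth_class One of `FULL_1LTR, FULL_2LTR, NO_GAG, NO_IN_RT,
#'   NO_LTR, CHIMERIC, OTHER`.
#' @param chimera_partner For `CHIMERIC`: list with `chrom`, `start`, `end`
#'   (0-based half-open genomic interval).
#' @param genome Named character vector (needed for `CHIMERIC`).
#' @param te_frag_len TE fragment length used for `CHIMERIC` (default
#'   701 bp from the element 5' end).
#' @return Object of class `circle_template` with `segments`, `sequence`,
#'   `total_len` and `truth_class`.
#' @export
make_circle_template <- function(te, truth_class, chimera_partner = NULL,
                                 genome = NULL, te_frag_len = 701L) {
  truth_class <- match.arg(truth_class, CIRCLE_CLASSES)
  n <- nchar(te$sequence)
  iv <- function(a, b) data.frame(source = te$name, start = a, end = b)
  segs <- switch(truth_class,
    FULL_2LTR = iv(0L, n),
    FULL_1LTR = iv(0L, domain_span(te, "LTR3")[1]),
    NO_GAG = rbind(iv(0L, domain_span(te, "LTR5")[2]),
                   iv(domain_span(te, "RT")[1], n)),
    NO_IN_RT = rbind(iv(0L, domain_span(te, "IN")[1]),
                     iv(domain_span(te, "RH")[1], n)),
    NO_LTR = iv(domain_span(te, "IN")[1], domain_span(te, "RH")[2]),
    OTHER = rbind(iv(0L, domain_span(te, "RT")[1]),
                  iv(domain_span(te, "RH")[1], n)),
    CHIMERIC = {
      if (is.null(chimera_partner) || is.null(genome))
        stop("CHIMERIC requires a chimera_partner interval and a genome")
      rbind(iv(0L, te_frag_len),
            data.frame(source = chimera_partner$chrom,
                       start = chimera_partner$start,
                       end = chimera_partner$end))
    })
  seq_of <- function(src, a, b) {
    if (src == te$name) substr(te$sequence, a + 1L, b)
    else substr(genome[[src]], a + 1L, b)
  }
  pieces <- mapply(seq_of, segs$source, segs$start, segs$end)
  sequence <- paste(pieces, collapse = "")
  segs$length <- segs$end - segs$start
  structure(list(segments = segs, sequence = sequence,
                 total_len = nchar(sequence), truth_class = truth_class),
            class = "circle_template")
}

#' Simulate a rolling-circle-amplification concatemer read
#'
#' The read is the circle rolled out from `start_phase` for `read_len`
#' bases and then corrupted by the error model. Ground-truth complete copy
#' count is `floor(read_len / total_len)`; reads shorter than one monomer
#' are flagged sub-monomer.
#'
#' @param template A `circle_template`.
#' @param read_len Target read length (bp).
#' @param start_phase 0-based offset into the circle, or `NULL` to draw
#'   uniformly (seeded).
#' @param config A `read_sim_config`.
#' @param id Read identifier.
#' @return Object of class `rca_read` with `seq`, truth `copies`, `phase`
#'   and `sub_monomer` flag.
#' @export
simulate_rca_read <- function(template, read_len, start_phase = NULL,
                              config = read_sim_config(), id = "rca_1") {
  total <- template$total_len
  with_seed(config$seed, {
    phase <- if (is.null(start_phase)) sample.int(total, 1L) - 1L
             else as.integer(start_phase)
    reps <- ceiling((read_len + phase) / total) + 1L
    rolled <- substr(strrep(template$sequence, reps), phase + 1L, phase + read_len)
    err <- sim_read_errors(rolled, config)
    structure(list(id = id, seq = err$seq, truth_class = template$truth_class,
                   copies = as.integer(read_len %/% total), phase = phase,
                   period = total, sub_monomer = read_len < total),
              class = "rca_read")
  })
}

#' Simulate genomic long reads spanning a locus
#'
#' Each read covers `locus` with at least `flank` bases on both sides
#' (where the chromosome allows), with seeded uniform placement, then gets
#' the configured error model.
#'
#' @param genome_seq Chromosome sequence the reads are drawn from (for
#'   variant studies, the mutated genome).
#' @param locus `c(start, end)` 0-based half-open interval to span.
#' @param n_reads Number of reads.
#' @param config A `read_sim_config` (its `seed` drives placement and
#'   errors).
#' @param read_len Read length (bp).
#' @param flank Minimum flank on each side of the locus (bp).
#' @param chrom Chromosome name recorded on the reads.
#' @param id_prefix Read id prefix.
#' @return List of `sim_read` objects (`id`, `seq`, `chrom`, `mut_start`,
#'   `mut_end`, `ops`).
#' @export
simulate_spanning_reads <- function(genome_seq, locus, n_reads,
                                    config = read_sim_config(),
                                    read_len = 20000L, flank = 1000L,
                                    chrom = "chr1", id_prefix = "read") {
  glen <- nchar(genome_seq)
  if (locus[1] < 0L || locus[2] > glen) stop("locus outside genome")
  if (read_len > glen) stop("read_len longer than the chromosome")
  lo_min <- max(0L, locus[2] + flank - read_len)
  lo_max <- min(locus[1] - flank, glen - read_len)
  if (lo_max < 0L) lo_max <- 0L
  if (lo_min > lo_max) lo_min <- lo_max
  if (n_reads == 0L) return(list())
  with_seed(config$seed, {
    starts <- lo_min + floor(runif(n_reads) * (lo_max - lo_min + 1L))
    lapply(seq_len(n_reads), function(i) {
      s <- as.integer(starts[i])
      err <- sim_read_errors(substr(genome_seq, s + 1L, s + read_len), config)
      structure(list(id = sprintf("%s_%d", id_prefix, i), seq = err$seq,
                     chrom = chrom, mut_start = s, mut_end = s + read_len,
                     ops = err$ops),
                class = "sim_read")
    })
  })
}

#' Emit ground-truth PAF alignments against the reference
#'
#' Constructs, for each simulated read, the alignment against the
#' reference genome implied by the implant record: an insertion appears as
#' an `I` CIGAR operation carrying the payload plus one TSD copy, a
#' deletion as a `D` operation, and a tandem-duplication junction as two
#' records whose reference intervals overlap. Per-base sequencing errors
#' from the read simulation are carried through as `X`/`I`/`D` operations.
#'
#' @param reads List of `sim_read` objects.
#' @param truth The `truth_table` from [implant_variants()].
#' @param mapq Mapping quality to report.
#' @return PAF data.frame (one or more records per read; `tp` marks the
#'   primary record).
#' @export
emit_truth_alignments <- function(reads, truth, mapq = 60L) {
  rows <- lapply(reads, function(read) {
    if (is.null(truth$blocks[[read$chrom]]))
      stop("read ", read$id, " not on a chromosome known to the truth table")
    compose_alignment_(read, truth$blocks[[read$chrom]],
                       truth$ref_len[[read$chrom]], mapq)
  })
  paf <- do.call(rbind, c(list(paf_frame()), rows))
  if (nrow(paf)) {
    # primary = best record per read
    o <- order(paf$qname, -paf$nmatch, paf$tstart)
    prim <- paf[o, ][!duplicated(paf$qname[o]), ]
    key <- paste(paf$qname, paf$tstart, paf$qstart)
    paf$tp <- ifelse(key %in% paste(prim$qname, prim$tstart, prim$qstart), "P", "S")
  }
  rownames(paf) <- NULL
  paf
}

# Core liftover walk: compose the read<->mutated-genome alignment runs with
# the mutated<->reference block map. Splits into a new record wherever the
# reference coordinate jumps backwards (tandem-duplication junction).
compose_alignment_ <- function(read, blocks, tlen, mapq) {
  mblocks <- blocks[blocks$mut_end > blocks$mut_start, , drop = FALSE]
  qlen <- nchar(read$seq)
  mut <- read$mut_start
  q <- 0L
  bi <- findInterval(mut, mblocks$mut_start)
  ops_len <- integer(0); ops_op <- character(0)
  cur_qstart <- NA_integer_; cur_first_ref <- NA_integer_
  record_open <- FALSE
  last_ref <- NA_integer_
  records <- list()

  emit <- function(op, len) {
    ops_len[length(ops_len) + 1L] <<- len
    ops_op[length(ops_op) + 1L] <<- op
  }
  close_record <- function() {
    if (record_open) {
      rec <- trim_record_(ops_len, ops_op, cur_qstart, cur_first_ref)
      if (!is.null(rec)) {
        rec$qname <- read$id; rec$qlen <- qlen
        rec$tname <- read$chrom; rec$tlen <- tlen; rec$mapq <- mapq
        records[[length(records) + 1L]] <<- rec
      }
    }
    ops_len <<- integer(0); ops_op <<- character(0)
    cur_qstart <<- NA_integer_; cur_first_ref <<- NA_integer_
    record_open <<- FALSE; last_ref <<- NA_integer_
  }

  for (k in seq_len(nrow(read$ops))) {
    op <- read$ops$op[k]; len <- read$ops$len[k]
    if (op == "I") {
      if (record_open) emit("I", len)
      q <- q + len
      next
    }
    while (len > 0L) {
      b <- mblocks[bi, ]
      t <- min(len, b$mut_end - mut)
      if (b$type == "ins") {
        if (op != "D") { # = or X: read bases over inserted sequence
          if (record_open) emit("I", t)
          q <- q + t
        }
      } else {
        r0 <- b$ref_start + (mut - b$mut_start)
        if (record_open && !is.na(last_ref)) {
          if (r0 < last_ref) close_record()
          else if (r0 > last_ref) emit("D", r0 - last_ref)
        }
        if (!record_open) {
          cur_qstart <- q; cur_first_ref <- r0; record_open <- TRUE
        }
        emit(op, t)
        if (op != "D") q <- q + t
        last_ref <- r0 + t
      }
      mut <- mut + t
      len <- len - t
      if (mut == b$mut_end && bi < nrow(mblocks)) bi <- bi + 1L
    }
  }
  close_record()
  do.call(rbind, c(list(paf_frame()), records))
}

# Trim leading/trailing I and D runs, then assemble one PAF row.
trim_record_ <- function(lens, opsv, qstart, first_ref) {
  while (length(opsv) && opsv[1] %in% c("I", "D")) {
    if (opsv[1] == "I") qstart <- qstart + lens[1]
    else first_ref <- first_ref + lens[1]
    lens <- lens[-1]; opsv <- opsv[-1]
  }
  while (length(opsv) && opsv[length(opsv)] %in% c("I", "D")) {
    lens <- lens[-length(lens)]; opsv <- opsv[-length(opsv)]
  }
  if (!length(opsv)) return(NULL)
  ops <- data.frame(len = lens, op = opsv, stringsAsFactors = FALSE)
  qspan <- cigar_query_span(ops)
  tspan <- cigar_ref_span(ops)
  data.frame(qname = NA_character_, qlen = NA_integer_, qstart = qstart,
             qend = qstart + qspan, strand = "+", tname = NA_character_,
             tlen = NA_integer_, tstart = first_ref, tend = first_ref + tspan,
             nmatch = sum(ops$len[ops$op == "="]), alnlen = sum(ops$len),
             mapq = NA_integer_, cigar = cigar_string(ops), tp = "P",
             stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ / a genome as FASTA / truth as TSV
#'
#' Plain deterministic writers so identical seeds give byte-identical
#' files.
#'
#' @param reads List of `sim_read` or `rca_read` objects.
#' @param genome Named character vector of sequences.
#' @param truth A `truth_table`.
#' @param path Output file.
#' @name sim-io
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- unlist(lapply(reads, function(r)
    c(paste0("@", r$id), r$seq, "+", strrep("I", nchar(r$seq)))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sim-io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname sim-io
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth$variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
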