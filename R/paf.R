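# PAF records are held as a plain data.frame with the 12 mandatory columns
# plus `cigar` (the cg:Z: tag) and `tp` (primary/supplementary). All
# coordinates are 0-based half-open, as in the format itself.

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "nmatch", "alnlen", "mapq", "cigar", "tp")

#' Construct an empty PAF table
#' @return A zero-row data.frame with the PAF columns used by this package.
#' @export
paf_frame <- function() {
  data.frame(qname = character(), qlen = integer(), qstart = integer(),
             qend = integer(), strand = character(), tname = character(),
             tlen = integer(), tstart = integer(), tend = integer(),
             nmatch = integer(), alnlen = integer(), mapq = integer(),
             cigar = character(), tp = character(),
             stringsAsFactors = FALSE)
}

#' Parse a CIGAR string into run-length operations
#'
#' @param cigar CIGAR string over `M I D N S H P = X`.
#' @return data.frame with integer `len` and character `op`.
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    return(data.frame(len = integer(), op = character()))
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  parts <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", parts)),
             op = sub("^\\d+", "", parts), stringsAsFactors = FALSE)
}

#' Collapse run-length operations into a CIGAR string
#' @param ops data.frame with `len` and `op` columns.
#' @return A CIGAR string with adjacent identical operations merged.
#' @export
cigar_string <- function(ops) {
  ops <- merge_ops(ops)
  if (!nrow(ops)) return("")
  paste0(ops$len, ops$op, collapse = "")
}

# Merge adjacent runs of the same op and drop zero-length runs.
merge_ops <- function(ops) {
  ops <- ops[ops$len > 0L, , drop = FALSE]
  if (nrow(ops) < 2L) return(ops)
  grp <- cumsum(c(TRUE, ops$op[-1L] != ops$op[-nrow(ops)]))
  data.frame(len = as.integer(tapply(ops$len, grp, sum)),
             op = ops$op[!duplicated(grp)], stringsAsFactors = FALSE)
}

QUERY_OPS <- c("M", "=", "X", "I", "S")
REF_OPS <- c("M", "=", "X", "D", "N")

cigar_query_span <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])

#' Validate PAF records against coordinate and CIGAR-length invariants
#'
#' Checks `0 <= qstart < qend <= qlen`, `0 <= tstart < tend <= tlen`, and
#' that query-consuming CIGAR operations sum to `qend - qstart` and
#' reference-consuming operations to `tend - tstart`.
#'
#' @param paf PAF data.frame.
#' @return Invisibly `TRUE`; otherwise an error naming the first bad record.
#' @export
validate_paf <- function(paf) {
  for (i in seq_len(nrow(paf))) {
    r <- paf[i, ]
    ok <- r$qstart >= 0 && r$qstart < r$qend && r$qend <= r$qlen &&
      r$tstart >= 0 && r$tstart < r$tend && r$tend <= r$tlen
    if (!ok) stop("PAF coordinate invariant violated for read ", r$qname)
    ops <- cigar_ops(r$cigar)
    clip <- sum(ops$len[ops$op %in% c("S", "H")])
    if (cigar_query_span(ops) != r$qend - r$qstart)
      stop("CIGAR query span != qend-qstart for read ", r$qname)
    if (cigar_ref_span(ops) != r$tend - r$tstart)
      stop("CIGAR reference span != tend-tstart for read ", r$qname)
    if (clip > 0) stop("clipped ops inside cg tag for read ", r$qname)
  }
  invisible(TRUE)
}

#' Write alignments as PAF with cg:Z: and tp:A: tags
#' @param paf PAF data.frame.
#' @param path Output file.
#' @export
write_paf <- function(paf, path) {
  lines <- vapply(seq_len(nrow(paf)), function(i) {
    r <- paf[i, ]
    paste(r$qname, r$qlen, r$qstart, r$qend, r$strand, r$tname, r$tlen,
          r$tstart, r$tend, r$nmatch, r$alnlen, r$mapq,
          paste0("tp:A:", r$tp), paste0("cg:Z:", r$cigar), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAF file (keeping cg:Z: and tp:A: tags)
#' @param path PAF file path.
#' @return PAF data.frame.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  out <- paf_frame()
  if (!length(lines)) return(out)
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    tags <- f[-seq_len(12)]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE)[1])
    tp <- sub("^tp:A:", "", grep("^tp:A:", tags, value = TRUE)[1])
    data.frame(qname = f[1], qlen = as.integer(f[2]), qstart = as.integer(f[3]),
               qend = as.integer(f[4]), strand = f[5], tname = f[6],
               tlen = as.integer(f[7]), tstart = as.integer(f[8]),
               tend = as.integer(f[9]), nmatch = as.integer(f[10]),
               alnlen = as.integer(f[11]), mapq = as.integer(f[12]),
               cigar = if (is.na(cg)) "" else cg,
               tp = if (is.na(tp)) "P" else tp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# One best record per read: highest nmatch, ties broken by lowest target
# name then lowest target start, so deduplication is deterministic.
dedup_best <- function(paf) {
  if (!nrow(paf)) return(paf)
  o <- order(paf$qname, -paf$nmatch, paf$tname, paf$tstart)
  paf <- paf[o, , drop = FALSE]
  paf[!duplicated(paf$qname), , drop = FALSE]
}
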