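# Per-TE-family quantification of eccDNA evidence from mobilome-seq
# alignments: artifact filtering, unique-read counting, RPM/FPKM
# normalization and mutant-vs-control enrichment.

paf_best_granges_ <- function(paf) {
  best <- dedup_best(paf)
  GenomicRanges::GRanges(best$tname,
                         IRanges::IRanges(best$tstart + 1L, best$tend),
                         qname = best$qname)
}

#' Remove reads whose best alignment falls in artifact intervals
#'
#' Mobilome libraries carry circles from organelle-homologous nuclear
#' insertions (NUPT/NUMT), rDNA repeats and centromeric repeats; reads
#' whose best alignment overlaps such an interval by at least
#' `min_overlap_frac` of its aligned length are removed. Removal reasons
#' are logged per artifact class in the `removed` attribute.
#'
#' @param paf Alignments (PAF data.frame).
#' @param artifacts `GRanges` with a `name` (or `class`) column labelling
#'   each interval's artifact class, e.g. from a BED file via
#'   `rtracklayer::import`. Required unless `allow_missing = TRUE`.
#' @param min_overlap_frac Overlap fraction of the aligned length above
#'   which the read is removed.
#' @param allow_missing Explicit opt-out: skip filtering when no
#'   annotation is supplied.
#' @return The retained alignment records (all records of retained reads),
#'   with attribute `removed` (data.frame qname, reason).
#' @export
filter_artifact_reads <- function(paf, artifacts = NULL,
                                  min_overlap_frac = 0.5,
                                  allow_missing = FALSE) {
  if (is.null(artifacts)) {
    if (!allow_missing)
      stop("artifact annotation missing; pass allow_missing = TRUE to skip")
    attr(paf, "removed") <- data.frame(qname = character(),
                                       reason = character())
    return(paf)
  }
  if (length(artifacts) == 0L) {
    attr(paf, "removed") <- data.frame(qname = character(),
                                       reason = character())
    return(paf)
  }
  cls <- if (!is.null(artifacts$name)) artifacts$name else artifacts$class
  if (is.null(cls)) stop("artifact annotation needs a name/class column")
  gr <- paf_best_granges_(paf)
  hits <- GenomicRanges::findOverlaps(gr, artifacts)
  removed <- data.frame(qname = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(artifacts)[S4Vectors::subjectHits(hits)]))
    frac <- ov / IRanges::width(gr)[S4Vectors::queryHits(hits)]
    bad <- frac >= min_overlap_frac
    if (any(bad)) {
      df <- data.frame(qname = gr$qname[S4Vectors::queryHits(hits)[bad]],
                       reason = cls[S4Vectors::subjectHits(hits)[bad]],
                       frac = frac[bad], stringsAsFactors = FALSE)
      df <- df[order(df$qname, -df$frac), ]
      removed <- df[!duplicated(df$qname), c("qname", "reason")]
    }
  }
  out <- paf[!(paf$qname %in% removed$qname), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Count unique reads per TE family
#'
#' Alignments are deduplicated to one best record per read (highest
#' matches; ties broken by lowest target coordinate), then each read is
#' assigned to every family whose annotation it overlaps by at least 1 bp.
#'
#' @param paf Alignments (PAF data.frame).
#' @param te_annotation `GRanges` with a `family` metadata column (or
#'   `name` from BED). Unlabeled rows are an error.
#' @param library_mapped_reads Library size; defaults to the number of
#'   distinct read ids in `paf`.
#' @return data.frame (one row per family): family, unique_read_count,
#'   feature_length_kb, library_mapped_reads.
#' @export
count_unique_reads_per_family <- function(paf, te_annotation,
                                          library_mapped_reads = NULL) {
  fam <- if (!is.null(te_annotation$family)) te_annotation$family
         else te_annotation$name
  if (is.null(fam) || any(is.na(fam)) || any(fam == ""))
    stop("te_annotation rows must all carry a family label")
  if (is.null(library_mapped_reads))
    library_mapped_reads <- length(unique(paf$qname))
  gr <- paf_best_granges_(paf)
  hits <- GenomicRanges::findOverlaps(gr, te_annotation, minoverlap = 1L)
  assign <- unique(data.frame(
    qname = gr$qname[S4Vectors::queryHits(hits)],
    family = fam[S4Vectors::subjectHits(hits)], stringsAsFactors = FALSE))
  fams <- sort(unique(fam))
  cnt <- table(factor(assign$family, levels = fams))
  flen <- tapply(IRanges::width(te_annotation), fam, sum) / 1000
  data.frame(family = fams, unique_read_count = as.integer(cnt[fams]),
             feature_length_kb = as.numeric(flen[fams]),
             library_mapped_reads = library_mapped_reads,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize family counts (RPM or FPKM)
#'
#' RPM = count * 1e6 / library size; FPKM = count * 1e9 /
#' (feature length in bp * library size).
#'
#' @param counts data.frame from [count_unique_reads_per_family()].
#' @param mode `"RPM"` or `"FPKM"`.
#' @return `counts` with an added `norm` column (and `mode` attribute).
#' @export
normalize_counts <- function(counts, mode = c("RPM", "FPKM")) {
  mode <- match.arg(mode)
  if (any(counts$library_mapped_reads <= 0)) stop("zero library size")
  counts$norm <- if (mode == "RPM") {
    counts$unique_read_count * 1e6 / counts$library_mapped_reads
  } else {
    counts$unique_read_count * 1e9 /
      (counts$feature_length_kb * 1000 * counts$library_mapped_reads)
  }
  attr(counts, "mode") <- mode
  counts
}

#' Compare normalized family abundance against a control
#'
#' Per family and sample, ratio = (norm_sample + c) / (norm_control + c)
#' with pseudocount `c`, plus log2 ratio. Families enriched
#' (log2 >= `log2_threshold`) in ALL samples (i.e. every replicate of a
#' genotype) are flagged.
#'
#' @param samples Named list of normalized tables ([normalize_counts()]).
#' @param control Normalized control table.
#' @param pseudocount Pseudocount on the normalized scale (default 1).
#' @param log2_threshold Enrichment threshold on the log2 ratio.
#' @return data.frame: family, control norm, per-sample norm / ratio /
#'   log2 columns, `enriched_all` flag.
#' @export
enrichment_vs_control <- function(samples, control, pseudocount = 1,
                                  log2_threshold = 1) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  fams <- control$family
  for (nm in names(samples)) {
    if (!setequal(samples[[nm]]$family, fams))
      stop("family sets differ for sample ", nm, ": ",
           paste(union(setdiff(samples[[nm]]$family, fams),
                       setdiff(fams, samples[[nm]]$family)), collapse = ", "))
  }
  out <- data.frame(family = fams, control = control$norm,
                    stringsAsFactors = FALSE)
  enr <- matrix(FALSE, nrow = length(fams), ncol = length(samples))
  for (i in seq_along(samples)) {
    nm <- names(samples)[i]
    s <- samples[[i]][match(fams, samples[[i]]$family), ]
    ratio <- (s$norm + pseudocount) / (control$norm + pseudocount)
    out[[paste0(nm, "_norm")]] <- s$norm
    out[[paste0(nm, "_ratio")]] <- ratio
    out[[paste0(nm, "_log2")]] <- log2(ratio)
    enr[, i] <- log2(ratio) >= log2_threshold
  }
  out$enriched_all <- rowSums(enr) == length(samples)
  out
}
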