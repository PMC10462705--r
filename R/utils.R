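BASES <- c("A", "C", "G", "T")

#' Evaluate code under a fixed RNG seed, restoring the previous RNG state
#'
#' All stochastic steps in the simulator funnel through this helper so that
#' identical seeds give byte-identical output without disturbing the
#' caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random DNA sequence
#'
#' @param n Length in bases.
#' @param seed Optional integer seed.
#' @return A single character string over A/C/G/T.
#' @export
random_dna <- function(n, seed = NULL) {
  with_seed(seed, paste(sample(BASES, n, replace = TRUE), collapse = ""))
}

# Proportion of identical positions between two equal-length strings.
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(NA_real_)
  mean(utf8ToInt(a) == utf8ToInt(b))
}

# All k-mers of x as a character vector (empty if x shorter than k).
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  i <- seq_len(n - k + 1L)
  substring(x, i, i + k - 1L)
}

#' Per-base coverage of a subject sequence by exact shared k-mers
#'
#' Marks every subject position lying inside at least one k-mer that also
#' occurs (exactly) in the query. This is the segmentation primitive used
#' for domain-presence and chimeric-segment calls: requiring 80% exact
#' 15-mer coverage is a strictly stronger condition than 80% alignment
#' coverage at 80% identity, and is robust once a consensus monomer has
#' been polished by majority voting.
#'
#' @param subject,query Character strings (DNA).
#' @param k K-mer size (default 15).
#' @return Logical vector of length `nchar(subject)`.
#' @export
kmer_cover <- function(subject, query, k = 15L) {
  ls <- nchar(subject)
  sk <- seq_kmers(subject, k)
  qk <- seq_kmers(query, k)
  cov <- logical(ls)
  if (!length(sk) || !length(qk)) return(cov)
  hit <- which(sk %in% qk)
  if (!length(hit)) return(cov)
  d <- tabulate(hit, nbins = ls + 1L) - tabulate(hit + k, nbins = ls + 1L)
  cumsum(d)[seq_len(ls)] > 0L
}

# First-occurrence subject positions (0-based) of each query k-mer;
# returns data.frame(qpos, spos) for matched k-mers only.
kmer_match_positions <- function(query, subject, k = 15L) {
  qk <- seq_kmers(query, k)
  sk <- seq_kmers(subject, k)
  m <- match(qk, sk)
  keep <- !is.na(m)
  data.frame(qpos = which(keep) - 1L, spos = m[keep] - 1L)
}

# Runs of FALSE in a logical vector, as 0-based half-open intervals.
uncovered_runs <- function(cov) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[!r$values], end = ends[!r$values])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
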