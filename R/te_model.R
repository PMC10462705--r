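# A TE model is the consensus sequence of an LTR retrotransposon together
# with an ordered domain layout (LTR5, GAG, AP, IN, RT, RH, LTR3) given as
# 0-based half-open coordinates on that sequence.

TE_DOMAINS <- c("LTR5", "GAG", "AP", "IN", "RT", "RH", "LTR3")

# Internal (between-LTR) domain proportions used when no domain table is
# supplied; loosely Ty1/Copia-like (GAG largest, then IN, RT, AP, RH).
INTERNAL_PROPS <- c(GAG = 0.28, AP = 0.12, IN = 0.27, RT = 0.22, RH = 0.11)

#' Construct a TE consensus model
#'
#' @param name Element name.
#' @param sequence Consensus DNA string.
#' @param domains data.frame with columns `label`, `start`, `end` (0-based
#'   half-open, sorted, non-overlapping, within the sequence). Labels must
#'   come from `LTR5, GAG, AP, IN, RT, RH, LTR3`.
#' @param ltr_identity Optional precomputed LTR5/LTR3 identity; computed
#'   from the sequence when missing.
#' @return An object of class `te_model`.
#' @export
te_model <- function(name, sequence, domains, ltr_identity = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  domains <- domains[, c("label", "start", "end")]
  if (!all(domains$label %in% TE_DOMAINS))
    stop("unknown domain labels: ",
         paste(setdiff(domains$label, TE_DOMAINS), collapse = ", "))
  if (is.unsorted(domains$start, strictly = TRUE))
    stop("domains must be sorted by start")
  if (any(domains$start < 0) || any(domains$end > nchar(sequence)) ||
      any(domains$end <= domains$start))
    stop("domain coordinates outside [0, sequence length)")
  if (any(domains$start[-1L] < domains$end[-nrow(domains)]))
    stop("domains overlap")
  if (is.null(ltr_identity) && all(c("LTR5", "LTR3") %in% domains$label)) {
    l5 <- domain_seq_(sequence, domains, "LTR5")
    l3 <- domain_seq_(sequence, domains, "LTR3")
    ltr_identity <- if (nchar(l5) == nchar(l3)) hamming_identity(l5, l3)
      else {
        al <- banded_edit_align(l5, l3, band = max(10L, abs(nchar(l5) - nchar(l3)) + 10L))
        al$matches / al$alnlen
      }
    if (ltr_identity < 0.95)
      stop("LTR5/LTR3 identity ", round(ltr_identity, 3), " below 0.95")
  }
  structure(list(name = name, sequence = sequence, domains = domains,
                 ltr_identity = ltr_identity),
            class = "te_model")
}

domain_seq_ <- function(sequence, domains, label) {
  d <- domains[domains$label == label, ]
  substr(sequence, d$start + 1L, d$end)
}

#' Extract the span or sequence of a model domain
#' @param model A `te_model`.
#' @param label Domain label.
#' @return `domain_span`: integer `c(start, end)` (0-based half-open);
#'   `domain_seq`: the domain sequence.
#' @export
domain_span <- function(model, label) {
  d <- model$domains[model$domains$label == label, ]
  if (!nrow(d)) stop("no domain ", label, " in model ", model$name)
  c(d$start, d$end)
}

#' @rdname domain_span
#' @export
domain_seq <- function(model, label) domain_seq_(model$sequence, model$domains, label)

#' @export
print.te_model <- function(x, ...) {
  cat("TE model", x$name, "-", nchar(x$sequence), "bp, LTR identity",
      round(x$ltr_identity, 3), "\n")
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' Build a TE model from a raw sequence by locating its terminal repeats
#'
#' Terminal repeats are found by exact-match seed extension: short seeds
#' from the 5' prefix are searched in the 3' half of the sequence; each hit
#' implies a candidate LTR length, which is verified by comparing the full
#' 5' prefix window against the 3' suffix window. The longest candidate of
#' at least `ltr_min_len` bases with >= 90% identity wins. Internal domains
#' come from `domain_table` when supplied, otherwise the inter-LTR region
#' is partitioned proportionally (GAG 28%, AP 12%, IN 27%, RT 22%, RH 11%).
#'
#' @param sequence DNA string (length >= 2 * `ltr_min_len`).
#' @param ltr_min_len Minimum LTR length in bp.
#' @param domain_table Optional data.frame (`label`, `start`, `end`) for the
#'   internal domains.
#' @param name Model name.
#' @return A `te_model`.
#' @export
build_te_model <- function(sequence, ltr_min_len = 100L, domain_table = NULL,
                           name = "TE") {
  n <- nchar(sequence)
  if (n < 2L * ltr_min_len) stop("sequence shorter than 2 x ltr_min_len")
  seed_len <- 20L
  best <- NULL
  for (off in seq(0L, ltr_min_len - seed_len, by = 7L)) {
    seed <- substr(sequence, off + 1L, off + seed_len)
    m <- gregexpr(seed, sequence, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (q0 in as.integer(m) - 1L) {
      if (q0 <= n %/% 2L || q0 == off) next
      L <- n - (q0 - off)
      if (L < ltr_min_len || L > n %/% 2L) next
      ident <- hamming_identity(substr(sequence, 1L, L),
                                substr(sequence, n - L + 1L, n))
      if (ident >= 0.90 && (is.null(best) || L > best$L))
        best <- list(L = L, identity = ident)
    }
  }
  if (is.null(best)) stop("no LTR found")
  L <- best$L
  if (is.null(domain_table)) {
    inner <- n - 2L * L
    bounds <- L + c(0L, round(cumsum(INTERNAL_PROPS) * inner))
    domain_table <- data.frame(label = names(INTERNAL_PROPS),
                               start = bounds[-length(bounds)],
                               end = bounds[-1L])
  }
  domains <- rbind(data.frame(label = "LTR5", start = 0L, end = L),
                   domain_table,
                   data.frame(label = "LTR3", start = n - L, end = n))
  te_model(name, sequence, domains, ltr_identity = best$identity)
}

#' Generate a synthetic LTR-retrotransposon model
#'
#' Random element with identical 5'/3' LTRs flanking a random internal
#' region carved into GAG/AP/IN/RT/RH. Defaults mimic a ~5.3 kb Ty1/Copia
#' element with ~400 bp LTRs.
#'
#' @param seed Integer seed.
#' @param ltr_len,internal_len LTR and internal lengths (bp).
#' @param name Model name.
#' @return A `te_model`.
#' @export
synthetic_te_model <- function(seed = 1L, ltr_len = 400L, internal_len = 4500L,
                               name = "synthTE") {
  with_seed(seed, {
    ltr <- random_dna(ltr_len)
    internal <- random_dna(internal_len)
    seqn <- paste0(ltr, internal, ltr)
    n <- nchar(seqn)
    bounds <- ltr_len + c(0L, round(cumsum(INTERNAL_PROPS) * internal_len))
    domains <- rbind(
      data.frame(label = "LTR5", start = 0L, end = ltr_len),
      data.frame(label = names(INTERNAL_PROPS),
                 start = bounds[-length(bounds)], end = bounds[-1L]),
      data.frame(label = "LTR3", start = n - ltr_len, end = n))
    te_model(name, seqn, domains)
  })
}
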