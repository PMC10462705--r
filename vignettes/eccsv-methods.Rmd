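---
title: "Methods: circle decomposition, insertion calling and SV detection in eccsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circle decomposition, insertion calling and SV detection in eccsv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccsv)
```

## The biological setting

When the epigenetic control of transposable elements (TEs) breaks down —
as in *Arabidopsis* mutants of DNA methylation and post-transcriptional
silencing — reactivated elements produce abundant extrachromosomal
circular DNA (eccDNA) and leave structural marks in the genome: new
insertions flanked by target-site duplications (TSDs), internally
truncated and chimeric elements, tandem duplications and small
deletions. Mobilome sequencing enriches the circular compartment and
amplifies it by rolling-circle amplification (RCA), so a single long
read contains many tandem copies (monomers) of one circle; long-read
genome resequencing captures insertions and deletions inside individual
read alignments rather than at alignment breakpoints.

`eccsv` implements the computational side of such a study as a reusable,
tested pipeline over four analysis stages plus a simulator:

* **synthsim** — synthetic references, implanted variants, circle
  templates, RCA concatemer reads, genomic spanning reads, and
  ground-truth PAF alignments;
* **circlestruct** — monomer decomposition of concatemer reads and
  structural classification of circles;
* **inscall** — CIGAR-walking insertion calling with support clustering
  and TSD validation;
* **svcall** — split-read tandem duplications, small deletions, control
  subtraction and depth profiles;
* **eccquant** — per-TE-family quantification of eccDNA evidence.

All coordinates are 0-based half-open internally and in BED/PAF output;
1-based coordinates appear only in human-readable region strings.

## The simulator defines the study conditions

The generator is first-class, tested code: every caller in the package
is validated against its ground truth. Design choices:

* **Error model.** Independent per-base substitution / insertion /
  deletion errors with defaults 0.03 / 0.015 / 0.015 — a long-read-like
  ~6% total error. Rates are capped at 0.2 each. Homopolymer-aware error
  structure is deliberately out of scope; this matters when interpreting
  the tests (below).
* **TSD construction.** An insertion at position *p* with `tsd_len = t`
  inserts the payload followed by a copy of the *t* reference bases
  preceding *p*, so the site is flanked by identical TSD copies. The
  package asserts this invariant across random configurations.
* **Truth alignments.** For each simulated read the alignment against
  the *reference* implied by the implant record is constructed directly:
  insertions appear as an `I` operation carrying payload plus one TSD
  copy, deletions as `D`, and a tandem-duplication junction as two
  records whose reference intervals overlap. Sequencing errors are
  carried through as `X`/`I`/`D` operations, so CIGAR length
  conservation holds exactly and is asserted on all simulated records.
  Using truth alignments as the default test path keeps the suite free
  of an external aligner; running one instead is an untested
  convenience.
* **Read placement and phase.** Spanning reads place uniformly subject
  to covering the locus with at least 1 kb of flank where the chromosome
  allows; RCA reads start at a uniformly drawn phase on the circle
  unless fixed. The RCA read length has no canonical distribution, so it
  is an explicit parameter rather than an assumption.
* **Determinism.** Every stochastic step funnels through a single
  seed-scoped helper; identical seeds give byte-identical
  FASTA/FASTQ/PAF/TSV output (tested).
* **Strand.** Simulated reads are forward-strand only. All callers are
  strand-agnostic except the duplication caller's same-strand
  requirement, which is still exercised; reverse-strand truth alignment
  emission is a known limitation of the generator, not of the callers.

## Monomer decomposition

**Period detection.** All offsets between repeated exact 15-mers along
the read are collected, clustered (offsets jitter under indel errors;
the linking tolerance is `max(3, 1%)` of the offset), and the modal
offset is taken after collapsing multiples: an offset near an integer
multiple `m * p` votes for `p`, so harmonics reinforce the fundamental
rather than competing with it. A period needs at least 5 supporting
k-mer pairs; short (< 2x the 200 bp minimum period) or non-repetitive
reads report no period. For a full-length element with two identical
LTRs the LTR-to-LTR offsets form minority clusters that cannot outvote
the whole-monomer offset carried by every unique internal k-mer. The
estimate agrees with a brute-force best-Hamming-shift oracle on
error-free reads (tested) and stays within 2% of truth at simulated
error rates.

**Decomposition.** The read is cut into consecutive period-length
windows; the first full window seeds the consensus and the others are
aligned to it with a banded global edit alignment (band = 10% of the
period, unit costs, deterministic tie-breaking: diagonal, then gap in
the window, then gap in the seed). A window counts as a complete copy at
>= 80% end-to-end identity. The consensus is a column-majority vote over
the seed's coordinates with *insertion recovery*: where a majority of
windows carry the same base(s) inserted relative to the seed — i.e. the
seed copy lost a base to a sequencing deletion — those bases are
restored. Without insertion recovery the consensus is systematically
short by about the deletion rate; with it, consensus error is well below
1% at 5% read error (tested).

**Classification.** The consensus is compared to the TE model by exact
shared 15-mers, with the consensus doubled so circular rotation cannot
split a match (classification is rotation invariant, tested). A domain
is PRESENT when >= 80% of its model span lies under shared k-mers. Exact
15-mer coverage at 80% is a strictly stronger condition than the more
conventional "80% of the span aligned at 80% identity"; it is fast
enough for the property suites and appropriate here because the
classified sequence is a voted consensus whose residual error is far
below raw read error. The label logic mirrors the observed circle
categories:

* all domains present, monomer length within half an LTR of the full
  element -> `FULL_2LTR`; all present but only one LTR unit fits the
  length -> `FULL_1LTR` (with identical LTRs a one-LTR circle still
  covers both LTR spans, so the length decides);
* GAG, AP, IN absent, rest present -> `NO_GAG`;
* IN, RT absent -> `NO_IN_RT`;
* LTR, GAG, AP absent -> `NO_LTR`;
* any unmatched consensus segment of >= 100 bp that maps to the genome
  (>= 80% k-mer coverage) -> `CHIMERIC`;
* anything else with some model match -> `OTHER_TRUNCATED`; no match to
  model or genome -> `unclassified`.

Observed categories tie circle calls to per-read copy counts ("more than
2" full-length copies, "more than 5" truncated, "3" for LTR-less
circles); since it is unstated whether those counts are definitions or
properties of the examples shown, `classify_reads()` exposes a single
configurable `min_copies` threshold (default 1) rather than hard-coding
per-class minima.

**Chimeric circle calls.** CHIMERIC reads are grouped by junction with
both breakends within ±20 bp; groups supported by >= 5 distinct reads
are retained. Junction anchors must be independent of each read's
rotation phase, so the TE-side anchor is the end of the first covered
run on the model and the genome-side anchor is the left edge of the
partner's matched interval. "Distinct loci" means different chromosomes
or > 50 kb apart; the ±20 bp tolerance and the 50 kb rule are package
choices (no criterion is stated in the source material for either).
Breakpoint positions of truncated circles are written out as a histogram
table by the analysis drivers, but no formal uniformity test is claimed
for "no truncation hotspot"-style statements.

## Insertion calling

`walk_cigar()` scans each alignment's CIGAR, accumulating query and
reference cursors, and emits an INS for every `I` >= 50 bp (with the
inserted query substring when read sequence is available) and a DEL for
every such `D`. The 50 bp default targets TE-scale events; the
small-deletion path uses 20 bp. Evidence is grouped by single-linkage
clustering within a 10 bp window — raw long-read positions jitter, and
"the same position" is read as post-grouping identity, so the window is
configurable down to 0 — and clusters are kept only with support
*strictly greater than* 4 distinct reads (one read counts once per
cluster, so duplicated alignment records cannot inflate support).

**TSD detection** reconciles two detectors. The sequence method takes,
per member read, the longest exact terminal match (1-30 bp) between the
inserted sequence and the adjacent reference bases — the insert's suffix
against the bases 5' of the insertion point, and its prefix against the
bases 3' (the two equivalent placements of a TSD-bearing insertion) —
and summarizes members by the modal length, which is robust to
individual reads corrupting the TSD copy. The split-read method takes
the overlap between the reference end of alignments stopping at the site
and the reference start of alignments beginning there. When both fire
they must agree, else the call is flagged ambiguous. Calls pass the TSD
filter when 5 <= length <= 20, both bounds inclusive; boundary behaviour
(4 and 21 rejected, 5 and 20 kept) is unit-tested.

**Family and truncation typing.** The representative insert is a
majority-vote consensus of the member inserts (the longest member when
fewer than three carry sequence): raw long-read inserts carry too many
errors for exact k-mer matching, while a consensus across >= 5
supporting reads does not. The insert is tested forward and
reverse-complement against each model; the family covering the most of
the insert wins, requiring >= 60% insert coverage, with ties broken
lexicographically for determinism. Per-domain model coverage then gives
`truncated` and `missing_domains`. Insertion points are annotated
against gene features with priority 5'UTR/3'UTR > exon > intron, else
intergenic with the distance to the nearest gene (UTRs take precedence
over plain exon hits because GFF3 exons contain their UTRs — checking
exon first would make UTR targeting, a hallmark of some DNA-transposon
families, unreportable); with no annotation the caller warns and reports
intergenic-only.

## Structural variants

**Tandem duplications.** A read spanning the head-to-tail junction
splits into two same-chromosome, same-strand alignments whose query
intervals are adjacent (gap <= 100 bp) and whose reference intervals
overlap — the later query segment jumps back to the duplication start.
The call spans the second segment's reference start to the first
segment's reference end; candidates merge within 50 bp and the length
filter is strict (> 1 kb, so a 1000 bp duplication is rejected and a
1001 bp one kept). Note a geometric property of the overlap criterion:
the two reference intervals of a junction read overlap only when the
read is longer than the duplicated span, so simulated junction reads for
55-56 kb duplications are 60 kb. Support defaults to a single junction
read — such junctions are typically validated manually — and is
configurable upward.

**Small deletions** reuse the CIGAR walk at a 20 bp minimum and the
insertion pipeline's clustering (default support > 4; configurable,
e.g. for pooled samples where a heterozygous deletion halves expected
support). Call length is the median `D` length over members; because
structural `D` operations are exact in truth alignments while error
deletions only rarely abut the junction, the median is unbiased
(tested: a 13,300 bp deletion is recovered at exactly 13.3 kb from 15
reads at 5% error).

**Control subtraction** removes a mutant call when any same-kind control
call overlaps it by >= 1 bp on half-open intervals — abutting calls do
not overlap. `subtract_control(X, X)` is empty and
`subtract_control(X, empty)` is `X` (tested).

**Depth profiles** average per-base coverage of primary records in
fixed-width bins; in a simulated heterozygous duplication the interval
runs at ~1.5x flank depth (tested).

## eccDNA quantification

Reads whose best alignment (highest match count; ties broken by lowest
target name then coordinate, so deduplication is deterministic) overlaps
an rDNA / centromeric / organelle-homologous interval by >= 50% of its
aligned length are removed, with per-class reasons logged. The 50%
fraction is a package choice: the filtering step is described in the
source protocol without a numeric criterion. Skipping the filter
requires an explicit opt-out rather than silently proceeding without an
annotation.

Counting assigns each deduplicated read to every family it overlaps by
>= 1 bp. Two normalizations are provided because the protocol uses FPKM
in its methods yet reads-per-million in its figure legend; the
discrepancy is surfaced here rather than resolved:

* RPM = count x 1e6 / library size,
* FPKM = count x 1e9 / (feature length in bp x library size).

Enrichment against a control uses ratio = (norm + c) / (norm_control +
c) with pseudocount c = 1 RPM (a package choice; the source is silent),
reports log2 ratios, and flags families enriched (log2 >= 1, also
configurable) in *all* replicates of a genotype — the
replicate-consistency rule under which, in the motivating study, only
two of 318 families survived. On simulated mobilomes with two spiked
families, exactly those two are flagged (tested).

## Problem sizes and what the tests do (and do not) show

The property suites run at sizes chosen to exercise the estimators well
inside a few minutes on one CPU: round-trip class recovery uses 200
reads per class at 3% total error (0.02 / 0.005 / 0.005) with reads of
4 monomer lengths, requiring >= 95% recovery per class and 100% on
error-free reads; the composition-mixture check uses 300 reads at the
truncation spectrum 13 / 19 / 20 / 48%; oracle-equivalence suites use
~10-70 kb toy chromosomes. Passing them shows the algorithms are correct
under the stated error model; it does not certify performance on real
ONT data, whose errors cluster in homopolymers, whose chimeras arise in
library preparation as well as biology, and whose alignments come from a
real aligner with its own clipping and MAPQ behaviour. The acceptance
script (`scripts/acceptance.R`) reconstructs the headline per-event
numbers — the two large duplication widths to the nearest kb, the 9 bp
TSD at the printed target-site motif, and the 13.3 kb deletion — from
seeded synthetic data built from the printed coordinates.

## Known limitations

* No reverse-strand read simulation; no homopolymer-aware errors; no
  nested variants or polyploid genomes.
* General-purpose SV typing (inversions, translocations) is out of
  scope; complex "3-hit" reads (three split segments over >= 2 loci) are
  reported descriptively by `flag_multihit_reads()`, not typed.
* Domain presence via exact k-mer coverage assumes a polished consensus;
  single-copy, high-error monomers may under-report domains and fall
  back to `unclassified` rather than guessing.
* With identical LTRs, the TE-side breakend of a chimera is inherently
  ambiguous between the two LTR copies; junction anchors are chosen for
  stability, not to resolve that ambiguity.
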