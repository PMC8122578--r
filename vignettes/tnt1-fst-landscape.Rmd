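---
title: "Mapping a Tnt1 insertion landscape from flanking sequence tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a Tnt1 insertion landscape from flanking sequence tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnt1fst)
```

## The problem

Tnt1, a tobacco LTR retrotransposon, is the workhorse insertional
mutagen in *Medicago truncatula* cv. R108. Each mutant line carries a
few dozen independent Tnt1 copies, and the insertion point of each copy
is recovered as a *flanking sequence tag* (FST): a TAIL-PCR amplicon
read that runs from inside the Tnt1 LTR into the adjacent host genome.
Locating hundreds of thousands of FSTs on a chromosome-scale assembly
turns a mutant collection into a searchable reverse-genetics resource:
for any gene, which lines carry an insertion in it?

`tnt1fst` implements that pipeline end to end — signature-based FST
quality control, insertion-site mapping with a self-contained
seed-and-extend local aligner, and the downstream landscape statistics
(per-chromosome tables, per-gene tallies, fixed-width bins with GC
content, synteny-block tallies, assembly partition statistics) — plus a
synthetic data generator that stands in for the real, non-desk-scale
FST collection.

## Quality control: the signature rules

A genuine FST must contain one of the three Tnt1 end motifs
(`CCCAACA`, `CATCATCA`, `TGATGATGTCC`) near one of its ends, because
TAIL-PCR is primed inside the LTR. Reads are therefore rejected, in
fixed precedence, when they are

1. shorter than `min_fst_length` (50 bp) — too short to map reliably
   (`TOO_SHORT`);
2. free of any motif — typically arbitrary-degenerate (AD) primer
   artefacts (`NO_SIGNATURE`);
3. carrying motifs only in the read interior, more than `end_window`
   (28 bp) from both ends — inconsistent with an LTR-terminal junction
   (`SIGNATURE_INTERNAL`).

The 28-bp window is interpreted inclusively: a motif *starting* at
0-based offset ≤ 27 is head-proximal, one *ending* within the last 28
bases is tail-proximal. Both boundary and comparator are configurable
(`end_window`), since the verbal rule ("outside the 28 bp … discarded")
does not pin down whether the window bounds the motif's first or last
base; we bound the motif edge nearest its read end.

Two further decisions matter in corner cases:

* **Reverse-complement search is on by default.** TAIL-PCR read
  orientation is not guaranteed, so each motif and its reverse
  complement are searched (`search_reverse_complement`). Occurrence
  search uses zero-width lookahead so overlapping tandem occurrences
  (e.g. `TGATGATGATG…`) are all reported.
* **Best-match selection.** When several end-proximal occurrences
  exist, the one closest to *its own* read end wins; ties prefer the
  head, then the longer motif. The motif-length tie-break exists
  because `revcomp(CATCATCA) = TGATGATG` is a prefix of
  `TGATGATGTCC`: at a shared end the full-length signature must define
  the junction, otherwise every call through the nested motif would be
  3 bp off.

## Mapping and the insertion-site call

High-confidence FSTs are near-identical to their source locus, so the
aligner is deliberately minimal: exact k-mer seeds (k = 15) from a
keyed index of the reference, merged per (chromosome, diagonal), then
ungapped extension in both directions under an x-drop rule
(`x_drop = 20`), scored +1/−2. Hits are reported when identity
(matches / alignment columns, the BLAST convention) is at least 90%
and the Karlin–Altschul E-value `E = K·m·n·exp(−λS)` is at most
1 × 10⁻⁵; `λ` is solved by bisection from the score distribution and
`K` by the lattice-case convolution series (the computed pair for
+1/−2 at uniform base frequencies, λ ≈ 1.33 and K ≈ 0.62, matches the
published ungapped BLASTN constants). Among threshold-passing hits the
best hit maximizes score, with ties broken by E-value, alignment
length, chromosome name, and reference start. No gapped extension is
provided: under a 90% identity filter on reads of ~363 bp, indels that
matter are rare enough that a gapped mode would add an untested code
path without changing any downstream count.

The insertion coordinate is the transposon/genome junction: the read
base immediately flanking the signature motif, projected through the
best hit's diagonal onto the reference (head signature → toward
`read_start`, tail → toward `read_end`, flipped on minus-strand hits).
The projection is extrapolated along the diagonal when the junction
base itself fell just outside the aligned segment — a substitution
error on the first flank base otherwise trims the alignment edge and
shifts the call by one for about 1 read in 100 at a 1% error rate,
which is a property of the alignment trim, not of the data.

E-values use the read length as *m* and the total concatenated genome
length as *n*, with no edge-effect correction; at a 1 × 10⁻⁵ threshold
and genome sizes in play this simplification is far from the decision
boundary.

## What the simulator emulates — and what it does not

`simulation_config()` defaults are the package's study conditions: a
1-Mb two-chromosome genome at 34% GC (legume-like), 100 non-overlapping
gene models of 1–5 kb (the real annotation has roughly one gene per
10 kb), 200 lines × 10 insertions = 2,000 planted insertions placed
uniformly (per-chromosome probability proportional to length), and
reads of length Normal(363, 80) with 1% per-base substitution noise.
Class fractions are 55% signature-bearing, 35% motif-free AD-primer
contaminant, 5% too-short and 5% internal-signature, chosen so the
high-confidence fraction is near the observed 56% (221,275 of 392,396)
while exercising every reject reason. Signature reads sample planted
insertions with replacement, as real FSTs redundantly tag the same
insertion; half of all reads are emitted reverse-complemented.

Class labels are enforced on the *emitted* sequence, after noise:
contaminant reads are rejection-sampled until motif-free (or
motif-internal-only) on both strands. Without this, substitution noise
occasionally manufactures an end-proximal motif and the generator
would mislabel its own read — any classifier would then "fail" through
no fault of its own.

The simulator does **not** model indels, chimeric reads, quality
scores, nested/rearranged insertions, repeat-induced multi-mapping
(the toy genome is i.i.d. random, so 15-mers are essentially unique),
or biased insertion preferences. Passing the recovery tests therefore
demonstrates the correctness of the QC rules, the aligner, and the
coordinate bookkeeping — not robustness to repetitive genomes or
structural artefacts of real TAIL-PCR libraries.

## Landscape statistics and rounding

Counting conventions follow the published tables:

* **Per-gene tallies** use the full gene span, introns and UTRs
  included, with inclusive interval containment; overlapping genes
  each receive the insertion (logged). Gene assignment runs on a
  GenomicRanges interval index and is tested against brute-force
  containment counting.
* **Per-chromosome tables** count FST-level records (no per-line
  deduplication), with percentages of the high-confidence total; a
  line-deduplicated site table is emitted in parallel for downstream
  use.
* **Frequency classes** count genes with ≥ 1, > 1 and ≥ 4 insertions.
  Whether the published "mean insertions per gene" divides by inserted
  genes or all annotated genes is not derivable from the printed
  counts, so both denominators are reported
  (`mean_per_inserted_gene`, `mean_per_annotated_gene`); the
  frequent-gene selection uses a strict `>` threshold at the mean.
* **Bins** tile each chromosome with `bin_width` windows (500 kb at
  full scale; the toy analysis uses 50 kb so bins stay populated),
  terminal bin truncated; GC is (G+C)/(A+C+G+T), N-excluded, with an
  `all_n` flag for gap-only bins.
* **Rounding** of every printed percentage is round-half-up at the
  precision of the corresponding published figure (2 dp for
  distribution tables, 1 dp for the 48.7%-style class percent, integer
  for the 92% mapping rate); `round_half_up()` is exposed because
  base R's round-half-to-even reproduces none of these reliably.

Assembly statistics use the standard N50 (largest length covering half
the total), and contigs are scaffold fragments split at runs of ≥ 10 N
(the gap threshold is configurable; the published tables do not state
their contig definition). Partition labels are caller-supplied — the
published small/tiny boundary is never defined, so the package invents
no hidden cutoff.

## Problem sizes and determinism

The bundled analyses and acceptance checks run the full toy condition
(1 Mb, 2,000 insertions, ~3,600 reads) in well under a minute on one
core; unit tests use smaller genomes (2–100 kb) so the whole suite
stays fast. All stochastic steps flow from a single `rng_seed`, and
classification/mapping are pure functions of (sequence, config), so
fixed-seed runs are byte-reproducible. The oracle-equivalence check
compares best-hit scores against an exhaustive all-placement,
both-orientation scan on references up to 2 kb, where brute force is
affordable and exact.

## Known limitations

* Ungapped alignment only; an FST spanning a true indel near the
  junction may be trimmed or (rarely) rejected by the identity filter.
* A read whose clean (error-free) stretch never reaches 15 bp yields
  no seed and goes unmapped; at ≤ 2% substitution rates this is
  negligible, but the k-mer seed length bounds error tolerance.
* Multi-mapping in repetitive genomes resolves by deterministic
  tie-break, not by mapping-quality modelling.
* The funnel/percentage reproductions of the published tables are
  arithmetic-level checks on the printed counts — the raw 392,396-FST
  dataset itself is not redistributable at desk scale.
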