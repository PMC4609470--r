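---
title: "Methods: comparative EST polymorphism analysis with estpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative EST polymorphism analysis with estpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Comparing the transcribed fraction of two closely related genomes — for
example an introgression line against its parent cultivar, or two EST
libraries sequenced from related wheat germplasm — asks a narrow question of
noisy data: across the transcripts the two libraries share, how often do
their sequences differ by substitution, by small insertion/deletion, and by
large structural events, and what do the patterns of those differences say
about the mutational mechanisms at work?

estpoly implements that comparison as a reusable pipeline over plain FASTA
input:

1. **clean** — fixed-prefix truncation and minimum-length filtering of
   single-pass reads;
2. **cluster** — greedy overlap clustering of each library into unigenes
   (contigs and singletons);
3. **match** — all-vs-all local alignment of the two unigene sets with
   identity, E-value and HSP-length filters and best-hit selection;
4. **call variants** — directional SNPs, small indels inside alignments,
   large indels between split alignments;
5. **statistics** — per-1000-nt frequencies, transition/transversion and
   per-pattern spectra, indel size spectra with insertion:deletion ratio
   correlation, flanking GC profiles, per-functional-category summaries;
6. **classify** — mechanistic grouping of large indels by their flanking
   sequence (identical flanks, boundary repeats, modified flanks).

A seeded simulator (`simulate_pair()`) generates library pairs with known
ground truth so every stage is testable offline; `recovery_report()` closes
the loop by comparing planted and estimated quantities.

# Cleaning and clustering

Single-pass cDNA reads degrade with read position, so only the first
`max_prefix_len` nucleotides (default 800) are retained, and sequences
shorter than `min_len` (default 100, boundary inclusive: a 100-nt sequence
is kept) are dropped with a per-record disposition report. IUPAC ambiguity
codes other than N are conservatively mapped to N, and N never counts as a
match, a mismatch partner for SNP calling, or a G/C in composition
statistics.

Clustering is single-linkage under a qualifying-overlap relation: two
sequences are linked when their best ungapped dovetail or containment
overlap spans at least `min_overlap` nt (default 50) at identity at least
`min_overlap_identity` (default 0.95), on either strand. Candidate pairs
are pre-screened with a shared 12-mer index, which cannot discard a
qualifying pair: an overlap of ≥ 50 columns at ≥ 95 % identity always
contains an exact run of ≥ 12 matching bases. Consensus sequences are built
by anchoring on the longest member (ties: lexicographically smallest id),
laying members out at their overlap offsets re-oriented to the anchor
strand, and voting per column; vote ties take the base of the longest
covering member, then the lexicographically smallest base. These tie-breaks
make clustering deterministic and invariant to input order up to unigene
numbering. The clusterer is a deliberately simple stand-in for a full
assembler: it has no error correction beyond majority vote and no repeat
resolution, which is adequate for the low-error, low-coverage EST setting
it serves.

# Matching

The aligner is an affine-gap Smith–Waterman (match +1, mismatch −2, gap
open 5, gap extend 2; a gap of length L costs 5 + 2L) with traceback,
returning the optimal HSP and, by greedy masking of the matched query
interval and re-alignment, non-overlapping suboptimal HSPs down to the raw
score implied by the E-value cut-off. Both subject orientations are tried.
Significance follows the Karlin–Altschul form `E = m·n·2^(−bit)` with
`bit = (λ·S − ln K)/ln 2`, using the published ungapped constants for the
+1/−2 scheme (λ = 1.28, K = 0.46). The constants parameterise the filter,
not the alignment; the contract is filter behaviour, not exact E-values.

Filters default to identity ≥ 0.96 (gap columns count in the denominator,
the convention of the heuristic aligners this stage emulates), E ≤ 1e-10,
and HSP length ≥ 33 columns. One best subject is kept per query — total bit
score, then pooled identity, then lexicographic subject id — which is the
cleanest way to keep paralogous secondary hits out of the frequency
denominators. Matched coverage is the summed aligned columns over retained
pairs divided by the summed length of the matched queries.

**Split topology for large gaps.** With plain affine costs an optimal local
alignment will happily bridge a gap of hundreds of nucleotides whenever the
flanking match score exceeds the gap cost, whereas the heuristic aligners
that define the "large indels split the match into two alignments" topology
terminate extension at such gaps (X-dropoff). estpoly reproduces the split
topology with a post-pass: any in-HSP gap run of length ≥ `min_large`
(default 23) splits the HSP at the run, with fragment scores and
coordinates recomputed and terminal gap columns trimmed. In-alignment gap
runs of 11–22 nt therefore remain `small` by topology — the size classes
are "within one alignment" vs "splits the alignment", not a length rule.

A by-product of seed-free optimal alignment is that every pairwise score is
exactly checkable: the test suite verifies the engine against an
independent exhaustive dynamic-programming oracle on a thousand random
short pairs.

# Variant calling conventions

* **SNPs** are directional, written subject→query: `"G->A"` means the
  subject (reference) library carries G where the query carries A.
  Transitions are A↔G and C↔T. Columns containing N or a gap are skipped.
* **Small indels**: each maximal run of consecutive gap columns inside an
  HSP is one event (so Table-style per-length tabulation counts events, not
  gap columns). Gaps in the subject row are insertions (sequence present in
  the query only); gaps in the query row are deletions. Flanks of up to 10
  nt are recorded from the carrier of the event sequence.
* **Large indels**: for consecutive collinear HSPs of a pair, with query
  gap `gq` and subject gap `gs`, an event of length `|gq − gs|` is emitted
  when the smaller gap is within `slop` (default 5 nt) and the larger at
  least `min_large` (default 23 nt). Local alignments can extend a few
  columns past the true breakpoint when the event boundary resembles the
  continuation; such extension appears as a small HSP overlap, and the left
  HSP is trimmed back through its alignment columns until the overlap
  disappears before the gap arithmetic is applied.

Two recognised blind spots are inherent to alignment-based calling and are
shared by the class of methods this pipeline belongs to: events closer to a
sequence end than the span needed to seed a local alignment (~10 nt) are
invisible, and opposite-polarity events a few bases apart are rendered as
mismatch columns by any optimal aligner (an INS+DEL pair becomes one or
more apparent SNPs). The recovery tests quantify both: at the default
rates they cost ≈ 1–4 % of events.

# Statistics

Frequencies are reported per 1000 nt with the denominator equal to the
total alignment columns of qualifying HSPs over best-hit pairs, gap columns
included. The source material does not pin down the denominator convention
(query bases, subject bases, or columns); columns are chosen because the
identity filter is defined over columns, making numerator and denominator
consistent. The choice moves frequencies by under ~1 % at these divergence
levels. Only small indels enter the per-kb indel frequencies; large indels
are tabulated separately by the spectrum and mechanism modules.

The insertion:deletion ratio spectrum bins small indels by exact length
1–10 and large indels by default into 23–70, 71–200 and > 200 nt. Ratios
are undefined in bins without deletions; those bins are excluded from the
Pearson correlation of ratio against bin length, the correlation is
undefined with fewer than three defined bins, and an all-equal ratio vector
is reported as r² = 0 with a zero-variance flag. The correlation is
computed on raw (length, ratio) pairs without transformation.

Flank GC profiles average G/C occurrence at each of the ten positions on
either side of an indel across all indels carrying a base at that offset,
per polarity and pooled.

# Mechanistic classification of large indels

Each large indel is assigned exactly one group, in precedence order:

1. **boundary_repeat** — the gained/lost segment duplicates a motif
   (1–51 nt) abutting the breakpoint: the event sequence starts with m
   while the 5′ flank ends with m, or ends with m while the 3′ flank starts
   with m. For a 1-nt motif this reduces to the indel base extending a
   homopolymer run; homopolymer and perfect tandem motifs are reported at
   unit length. Because the placement of an indel against its carrier is
   ambiguous exactly when such repeats exist, the classifier enumerates all
   alignment-equivalent placements (sliding the event left and right one
   base at a time) and keeps the longest motif any placement yields.
2. **modified_flanks** — at least one substitution within `flank_window`
   (default 10) alignment columns of the breakpoint on either side.
3. **identical_flanks** — those flank columns are mismatch- and gap-free.
4. **unclassified** — gap-containing but substitution-free flanks.

Repeats are checked first because they are the most specific signal; the
flank-substitution count is reported regardless of group.

Short motifs arise by chance: a random insertion starts or ends with a
matching 1-nt motif with probability ≈ 1/4 per boundary/side combination,
so 1–2-nt motif calls are individually uninformative even though their
aggregate count is meaningful. `classify_indels()` therefore reports every
motif with its length and exposes `min_motif`; the default 1 matches the
field convention of counting homopolymer-extension events, while
motif-level precision/recall statements (and the recovery report's
boundary-repeat fraction) are made at `min_motif = 3`, where chance calls
are rare. The simulator-based test plants motifs of 3–51 nt on
mutation-free flanks and requires precision and recall ≥ 0.9.

# The simulator

`simulate_pair()` draws ancestral unigenes with i.i.d. bases (default 500
sequences of 700–1000 nt at GC 0.54, matching the unigene length mode and
base composition of the EST collections this pipeline targets) and evolves
two descendant libraries:

* **Substitutions** are applied independently per branch at `sub_rate` per
  site (default 11.328/2 per kb so the pairwise expectation matches the
  reference comparison), transition with probability r/(1+r) at
  `tstv_ratio` r (default 6.701/4.627 ≈ 1.45).
* **Indels** are drawn as pairwise events: per-site small-indel probability
  1.577e-3 with a 1-nt-dominated length distribution over 1–10 nt taken
  from the observed per-length frequencies; Poisson large-indel count per
  sequence 0.067 with lengths uniform on 23–574 nt; insertion polarity with
  probability 1331/2120 ≈ 0.63. Each event is realised as an insertion
  into one branch — into the query branch for pairwise insertions, the
  subject branch for pairwise deletions. Pairwise statistics are identical
  to a mixed insertion/deletion realisation, but this choice keeps
  coordinate bookkeeping closed (no sequence ever shrinks) and makes
  repeat-mediated events constructible for both polarities.
* **Repeat-mediated events** (fraction `repeat_fraction`, default 0.44,
  the observed share of the boundary-repeat group among large indels)
  duplicate a motif of `motif_len_range` (default 1–51 nt, capped by the
  event length) from the adjacent branch sequence at a randomly chosen
  side; the remainder of the inserted segment is random.
* Substitutions are placed before indels within each branch, so motif
  copies are taken from the substituted background and the recorded edit
  list reproduces each descendant exactly (`apply_edits()`; the liftover
  closure test asserts byte equality across seeds).

The random stream is consumed in a fixed documented order, so a fixed seed
yields byte-identical libraries and truth tables.

What the generator deliberately does **not** emulate: sequencing error and
chromatogram quality structure (the pipeline starts from cleaned FASTA),
codon structure and selection, expression-level sampling bias, genuine
paralogy within a library, length-dependent insertion:deletion odds, and GC
enrichment of indel flanks. Passing recovery tests therefore demonstrate
that the pipeline measures what was planted under an idealised divergence
model — they bound algorithmic error, not the biological uncertainties of
real libraries, where paralog filtering and assembler behaviour dominate.

# Validation conditions and numerical choices

The recovery acceptance runs 500 unigenes under the default conditions and
requires every estimated rate (SNP, transition, transversion, small
insertion, small deletion) within 10 % of the planted count; observed
errors are ≤ 5 %. Self-consistency checks run 20 seeds at 30 unigenes
(liftover closure plus planted-vs-expected counts within three binomial
standard errors), and the property suites use 6–80 unigenes per case.
Recovery comparisons share the pipeline's matched-column denominator
between planted and estimated rates so they isolate variant recovery from
denominator convention.

Other fixed numerical choices: cleaning keeps the boundary-length sequence;
slop = 5 nt absorbs ragged alignment ends around large indels;
`max_gap_run` for HSP splitting is tied to `min_large`; the k-mer
prefilter requires 5 shared 12-mers for matching (a ≥ 96 %-identity
full-length homolog shares hundreds) and 1 for clustering; all coordinates
in R-facing tables and emitted TSVs are 1-based inclusive; SNP patterns use
ASCII `"G->A"`. Every threshold is a `pipeline_config()` field and can be
overridden; in particular, simulated libraries are analysed with
`max_prefix_len` raised above the simulated lengths so the cleaning stage
passes them through untruncated, keeping the planted truth and the
observable window identical.

# Known limitations

* Two large indels separated by fewer than `min_hsp_len` conserved
  nucleotides cannot be separated by any HSP-based caller; the intervening
  segment is too short to align, and the events merge or are dropped
  (conservatively, when neither side's gap is within slop).
* The unigene clusterer is not a full assembler; deep clusters with
  conflicting offsets resolve by BFS from the anchor and majority vote,
  which is adequate for EST coverage but not for repeat-rich data.
* E-values use ungapped constants with an affine-gap engine; they order
  hits correctly and gate noise, but are not calibrated probabilities.
* The minus strand is supported throughout matching and calling, but the
  simulator only emits forward-strand homologs; strand handling is
  exercised by constructed tests.
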