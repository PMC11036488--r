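---
title: "loxkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{loxkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxkit)
```

## The model

A SCRaMbLE-competent synthetic chromosome is modeled as a sequence of
**loxP units (LUs)** separated by single copies of a recombination motif,
by default the 34 bp palindromic loxPsym site. Because loxPsym equals its
own reverse complement, one forward-strand scan finds every copy, and
recombination outcomes are orientation-independent. The genotype at LU
granularity is a **signed arrangement**: an ordered list of (LU id,
orientation) pairs referencing a fixed reference chromosome. Ids may repeat
(duplication) or be absent (deletion). `render_arrangement()` is the exact
inverse of segmentation: it concatenates LU sequences (reverse-complementing
negative units) with one motif copy per junction, so every simulated
genotype has a concrete DNA realization and every event has exact length
arithmetic (deletion of *b* LUs removes their lengths plus *b* motif copies;
inversion is length-neutral; duplication adds lengths plus *b* copies).

Coordinates are 0-based half-open everywhere — internally, in BED output and
in the primer CSV. For circular chromosomes there are as many LUs as motif
sites; LU0 begins immediately after the first motif site and rendering
starts at LU0.

Junction *k* denotes the motif copy between LU *k* and LU *k*+1 and is
labeled `[k:k+1]`. This is an internal convention; it need not coincide with
any house numbering of junctions on published synthetic chromosomes.

## Junction assays and their blind spots

A junction-spanning primer pair amplifies across one motif copy: the forward
primer sits in the upstream LU, the reverse primer in the downstream LU.
The assay logic, and the limits the package deliberately preserves:

* **Deletion** of LUs between two junctions destroys every assay whose
  primer lands in a deleted LU: ≥ 2 consecutive missing amplicons.
* **Inversion** of a block flips both boundary junctions but leaves internal
  junctions amplifiable (both primers flip strand together and detection is
  strand-symmetric): two *distant* missing amplicons. An inversion and a
  translocation of the same block can produce identical patterns, so the
  classifier only ever emits the merged hypothesis
  `inversion_or_translocation` — calls are indicative and need sequencing
  confirmation.
* **Single-LU inversions** break two *adjacent* junctions and are therefore
  indistinguishable from single-LU deletions at the pattern level; they fall
  into the deletion-hypothesis class.
* **Blocks touching a linear chromosome end** break only one junction (no
  junction exists beyond the telomere); a lone missing amplicon is reported
  as `indeterminate`, never over-interpreted.
* **Duplications** create no missing amplicon at all: every reference
  junction still exists somewhere. This blind spot is structural; the
  classifier never hypothesizes a duplication and attaches the caveat to
  every report.

`classify_pattern()` applies these rules deterministically to the maximal
runs of zeros (wrapping on circular chromosomes, where the shorter of the
two arcs between two singletons is hypothesized and the complement noted as
the alternative).

## Primer design

For each junction, all candidate primers within the flanking LUs (windowed
by the amplicon cap) are enumerated and the pair minimizing

    w_len * |len - len_opt|   (each primer)
  + w_tm  * |Tm - Tm_opt|     (each primer)
  + w_gc  * dist(gc, range)   (each primer)
  + w_pair * |Tm_f - Tm_r|

is returned, subject to hard length, Tm, GC, masking and amplicon-size
constraints. The search is exhaustive (with a branch-and-bound cutoff that
cannot change the optimum) and ties are broken deterministically: smaller
forward start, then shorter amplicon, then lexicographic forward and reverse
sequence. Identical inputs give byte-identical panels.

Defaults — primer 18/20/25 nt, Tm 57/60/63 °C, GC 0.30–0.70, amplicon
100–500 bp, unit weights — are standard end-point qPCR ranges; every value
is overridable programmatically or via YAML/JSON config. If a flanking LU
cannot host a primer (too short, masked, or thermodynamically infeasible),
the search widens to span up to `max_span_motifs` (default 2) motif copies
before recording the junction as failed with a machine-readable reason.
Zero-length LUs are legal in the model but excluded as primer hosts.

Melting temperatures use the unified nearest-neighbor parameter set
(Allawi & SantaLucia 1997 stacks, duplex-initiation terms per terminal base
pair) with the SantaLucia 1998 monovalent-salt entropy correction
ΔS′ = ΔS + 0.368·(N−1)·ln[Na⁺] and
Tm = 1000·ΔH / (ΔS′ + R·ln(C_T/4)) − 273.15, at 50 mM Na⁺ and 250 nM
total strand by default. During panel enumeration the same sums are computed
via prefix arrays over the template; the two code paths agree to ~1e-10 °C
(floating-point summation order), far below any chemical meaning.

Masking unions three rules before design: homopolymer runs ≥ 6 bp, DUST-style
low-complexity windows (64 bp windows, 32 bp step; score
Σ c_t(c_t−1)/2 / (w−3) over trinucleotide counts, threshold 2 — a uniform
random sequence scores ≈ 0.5), and user BED intervals. N runs are always
masked: Ns are tolerated in chromosomes but never inside primers.

Off-target screening is an exact brute-force Hamming scan of every primer
against both strands of every reference sequence (default ≤ 4 mismatches), a
deliberate choice of reproducibility over speed at desk-scale genome sizes.
A primer with more than one match is flagged; any unintended plus/minus hit
combination within the amplicon cap is flagged as a spurious amplicon, by
default only when the 3′-terminal base matches exactly (polymerase extension
requirement; configurable off).

## In-silico PCR

`predict_amplicons()` reports an amplicon for every forward-primer hit on
one strand paired with a reverse-primer hit on the opposite strand,
downstream, non-overlapping on the template, within the size cap (defaults:
≤ 1000 bp, ≤ 2 mismatches per primer — tolerant because query sequences are
typically imperfect long-read assemblies). Mismatches are counted uniformly
along the primer; no positional weighting and no 3′ requirement here, by
design. Any amplicon ⇒ presence 1: end-point PCR cannot distinguish
multiplicity, though all amplicons are recorded for diagnostics. Detection
is strand-symmetric, monotone in both tolerance parameters, and handles
circular queries via a doubled-sequence scan with positions reported modulo
the length (origin-crossing amplicons are legal, capped at one full turn).

## The simulator and what a green test establishes

`sample_events()` draws the number of events (fixed or Poisson, default
λ = 3), then per event a kind from the configured mix, a contiguous block
(uniform start; geometric length, mean 2 LUs, truncated), and insertion
targets where applicable. The default mix — deletion 0.63, inversion 0.23,
duplication 0.07, translocation 0.07 — follows observed event proportions on
a circular synthetic chromosome, with the unreported remainder split evenly
between the two complex kinds; the reported mean event size is in kb, not
LUs, so the block-length mean of 2 LUs is this package's own choice of a
realistic default, configurable. Viability is modeled only as a
protected-LU set (e.g., a centromere-bearing LU); there is no essential-gene
or fitness model. Events violating viability, and no-op translocations, are
rejected and redrawn within a bounded retry budget.

Reproducibility contract: per-isolate RNG substreams are derived as
`(master_seed + 1000003·index) mod (2^31 − 1)`, so a single isolate can be
regenerated without replaying the population, and the JSON truth log is
sufficient to replay every final arrangement exactly (`replay_log()` +
`render_arrangement()` reproduce the emitted FASTA byte-for-byte).

The fixture generator emulates the geometry of a synthetic chromosome —
i.i.d. random LUs at a chosen GC, single motif copies between them, no
spurious motif occurrences (rejection sampling) — and none of its biology:
no genes, no recoding, no PCRTag sequence context, no repeat structure, no
assembly errors. A green end-to-end test therefore establishes the
correctness of the computational contracts (design optimality, detection
logic, replay arithmetic) on clean sequence, not performance on real
assemblies, where mapping/assembly artifacts dominate the error budget.

## Arrangement annotation

`compare_arrangements()` is a deterministic greedy annotator, not a minimal
rearrangement-distance solver. It decomposes the observed arrangement into
maximal blocks with reference-consistent signed adjacencies; missing
reference runs become deletions; reference runs present in extra copies
become duplications (the redundant copy is identified by neighborhood
consistency before positional analysis); an order-reversed, sign-flipped
block sitting between its original neighbors is an inversion; blocks outside
the heaviest reference-ordered chain are translocations. Breakpoints count
observed adjacencies absent from the signed reference adjacency set.

For single-event histories the annotation is provably exact in kind and
count, with one caveat: a transposition has two sequence-identical
descriptions (block B moved over block C ≡ C moved over B), so the reported
span is one of the two equivalent blocks — the heavier chain is kept, which
reports the lighter block as moved. For multi-event histories the output is
a parsimonious annotation validated property-wise (e.g., reported deletions
always equal the reference-minus-observed multiset difference), mirroring
how rearrangement counts are annotated rather than proven minimal in
practice. Circular observed arrangements are compared with wrap-around
adjacencies but are assumed to start at the reference origin (the simulator
never rotates); rotation-invariant comparison is a known limitation.

## Candidate selection

`diversity_score()` is simply the number of missing amplicons — a proxy for
rearrangement extent. `select_candidates()` seeds with the highest-scoring
sample and then greedily maximizes the minimum Hamming distance to the
chosen set (ties: higher score, then name), the standard max-min design for
avoiding redundant sequencing of identical genotypes. Forced picks at
distance 0 carry an explicit redundancy warning. The greedy max-min choice
is a stand-in heuristic: the selection objective for strain triage is not
uniquely defined by presence patterns alone.

## Numerical and degenerate-input choices

* Motif scans resolve overlapping occurrences leftmost-greedy (impossible
  for loxPsym, possible for low-complexity user motifs).
* Lowercase input is uppercased on load; non-ACGT motifs are rejected.
* A circular chromosome with zero motif sites cannot be segmented (error);
  a linear one yields a single LU and no junctions.
* `max_amplicon` must exceed the summed primer lengths; primer sites may
  not overlap on the template.
* Config files may be YAML or JSON; unknown keys are passed through so
  subcommand blocks can share one file; CLI flags override config values.
* Penalty ties in design are broken by a strict total order (see above), so
  equality of floating-point penalties across candidates — rare but possible
  — cannot produce nondeterminism.

## Known limitations

* Pattern calls are indicative only; inversion vs translocation is never
  resolved, small-LU events can hide inside amplifiable products, and
  duplications are invisible by construction.
* No secondary-structure, primer-dimer or multiplexing model; Tm difference
  is the only pair-compatibility term.
* No read-level or assembly-based SV calling; the comparator consumes known
  signed arrangements (from truth logs or external reconstruction).
* The simulator models whole-LU events only; intra-LU breakpoints,
  inter-chromosomal events, aneuploidy and whole-genome duplication are out
  of scope.
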