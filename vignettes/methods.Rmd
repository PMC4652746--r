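---
title: "Cost-ordered seeding and quality-aware read alignment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-ordered seeding and quality-aware read alignment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relign)
```

# The problem

Short-read aligners that seed with short, low-edit-distance exact matches
misplace exactly the reads that matter most for variant calling: reads whose
seeds carry several mismatches (polymorphic regions), reads with indels in
the seed, and reads spanning structural-variant (SV) breakpoints.  A read
simulated with *k* mismatches can often be placed *uniquely* somewhere else
with fewer than *k* mismatches -- and the lowest-mismatch placement is then
confidently wrong.  Paired-end modes that over-trust the expected insert
size compound this: a discordant (SV-spanning) pair gets forced into a
concordant placement elsewhere.

`relign` implements the opposite strategy ("search the reference first"):

1. **Cost-ordered seeding.**  A long seed (75 bp) is scanned against the
   genome in increasing order of alignment cost, allowing up to five
   mismatches and one gap *inside the seed*.  Every genome position is
   assigned its least-penalty signature (mismatch count, gap length/type),
   and hits are yielded step by step, cheapest signatures first.
2. **Deep scanning.**  Enumeration does not stop at the least-cost hit:
   scanning continues to collect next-best hits, both to avoid the
   lowest-mismatch trap and because mapping quality is computed from the two
   best hits.
3. **Quality-aware scoring.**  Candidates are extended to the full read and
   ranked by a base-quality-aware affine score, not by raw mismatch count.
4. **Unbiased pairing.**  Ends are aligned independently; alignment scores
   precede mate-pair information, so a confident discordant pair is never
   displaced by a weaker concordant combination.
5. **Supplementary alignment.**  Soft-clipped tails longer than 20 bp are
   realigned through an exact 20-bp scan so that primary plus supplementary
   records jointly represent a breakpoint-spanning read.

# Model and scoring

For a base with Phred score $Q_i$, the correct-call probability is
$P_i = 1 - 10^{-Q_i/10}$, and assuming no nucleotide bias each specific
wrong base has probability $(1 - P_i)/3$.  (The latter is the only sensible
probabilistic reading: the quantity must vanish as $Q_i \to \infty$.)

The alignment score is affine-gap and quality-aware.  The published
principle -- match/mismatch contributions are Phred-scaled functions of
$P_i$ -- does not pin exact constants, so this package fixes a concrete
monotone scheme and exposes every constant in `scoring_scheme()`:

* match bonus: 2 for $Q \ge 10$, else 1;
* mismatch penalty: $\max(2, \min(Q, 40)/5)$, i.e. 2 to 8 -- disagreeing
  with a confident base costs four times more than with a doubtful one;
* gap run of length $L$: $-(\mathrm{open} + (L-1)\,\mathrm{ext})$ with
  open = 12, ext = 2; soft clips score 0;
* `N` in read or reference never matches and is penalised as a quality-0
  mismatch.

**Mapping quality** is derived from the two best full-read scores:
$\mathrm{mapQ} = \min(60,\; 2\,(s_1 - s_2))$, 0 on ties and for
repeat-flagged reads, and with $s_2$ replaced by half the perfect-match
score when no runner-up exists inside the search budget.  The exact
published mapQ formula is not available, so the contract implemented here
is the stated one -- two-best-hit based, 0 means ambiguous, capped -- with
the scale and floor as package constants.

# Seeding: cost-ordered search with one gap

`enumerate_cost_steps()` precomputes all (mismatches $\le 5$, gaps $\le 1$,
gap length $\le d_\mathrm{seed}$) signatures sorted by penalty
(`mismatch = 4`, `gap = open 6 + 1/bp`; these unit costs only *order* the
scan and are deliberately decoupled from the quality-aware scores used for
ranking).  Ties order deterministically: fewer gaps, then fewer mismatches,
then shorter gaps.

The canonical configuration space at a genome anchor $p$ is: a zero-gap
placement, or a split of the seed at an interior point with one gap of
length $g$ (reference-skipping or read-skipping) between the two parts.
Each anchor's signature is the least-penalty configuration.  The index is a
hashed 10-mer position table; candidates come from pigeonhole parts (7
parts of a 75-bp seed cover 5 mismatches + 1 gap + 1), shifted by up to
$\pm d_\mathrm{seed}$ to catch parts displaced by a gap, then verified
exhaustively.  The test suite proves the hit sets equal a brute-force
position-by-signature scan of every genome position.

Defaults: seed length 75 (reads shorter than 150 bp use their first
`min(75, length)` bases with the mismatch budget scaled as
$\lfloor 5\,\ell/75 \rfloor$), $d_\mathrm{seed} = 10$ (longer indels are
the extension stage's job), repeat guard $H = 64$ hits per step.

**Deep-scan stopping rule.**  The published description leaves the exact
stopping rule open; here the default is one further non-empty cost step
past the first (configurable), which is exactly what the two-best-hit mapQ
needs.  One subtlety discovered in testing: under the canonical
configuration space, anchors adjacent to an already-found locus re-derive
*the same* placement as a costlier gapped signature ("shadows").  A step
contributing only shadows does not consume scanning depth -- otherwise the
depth budget is spent on re-descriptions of the known locus and the genuine
runner-up (e.g. the true locus of a high-mismatch read) is never reached.
Novelty is judged by anchor distance $\le d_\mathrm{seed}$ on the same
chromosome and strand.

**Breakpoint fallback.**  A rearrangement junction inside the seed defeats
every within-budget signature.  When the full-length seed finds nothing,
the seed is re-scanned as two half-length segments with proportionally
scaled budgets; a junction leaves at least one half intact, and the intact
half seeds the side of the read that the primary alignment will cover.

# Extension

**One-gap semi-global kernel.**  Assuming at most one gap run in the read,
the read is split into two halves; the half carrying the gap is tested
$j = 1..d$ bases away from the other, in both gap directions, over every
anchor in the window -- implemented with per-offset prefix-score tables so
each (anchor, gap length) pair costs $O(\ell)$.  The read is never clipped
by this kernel.  Tests prove it equals the naive enumeration of all one-run
alignments exactly, never exceeds an unconstrained affine DP, and matches
the DP optimum whenever that optimum has at most one gap run of length
$\le d$.  Default $d = 30$ bp.

**Local fallback.**  When the semi-global score drops below 90% of the
perfect-match score (the score for an exact match, $\sum_i \mathrm{mb}(Q_i)$),
a local affine Smith-Waterman is run in two steps, score-only first, then a
banded traceback through the reported end cell (band 16, doubling to 256 on
score mismatch -- a disagreement after maximal growth is an internal
error).  Negative-scoring tails become soft clips, which is what turns a
breakpoint-spanning 100-bp read into `65M35S`.  The threshold comparison is
strict (`< 0.9`), making the boundary exactly testable.

Acceleration heuristics follow the published design: at most `sw_budget`
(32) local extensions per read; extension stops after `stall_limit` (8)
candidates without improvement; the traceback is skipped when a candidate's
local score falls *strictly below* the current best.  Ties are deliberately
kept: a tying candidate at another locus is precisely the ambiguity
evidence that must drive mapQ to 0.

# Whole-read pipeline

Reads of at least 150 bp are split into consecutive non-overlapping 75-bp
segments from the 5' end (remainder bases participate in extension only).
If every segment's least-cost hit is unique and the hits are mutually local
(same chromosome and strand, implied read anchors within read length
$+ d$), the whole read is extended once over that locus; otherwise the
whole read is extended at every segment's candidate loci and the best
score wins.  The uniqueness requirement matters in repeat regions: a
segment with two equal-cost hits cannot adjudicate between repeat copies,
so both copies must be extended -- the resulting tie correctly yields
mapQ 0.

**Supplementary realignment** triggers when a soft clip exceeds 20 bp: the
outermost 20 clipped bases (the choice of outermost-vs-breakpoint-nearest
is a config flag) are scanned exactly on both strands, the read is locally
realigned at each candidate locus, and the best complementary alignment
(covering clipped bases, overlapping the primary's read span by at most
10 bp) is emitted with FLAG 2048.

**Pairing.**  Both ends align independently.  If both top hits are
confident (mapQ $\ge 20$), they are reported as-is -- concordant or not.
Otherwise the candidate cross-product is searched for the best
$s_1 + s_2 + \mathrm{bonus}$ combination, with a deliberately small
concordance bonus of one gap-open unit so scores dominate pairing, and the
pair mapQ is recomputed from the two best combination scores.  A missing
mate is rescued by local alignment over the window the FR orientation
predicts (anchor $\pm(\mu + 4\sigma + \ell_m)$); a rescue is accepted only
at $\ge 0.75$ of the mate's perfect-match score and never carries more
mapQ than its anchor.  The insert model is median/MAD-estimated from pairs
with both ends at mapQ $\ge 20$ on one chromosome, falling back to nominal
values below 100 qualifying pairs; the concordance window is
$\mu \pm 4\sigma$ with $\sigma$ floored at 10 bp.

# Synthetic data

The generators reproduce the four benchmark read classes at desk scale and
are first-class, tested code:

* `make_genome()`: i.i.d. bases at GC 0.41, with `repeat_fraction` of the
  sequence made of annotated 200-1000 bp duplicated segments to exercise
  repeats and deep scanning.  Real genomes have structured repeat families,
  mutated repeat copies and compositional heterogeneity that this does not
  model, so passing tests speak to algorithmic correctness, not to
  performance on real libraries.
* `simulate_reads()`: uniform positions on both strands; per-cycle quality
  curve starting near Q38 and decaying to ~Q25 (logistic, with noise);
  substitution probability proportional to the quality-implied error rate,
  optionally rescaled to a target mean rate; combined per-read errors
  capped at 7%.
* `spike_indels()`: per-base indel rate 0.001 (the benchmark uses an
  elevated rate; genomic indel density is far lower), geometric lengths
  truncated at 10 bp, separate insert-only and delete-only modes; deletions
  extend the genomic span so read length is preserved.
* `simulate_pairs()`: FR fragments at Normal(500, 50) truncated to twice
  the read length (overlapping ends are refused), or discordant pairs with
  ends drawn from two different chromosomes.
* `rearrange_genome()`: non-overlapping deletions, insertions, tandem
  duplications, inversions and translocations, 100-2000 bp, uniform type
  mix by default (the benchmark's per-type proportions are not published).
  Insertions and translocations are donor-derived -- copied or cut from
  another locus of the same genome, as SV simulators place them -- so
  clipped tails remain mappable against the reference.  Events are recorded
  such that replaying them on the reference reproduces the rearranged
  genome byte-for-byte, and every junction is emitted with its rearranged
  coordinate.
* `simulate_breakpoint_reads()`: reads straddling recorded junctions with
  at least 25 bp on each side; error-free by default, a generator design
  choice that isolates breakpoint geometry from base-call noise in the
  clip-realignment tests (the Illumina-profile generators keep their own
  error models).

All generators take a mandatory seed, are deterministic under it, and use
per-component seed offsets so the RNG streams do not interfere.

# Evaluation harness

An alignment is *correct* when it is on the simulated chromosome and
strand with its leftmost position within 50 bp of the simulated origin
(slack for indel placement and soft clips).  `roc_by_mapq()` discards
mapQ-0 records as ambiguous, then accumulates correct/wrong counts by
decreasing mapQ; sensitivity is $TP/(TP+FN)$ and accuracy (used
interchangeably with specificity, as there are no true negatives) is
$TP/(TP+FP)$, with $TP$/$FP$ the correct/incorrect mapQ>0 primaries and
$FN$ the simulated reads with no mapQ>0 primary.
F-measure = $2\,SEN\cdot ACC/(SEN+ACC)$.  For data without truth,
`concordance_eval()` maps paired reads single-end and counts a pair
concordant when the ends are FR-oriented on one chromosome within 1000 bp
and both exceed mapQ 10, stratified by the head (read 1) mapQ; pairs with
an unmapped end are excluded.

# Numerical and degenerate-input choices

* Scores are doubles; DP ties break deterministically (zero-gap before
  gapped, shorter gap first, smaller anchor/split; diagonal moves preferred
  in tracebacks).  Candidate ranking ties break on (chrom, pos, strand).
* Coordinates are 0-based half-open everywhere; conversion to SAM's 1-based
  `POS` happens only in `write_sam()`.
* Only `M/I/D/S` CIGAR codes are emitted.
* All-`N` (or shorter-than-12) reads are unmapped records, never errors.
* Overlapping extensions of one locus reached through different signatures
  are deduplicated by >50% reference-interval overlap before ranking, so a
  locus cannot tie with itself into a spurious mapQ 0.
* An all-`N` genome refuses to index.

# Problem sizes

The shipped tests exercise: 200 random seed-search instances (2-6 kb
genomes) against the brute-force oracle; 500 random read/window pairs
against full-matrix DP oracles; 5,000 100-bp reads on a 100-kb genome with
10% repeats at 1% substitutions + 0.1% indels; 1,000 concordant plus 1,000
cross-chromosome discordant pairs on a 200-kb two-chromosome genome; and
500 SV-breakpoint reads over 25 mixed rearrangements on 150 kb.  These
sizes were chosen as the smallest that leave the statistical assertions
comfortably powered; `scripts/acceptance.R` re-runs the same computations
end to end and writes the headline numbers as JSON.

# Known limitations

* The index is a hashed k-mer table chosen for its query contract, not a
  compressed full-text index; memory is linear in genome size and the
  package targets desk-scale genomes (up to a few Mb), not hg-scale ones.
* Quality-aware scoring constants are package choices within the published
  principle; absolute mapQ values are therefore not comparable across
  aligners (only the contract -- 0 means ambiguous, capped, two-best-hit
  separation -- is).
* No SIMD: the local aligner is plain C++ validated against naive DP; the
  published speed claims are out of scope.
* Base-quality recalibration, RF/long-insert libraries, secondary-hit
  reporting beyond the ranked candidate set, and BAM/CRAM output are not
  implemented.
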