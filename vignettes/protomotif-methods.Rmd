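---
title: "Detecting coding signals by protomotif accumulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coding signals by protomotif accumulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomotif)
```

## The model

The package rests on a single empirical observation: when the putative
amino-acid translations of a genomic sequence (all six reading frames) are
searched against a large non-redundant protein database with a deliberately
permissive threshold, the resulting alignments — *protomotifs*, most of
them individually insignificant — do not fall uniformly.  They accumulate
over present and ancient protein-coding sequence, concentrated in the true
reading frame, and are rare elsewhere.  Accumulation converts a collection
of weak, unreliable signals into a strong positional one, without requiring
an intact open reading frame, splice signals, or conventional homology
significance.  That makes the approach complementary to ordinary gene
finders: it can flag pseudogenes, frame-shifted fossils and small ORFs, at
the price of having no gene-structure model at all.

The pipeline is:

1. **Filter** (`filter_and_map()`): keep a hit as a protomotif when its
   bit-score is at least `B` and its e-value at most `Emax`.  Both bounds
   are closed: a run at `B = 30` includes score-30.0 hits.
2. **Accumulate** (`build_profiles()` / `pileup()`): per chromosome and
   strand, the depth profile `D(p)` counts the protomotifs covering each
   position.  A plus-strand protomotif contributes only to the plus
   profile, whatever its frame index; likewise minus.
3. **Call** (`call_coding_signals()`): a coding-signal is a maximal run of
   positions with `D(p) ≥ H`.  Its *peak-height* is the maximum depth
   inside it.
4. **Evaluate** (`evaluate()` and friends): compare signals to an
   annotation under the reciprocal 20 % rule and report precision and
   recall in percent.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bit_score_min` (`B`) | 30 | bits | the working point of the method; 29/31 are the conventional more/less permissive settings.  Implemented as a single lower bound — restrictiveness rises monotonically with `B`, so a band-pass reading would discard exactly the strong alignments that anchor true peaks. |
| `e_value_max` | 10 | — | permissive on purpose: the method's raw material is alignments everyone else discards. |
| `peak_height_min` (`H`) | 100 | protomotifs | scales with the database: on the order of 100 for a ~20M-sequence database, 35 for a ~4.5M-sequence one, 26 as a permissive variant.  There is no universal default; the synthetic fixtures in this package pile to peak-heights of order 40–90, so examples and tests typically use 20–35. |
| `merge_gap` | 0 | nt | no merging rule is part of the method definition; merging is offered for users who want browser-style smoothed peaks. |
| `signal_extent` | threshold-run | — | see below. |
| `overlap_fraction` | 0.20 | — | a signal matches an element when ≥ 20 % of the element is covered *or* ≥ 20 % of the signal lies in the element; closed bound on either fraction. |
| `element_flank` | 100 | nt | elements are extended by 100 nt on both sides (clipped at chromosome ends) before measuring their protomotif support, since coding signals routinely overhang annotated boundaries. |
| `fn_min_protomotifs` | 5 | protomotifs | elements with fewer than 5 supporting protomotifs are binned as undetectable false negatives regardless of any peak-height, the count rule taking precedence over the height bins. |
| `height_bins` | (26, 35) | protomotifs | element discovery bins `< 26`, `[26, 35]` (closed on both ends), `> 35` (strict), mirroring the conventional printed bin labels. |

## Coordinates and frames

Internally everything is 0-based, half-open, expressed on the plus strand;
strand is an attribute, never a coordinate flip, and half-open intervals
sharing an endpoint do not overlap (BED semantics).  Format converters
normalize at the boundary: GFF3 and BLAST tabular are 1-based inclusive
(with `q_start > q_end` encoding minus-strand hits, retained as printed
until `filter_and_map()`), BED and bedGraph are already 0-based half-open.

Reading frames follow the blastx convention.  A plus-strand span starting
at 0-based position `s` is in frame `+((s mod 3) + 1)`; a minus-strand span
with exclusive end `e` on a chromosome of length `L` is in frame
`−(((L − e) mod 3) + 1)` — the frame index counts the codon offset on the
reverse complement.  For an annotated CDS the phase shifts the anchor:
first in-frame codon start `start + phase` (plus) or rightmost base
`end − phase` (minus).  The test suite verifies this arithmetic two
independent ways: against an explicit six-frame codon enumeration, and
against the `qframe` column reported by a real blastx run on a fixture.

## Signal extent: threshold-run vs support-run

The method's definition of a peak's *height* is unambiguous; its lateral
*extent* is not.  Two semantics are provided:

* **threshold-run** (default for `call_coding_signals()`): the signal is
  the maximal run with `D(p) ≥ H`.  Extents are deterministic and shrink
  as `H` rises, but a peak with an internal dip splits into several
  signals at thresholds above the dip.
* **support-run**: the signal is the maximal run of non-zero depth whose
  internal maximum reaches `H` — the whole peak, scored by its height.

`sweep_thresholds()` defaults to **support-run**, deliberately diverging
from the calling default.  Under support-run a peak is an entity whose
extent does not depend on the threshold being swept, so raising `H` only
removes peaks and the TP/FP counts and recall are exactly non-increasing —
the property a threshold sweep is meant to display.  Under threshold-run
that monotonicity is demonstrably false (splitting inflates the TP count
through the middle of the sweep), which we verified empirically before
fixing the sweep default.  Users who want threshold-run sweeps can pass it
explicitly and should expect non-monotone signal counts.

Two related bookkeeping choices: a signal's `n_protomotifs` counts
protomotifs *intersecting* it (not fully contained — containment would
undercount the flanks that low-score alignments routinely overhang), and
the frame-distribution matrix counts one incidence per (protomotif,
overlapped CDS) pair, so a protomotif spanning two CDS records contributes
twice.

## Evaluation conventions

* Strand policy: profiles are intrinsically stranded, so matching defaults
  to `require_match` (unstranded annotation rows match either strand);
  `strand_mode = "ignore"` is the escape hatch, under which an element's
  peak-height is the maximum over both strands.
* Precision counts signals; recall counts elements.  The denominators
  differ by design: one signal spanning two exons is one correct
  prediction that recovers two elements.
* Degenerate inputs: with no signals precision is `NaN` with a warning
  (recall is then 0 if elements exist); with no elements recall is `NaN`.
* Rounding happens only at presentation; all comparisons are exact
  integer/rational arithmetic on interval lengths.

## Negative controls

The reversed-sequence control is implemented as literal character reversal,
not reverse complementation: reversal destroys codon structure on both
strands, whereas a reverse complement merely moves the sense-strand signal
to the opposite strand and would still accumulate protomotifs.  A
`revcomp` mode is available for users who want the weaker control.  The
shuffle control is a mononucleotide (uniform permutation) shuffle —
composition is conserved exactly, codon and dinucleotide structure are
randomized — with 100 replicates by default and all randomness derived
from one seed.

## The synthetic fixture generator

`generate_genome()` plants real ORFs (ATG, sense codons, terminal stop) at
chosen strand/frame combinations in i.i.d. uniform background, at least
250 nt apart so flanked elements stay disjoint; `simulate_hits()` draws
Poisson-many hits per planted region (frame equal to the region's true
frame, with probability 0.1 of a same-strand frame shift and 0.01 of the
opposite strand, echoing the empirical observation that off-frame
protomotif mass concentrates on the coding strand), sparse background hits
over the non-coding gaps, and optional dense decoy clusters as a precision
stressor.  Default rates — 600 coding hits/kb with 30–150 nt spans
(piling to peak-heights of order 40–90, the regime where working
thresholds of 26/35 are meaningful), 2 background hits/kb (depth rarely
above 2–3), bit-scores uniform on [30, 100] for coding and [29, 32] for
background hits — were chosen once as a realistic desk-scale regime and
are deliberately simple.

What the fixtures do **not** emulate: sequence-level homology.  The hit
simulator is conditioned on the planted truth, not on the sequence itself,
so it cannot reproduce database-dependent phenomena — the growth of
peak-heights with database size, the bit-score decay of ancient fossils,
low-complexity artifacts, or the residual-hit fraction a real shuffled
query retains against a real database.  Consequently the shuffle-control
invariant on fixtures is exact (zero protomotifs in every replicate, the
simulator emitting coding hits only over planted regions and the control
experiment setting the background rate to zero), where a real database
search would show a small non-zero remainder.  Passing tests therefore
demonstrate the pipeline's mechanics — coordinate handling, frame
arithmetic, pileup exactness, threshold monotonicity, scoring rules — not
the biological discovery power of the method, which only a genome-scale
search against a real database can show.

## Numerical and degenerate-input choices

* Pileup is computed by a difference array (+1 at starts, −1 at ends,
  cumulative sum): exact integer arithmetic, one pass, no floating point.
* Gapped alignments yield spans that need not be multiples of 3; spans are
  used as reported, since pileup semantics only need genomic extent.
* Codons containing `N` translate to `X` and still count toward pileup
  extent; stop codons render as `*` with no ORF splitting.
* A hit's reported frame column, when present, must agree in sign with its
  coordinate orientation; contradictions are an input error naming the
  record rather than a silent repair.
* Empty interval sets, all-zero profiles, empty reports and annotation
  subsets with no members are all defined, tested identities rather than
  errors.

## Problem sizes

The shipped tests run on 10–100 kb fixture chromosomes with 2–8 planted
ORFs and hit reports of a few thousand records; the brute-force oracles
(per-position pileup counting, all-pairs overlap checks, exhaustive
threshold scans) are run at sizes where they complete in seconds.  These
sizes exercise every code path; nothing in the implementation is specific
to them, and the dense per-position profile representation comfortably
handles chromosomes in the tens of megabases.

## Known limitations

* No gene-structure model: signals are intervals, not exon chains; no
  start/stop or splice-site accuracy is measured.
* The dense depth vector trades memory for simplicity (one integer per
  position per strand); genome-scale runs may prefer chunking.
* `run_search_backend()` is a thin convenience wrapper over local BLAST+;
  database construction, clustering and scheduling are out of scope.
* The simulator's statistical simplicity means fixture-based precision and
  recall are upper bounds with no claim about real genomes.
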