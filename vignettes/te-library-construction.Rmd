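---
title: "Building and benchmarking transposable element libraries with TEforge"
author: "TEforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking transposable element libraries with TEforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEforge)
```

## The problem

De novo transposable element (TE) annotation of a newly assembled genome
proceeds in two steps: first a library of family exemplar sequences is
constructed, then the genome is annotated by homology to that library.
Structure-based TE detectors are sensitive but noisy — their raw candidate
sets contain tandem-repeat contamination, short spurious fragments,
elements with shifted boundaries, captured or nested sequence from other
TE classes, and outright cross-class misclassifications. Because the
library is applied genome-wide, any contamination in it is amplified in
the final annotation.

TEforge provides the three ingredients needed to build and evaluate such
libraries reproducibly, with no external data:

1. **A base-pair-resolution benchmarking framework.** A test annotation is
   compared against a curated annotation by partitioning every genomic
   base into TP/FP/FN/TN and deriving six metrics (sensitivity,
   specificity, accuracy, precision, FDR, F1). Working in bp rather than
   per-element avoids double counting and boundary ambiguity.
2. **A multi-stage filtering cascade** that turns raw candidates into a
   clean, non-redundant, classified library.
3. **A TE genome simulator** that plants structurally faithful copies with
   complete ground truth, so both of the above are testable end to end.

A self-contained k-mer seeded homology masker stands in for a
full repeat masker so that the whole cycle — simulate, filter, annotate,
benchmark — runs inside one R session.

## The benchmarking model

Let $T$ be the set of genomic bases covered by curated annotations of the
target classes and $P$ the bases covered by the test annotation. Then

$$\mathrm{TP} = |T \cap P|,\quad \mathrm{FN} = |T \setminus P|,\quad
\mathrm{FP} = |P \setminus T|,\quad \mathrm{TN} = G - |T \cup P|$$

with $G$ the genome length; the four counts always sum to $G$. From these,
sensitivity $= \mathrm{TP}/(\mathrm{TP{+}FN})$, specificity
$= \mathrm{TN}/(\mathrm{TN{+}FP})$, accuracy
$= (\mathrm{TP{+}TN})/G$, precision $= \mathrm{TP}/(\mathrm{TP{+}FP})$,
FDR $= 1 -$ precision, and F1 is the harmonic mean of precision and
sensitivity. A ratio of the form $0/0$ is undefined and is reported as
`NA`, never as 0 — an empty prediction set must not masquerade as a bad
one. Overlap is strand-insensitive, and double-covered bases count once.
`confusionCounts()` implements this with interval arithmetic; the test
suite checks it against brute-force per-base labeling on a thousand
random cases.

Classification consistency is assessed by `misclassificationRate()`: a
base is misclassified when two annotations (or two overlapping records of
one annotation) assign it different TE subclasses (LTR retrotransposon,
TIR transposon, Helitron, non-LTR). Both a reference mode and a
self-consistency mode are provided, and the output records which
definition was used; the reference mode is the default throughout this
package because the simulator supplies trusted class labels.

`classifyCopies()` merges records of one library entry separated by at
most 50 bp into regions and calls a region a *complete* copy only when
its aligned bases exceed 80% of the entry length — strictly: exactly 80%
counts as fragmented.

## The filtering cascade

Raw candidates, partitioned by class (LTR, TIR, Helitron, and optionally
non-LTR), pass two stages. Every removal is logged as
(entry, stage, rule, detail).

**Stage 0 — basic cleaning** (`runStage0()`):

* length: < 80 bp (TIR/MITE) or < 100 bp (other classes) is dropped;
* missing data: more than 50,000 N bases is dropped;
* tandem contamination: `tandemFraction()` > 0.9 is dropped;
* TIR candidates of at most 600 bp are re-flagged as MITEs;
* Helitron candidates must carry the signature 5'-TC...CTRR-3' termini
  (R = A or G), sit in an AT or TT target site, and have a prediction
  score of at least 12 when one is available.

**Stage 1 — advanced filtering** (`runStage1()`), for TIR and Helitron
candidates (LTR candidates are assumed pre-validated by the upstream
structural pipeline and pass through unchanged):

* *terminal copy-number test*: the 60-bp windows centered on each
  boundary (30 bp inside + 30 bp outside) are counted in the genome.
  Since TIR and Helitron termini are short, a candidate called inside
  another abundant repeat shows abundant (>= 20 full-length copies)
  windows. One abundant terminus marks a false positive; with both
  abundant, the 60-bp window centered on the target site (30 bp joined
  from each flank) is counted, and the candidate survives as a *nested*
  true candidate while the terminal count stays below 20,000 times the
  target-site count (clamped to at least 1 to keep the ratio defined).
* *terminal SSR test*: more than 15 of the terminal 20 bp covered by
  simple sequence repeats marks a false element; terminal SSR arrays of
  survivors are trimmed and the class length minimum re-checked.
* *reciprocal richness purification*: for every candidate, homology-based
  richness — total aligned bp over all 80%-identity matches, summed over
  entries so that abundance counts — is computed in its own sublibrary
  and in every other one. A candidate not at least twice as rich in its
  own sublibrary as in some other (non-zero) one is a cross-class
  contaminant and is discarded. All candidates are judged on the frozen
  input state and removals applied simultaneously, making the operation
  order-independent.
* *aggregation, redundancy and nesting removal*
  (`removeNestedRedundancy()`): iterated up to five times with early
  stopping — an entry engulfed by a longer entry under the 80-80-80 rule
  (>= 80% of the query aligned, >= 80% identity, >= 80 bp) *and* covering
  most of that longer entry is redundant and deleted; an entry containing
  an internal copy of a shorter entry has the nested span excised and its
  flanks rejoined. The distinction matters: a short element nested inside
  a long host must be excised from the host yet kept as its own entry,
  so engulfment alone (which the 80-80-80 rule would already flag) is
  deliberately not a deletion criterion.
* *optional CDS cleanup* (`cdsFilter()`): spans matching user-supplied
  TE-free coding sequences at >= 80% identity over >= 80 bp are excised;
  entries reduced below their class minimum are dropped.

All thresholds live in `filterConfig()` and are inclusive exactly as
stated (80 bp passes the length filter, score 12 passes the Helitron
filter, 600 bp is a MITE, 15/20 SSR bases pass, exactly 80% copy coverage
is fragmented).

## The homology engine

`maskGenome()` is a deliberately small stand-in for a production repeat
masker, not a reimplementation of one: exact shared k-mers (default 13)
seed a greedy extension that tolerates mismatches and single-base gaps,
stops by an X-drop rule, and trims back to the score maximum. Collinear
fragments to the same entry separated by at most 50 bp are merged. Hits
are kept up to 40% divergence — the conventional ceiling for
homology-based TE annotation — at a minimum length of 80 bp and a score
threshold on `matches - penalty * (mismatches + gaps)`, with the penalty
`(1 - maxDivergence)/maxDivergence` chosen to break even exactly at the
divergence ceiling: any sufficiently long hit within the ceiling scores
positively, the way a repeat masker's divergence-adjusted scoring
matrices behave, while short noisy hits fall below the default cutoff
(calibrated so an 80-bp hit at exactly 80% identity passes). Overlaps are resolved
deterministically (score, then length, then entry name); losers are
trimmed to their non-overlapping remainder and kept if still >= 80 bp.
Whitelisted intervals receive no records, so re-masking with a previous
result whitelisted returns nothing — a property the tests exercise.

The same engine backs `copyNumber()` (non-overlapping genomic hits
covering >= 95% of a query at >= 80% identity), `matches808080()` (the
80-80-80 homology rule, with coverage allowed to accumulate over
collinear local alignments, since fragmented homology is the norm for
diverged TEs), the richness matrix, nested-span detection and CDS
excision. Identity is computed over aligned columns, so unaligned chain
gaps dilute neither identity nor score. The `tandemFraction()` and
`ssrSpan()` detectors are independent of it: tandem arrays are found by
k-mer self-distance periodicity (periods 1-500 bp, >= 2 copies, >= 80%
array identity over a window of at least 12 bp — the window floor keeps
single-base chance matches from counting as period-1 arrays), SSRs by
exhaustive perfect-array scanning (motifs of 1-6 bp, >= 3 copies, >= 6 bp).

## The simulator and what it does (not) emulate

`makeExemplars()` builds one exemplar per family with class-diagnostic
structure: LTR elements begin TG and end CA with identical long terminal
repeats (>= 100 bp) at both ends and receive a 5-bp target-site
duplication (TSD) on insertion; TIR elements carry exact
reverse-complement terminal inverted repeats of 12-28 bp and
superfamily-specific TSD lengths (hAT 8 bp, CACTA 3 bp, Mutator 9 bp,
PIF 3 bp, Tc1 2 bp; MITE families use Tourist 3 bp / Stowaway 2 bp and
stay below 600 bp); Helitrons begin TC, end CTRR, carry a GC-rich
stem-loop within the final 30 bp, insert at AT/TT host dinucleotides and
leave no TSD; LINEs and SINEs end in a poly-A tail.

`simulateGenome()` places copies sequentially on i.i.d. background
(GC 0.43): each copy is substituted at the configured divergence and
indel-mutated, possibly truncated (20-80% off one end), then inserted
either into background or — with the nesting probability — inside a
previously placed TE, splitting that host's truth record in two exactly
as a curator would represent a nested insertion. TSDs are duplicated
exactly and then subjected to the same substitution process as the
element. One pseudo-random stream per operation, seeded from the config
seed, makes every product byte-reproducible.

Default study conditions: one 500-kb chromosome, five families per class,
3-8 copies per family, 10% divergence, 1% indels, 10% nesting, 20%
truncation. These describe a compact, recently active, plant-like TE
landscape: small enough to run in seconds, large enough that every
filter sees real work. Divergence sits well below the 40% masker ceiling
because library construction targets recently active families — and
because structure-based detectors can only find copies whose diagnostic
termini survive, substitutions (not indels or truncation) spare the few
class-diagnostic terminal bases by default (`preserveTermini`), mirroring
that ascertainment.

`makeNoisyCandidates()` emits what a well-behaved structural detector
would return — one candidate per intact, uninterrupted copy, with 60-bp
flanks and (for Helitrons) a prediction score — and then plants the
configured corruptions: pure tandem arrays, short (< 80 bp) fragments,
terminal-motif-violating Helitron candidates cut from random genomic
intervals, cross-class mislabeled copies, boundary-shifted copies, and
candidates spanning a nested pair (the sequence-capture route by which
real stage-0 libraries acquire misclassified bases). Every candidate is
tagged with its corruption type, so filter behaviour is assertable
against the tags. Mislabels are drawn from distinct families with at
least four intact copies — abundant families being the usual source of
cross-class confusion — which also keeps the richness test's
denominators meaningful.

What the simulator does *not* emulate: realistic substitution matrices or
rate heterogeneity, solo-LTR formation, transduplication of host genes,
segmental duplications, low-complexity background, or assembly artifacts
beyond N handling. Passing tests therefore demonstrate the correctness
and internal consistency of the operations on structurally faithful
data, not performance on a real genome, where divergence structure and
repeat landscapes are far messier.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed throughout (the GRanges convention);
  BED's 0-based half-open system exists only at the I/O boundary, and
  GFF3 carries `Name`, `Classification` and `Identity` attributes.
* Ambiguity codes other than N are folded to N with a warning rather
  than rejected; residues outside the IUPAC alphabet are format errors.
* Overlap-resolution ties break by score, then hit length, then entry
  name; all cascade loops run in fixed name order — identical inputs
  give identical outputs including log order.
* The terminal copy-number ratio test clamps a zero target-site count to
  1, since the target-site window of a genuinely nested candidate can be
  unique in the genome.
* Candidates whose terminal windows would extend beyond the contig are
  kept with verdict `unevaluated` (with a warning) rather than silently
  judged on truncated windows; unanchored candidates are treated the
  same way.
* Empty genomes mask to empty annotations; empty candidate classes pass
  through with a warning; a metric whose denominator is zero is `NA`.

## Problem sizes used in the tests

The bundled tests run the full cycle at the default 500-kb study
conditions (and the filter cascade with 12 plants of each corruption
type plus 8 nested-span and 8 boundary-shifted candidates), the
metric-oracle comparison on 1,000 random genomes of up to 10 kb, and the
boundary checks on constructed sequences. On these sizes the whole suite
completes in a few minutes on one core; all sizes are ordinary function
arguments, so larger experiments only need a different `simConfig()`.

## Known limitations

* The masker's greedy extension is not an optimal local aligner; hit
  boundaries can be off by a few bases at high divergence, and heavily
  gapped homology (beyond occasional single-base indels) is outside its
  design envelope. For production annotation a dedicated masker should
  be used — the package's formats are interoperable by construction.
* Richness purification is a deterministic ratio test (default 2x), not
  a statistical test; with sublibraries of only one or two related
  entries its denominators are weakly informed, and a true family with a
  single copy and a cross-class twin can be lost.
* Protein-space homology (for gene cleanup) is out of scope; the CDS
  filter works in nucleotide space.
* Non-LTR elements receive no structural validation beyond the poly-A
  tail the simulator plants; like the class filters, this mirrors the
  current state of structure-based LINE/SINE detection.
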