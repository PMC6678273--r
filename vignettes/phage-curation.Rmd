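---
title: "Rubric-based curation of phage genome annotations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rubric-based curation of phage genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageCurate)
```

## The model

Phage gene annotation is treated here as two sequential decisions over a
fixed candidate universe.

**Gene identification.** The universe is every open reading frame longer
than a minimum length (default 76 bp, i.e. strictly longer than 75 bp —
phage proteins as short as ~27 aa are known) on either strand. An ORF is a
stop-to-stop frame segment reported from its 5'-most permitted start codon
through its stop codon, with the stop included in its length, and is
identified by its *stop anchor* (3' coordinate + strand). The identification
decision integrates five independent evidence sources into an additive
integer score; a gene is kept at a total of 3 or more, discarded at 0 or
less, and flagged for human review in between. The asymmetric thresholds
encode a structural assumption: overlap and length are *penalty-only*
criteria (maximum joint contribution +1, from an operon junction), so no
gene can be kept without at least some support from caller consensus,
coding potential, or sequence similarity.

**Start selection.** Conditional on keeping a gene, one start codon is
chosen from the in-frame candidates between the previous in-frame stop and
the gene's stop. The criteria are applied as strict lexicographic filters,
in decreasing order of importance: (1) retaining the full coding-potential
plateau, (2) overlap plausibility — candidates with more than ~100 bp of
overlap are removed and operon-forming candidates (exact 1/4/8 bp
stop/start overlap) are privileged, (3) caller votes for that exact start,
(4) start-specific similarity matches, (5) Shine–Dalgarno score, (6) longest
resulting gene without more than 10 bp of overlap. Lexicographic (rather
than weighted-sum) combination is the one reading consistent with the
worked precedent we reproduce in the tests: a candidate with two caller
votes beats one with a single vote *despite* the latter having twice the
similarity matches, so votes must dominate similarity outright.

The whole engine is deterministic: identical inputs and configuration give
identical outputs, and `select_start()` is invariant to the order in which
candidate rows are supplied.

## Assumptions and scope

* Gene callers are treated as black boxes; their calls are *inputs* (TSV or
  GFF3). The package never runs Glimmer/GeneMark/Prodigal/PHANOTATE.
* Coding potential is consumed as a per-position, per-frame posterior track
  in [0, 1], as produced by the posterior decoding of an HMM gene finder.
  No standard machine-readable format exists for these tracks (they are
  usually published as figures), so the TSV layout here
  (`position`, `frame` 1–6, `posterior`) is this package's own.
* Shine–Dalgarno scores are inputs, not computed: the scoring matrices of
  the conventional desktop tool (Kibler6 / Karlin Medium) are not publicly
  specified. A gene forming an operon junction ignores SD entirely — a
  co-transcribed gene needs no ribosome-binding site of its own.
* Genomes are single replicons over unambiguous ACGT. Ambiguity codes and
  multi-contig assemblies are out of scope; circular replicons are
  supported but off by default, since reference phage genomes are deposited
  linearised.

## Parameters

All tunables live in one validated object, `rubric_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `min_orf_len` | 76 | bp | "longer than 75 bp" as a strict inequality |
| `start_codons` | ATG, GTG, TTG | — | standard bacterial/phage start set; the source guidelines are silent, so it is configurable |
| `coding_high` | 0.75 | posterior | threshold for "high" signal |
| `coding_sustain` | 0.5 | fraction of ORF | threshold for "sustained" signal |
| `coding_low` | 0.25 | posterior | "low but sustained" floor; nothing in the guidelines pins this down, so it is exposed and stamped into output provenance |
| `sim_sig`, `sim_mid`, `sim_strong` | 1e-10, 1e-20, 1e-50 | E-value | half-open significance bins; E-values in [1e-20, 1e-10) score 1 point, matching the worked example where 1e-13 contributes 1 |
| `overlap_bins` | 10, 40, 70, 100 | bp | left-closed penalty bins: [10,40) → −1 … [100,∞) → −4 |
| `operon_overlaps` | 1, 4, 8 | bp | exact stop/start junction lengths indicating co-transcription |
| `divergent_gap` | 50 | bp | promoter room required between facing 5' ends |
| `length_bins` | 90, 120, 150, 200 | bp | right-closed penalty bins: (150,200] → −1 … (0,90] → −4 |
| `keep_thresh`, `discard_thresh` | 3, 0 | points | keep/discard cutoffs |
| `large_overlap` | 100 | bp | start-candidate disqualification ("e.g., over 100 bp" is treated as a default, not a law) |
| `sd_tie_tol` | 0.1 | score units | SD scores this close are tied; SD is a late, soft criterion and sub-0.1 differences are not meaningful |
| `anchor_programs` | (unset) | — | the two callers whose joint calls define "strong" genes |

## Numerical and tie-breaking choices

* **Bin boundary inclusivity.** The guidelines write "between 10 and 40 bp"
  without saying which endpoint is included. Overlap bins are half-open on
  the left and length bins half-open on the right; this is the unique
  deterministic choice consistent with all three worked scoring rows
  (43 bp → −2, 153 bp → −1, 99 bp → −3) and is frozen in the acceptance
  tests. Boundaries remain configurable.
* **Worst overlap, not summed overlap.** A candidate overlapping two strong
  calls is binned on the *maximum* single overlap: the spreadsheet has one
  Overlap column per gene, and summing would double-penalise a gene wedged
  between neighbours.
* **Overlap among putative genes is not scored.** Within a coding gap it is
  unknown which putative genes survive, so mutual overlap there contributes
  nothing; only strong calls (both anchor programs agreeing on a stop) form
  the reference frame.
* **Divergent rule.** The guidelines require ≥50 bp between the facing 5'
  ends of a head-to-head pair but prescribe no score. The minimal
  mechanisation adopted: the shortfall (`50 − gap`, floored at 0) is binned
  exactly like overlap. It only ever penalises; it never awards points.
* **Overlap/gap bookkeeping.** The start-selection arithmetic (+1 for
  overlaps, −1 for gaps after the coordinate subtraction) makes gap
  magnitudes 2 bp larger than the intergenic base count. The formula is
  implemented verbatim because it is only used comparatively;
  `divergent_pair_table()` therefore reports the bookkeeping value *and*
  the geometric 5'-to-5' gap side by side, and the promoter-rule flag uses
  the geometric gap (≥50 bp passes, a 50 bp gap is a boundary pass,
  overlapping 5' ends always fail). The printed-formula sign convention is
  internally ambiguous between the two orientations described in the
  source guidelines; exposing both numbers avoids guessing intent.
* **Missing SD scores** compare as worst. If every surviving candidate is
  operon-forming, the SD criterion is skipped entirely.
* **Degenerate inputs.** An ORF with no start candidates is simply not an
  ORF here (the segment is dropped at enumeration). `select_start()` on zero
  rows errors. Plateau ties break towards the 5' end of the gene. A fully
  tied candidate set falls through to the longest-gene rule and then to the
  smallest coordinate, keeping the result permutation-invariant.
* **Rounding** to the nearest 0.5% (half-up) is presentation-layer only;
  stored metrics are unrounded.

## Design decisions where the source was open

* **Gene identity is the stop anchor.** Callers disagree on starts
  constantly but share stops; counting programs per exact interval would
  understate consensus and break the separation between gene
  identification and start selection. Nested genes with distinct stops are
  therefore scored independently.
* **The printed worked-example rows are trusted over their coordinates.**
  Two of the three published example rows have lengths inconsistent with
  their own coordinate pairs (a 373–495 span printed as 204 bp; a
  2189–2391 span printed as 153 bp) — evidently transcription errors. The
  acceptance fixtures synthesise coordinates that match the printed
  *evidence columns*, which are what the rubric consumes.
* **The similarity start-offset anchor.** "Matches that use that start
  codon" needs an anchor to be machine-checkable. The offset is stored
  relative to the ORF's 5'-most candidate (the one well-defined start
  before any selection happens); a match supports candidate *c* when the
  anchor shifted by the offset lands on *c*.
* **The function bonus requires a significant match.** A gene whose only
  known-function hit fails the significance threshold earns nothing;
  otherwise a 0-point similarity column could acquire a bonus from noise.
* **Borderline totals (1–2) are never auto-resolved**; they are emitted
  with a review flag, mirroring the case-by-case instruction of the manual
  workflow.
* **TN universe.** Published benchmark tables imply a specific non-coding
  ORF universe (545 for one genome, 628 for the random sequence) that
  depends on unstated choices of start-codon set and stop inclusion; those
  counts are not reproducible exactly under any single parameterisation.
  The package therefore defines the universe *operationally* as its own
  `find_orfs()` output, and the metric formulas are tested directly against
  the published confusion counts instead — separating formula correctness
  from ORF-definition ambiguity. Relatedly, one published specificity value
  (99% printed where the counts give 99.27% → 99.5% under the caption's own
  rounding, while an identical count pair elsewhere prints 99.5%) is
  treated as an erratum and excluded; three values printed at 0.1%
  precision (99.9%) cannot be multiples of 0.5 and are compared after
  applying the same rounding to both sides.

## What the simulator does and does not establish

`plant_genome()` draws coding regions from a fixed biased codon
distribution (interpolated towards uniform by `codon_bias_strength`) and
intergenic sequence uniformly; it plants exact 1/4/8 bp operon junctions
and one divergent pair with 60 bp promoter room. `mock_program_calls()`,
`mock_coding_track()` and `mock_similarity()` emulate caller dropout
(`fn_rate`), spurious calls (`fp_rate` over decoy ORFs), 3'-ward in-frame
start perturbation, the four qualitative coding-potential classes, and
log-uniform E-values, all from named sub-streams of one seed.

Default rates in the recovery tests — 4 pseudo-callers, 10% dropout, clean
track and similarity — describe a *stated world*, deliberately easier than
real genomes: real coding potential has sloped flanks and frame bleed, real
callers make correlated errors, and real homology evidence is patchy and
redundant. A green recovery test (aggregate sensitivity ≥95%, specificity
≥99% over ten 20 kb fixtures, perfect start recovery under clean evidence)
establishes that the *engine* implements the rubric faithfully and loses no
information end to end — not that the rubric achieves those numbers on real
phages. Conversely, the random-genome generator gives a universe with no
true genes at all, exercising the false-positive path: with no evidence
loaded, no ORF can ever reach the keep threshold, which the tests assert as
an invariant.

## Known limitations

* Mutually overlapping putative genes inside one coding gap are all scored
  independently; the package does not arbitrate among them (the manual
  workflow defers this too).
* Genes-within-genes sharing a stop anchor collapse to one candidate.
* The GenBank reader is a minimal CDS feature-table parser (no offline R
  package parses GenBank flat files); compound `join(...)` locations
  collapse to their outermost coordinates with a warning.
* Circular-genome ORF frames are reported relative to the doubled-sequence
  scan; coordinates of origin-spanning ORFs extend past the genome length
  rather than wrapping.
* The optional SD convenience path only reads externally computed scores;
  no anti-SD complementarity scoring ships in the scored pipeline.
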