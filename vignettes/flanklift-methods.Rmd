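---
title: "Flank-anchored SNP lift-over: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flank-anchored SNP lift-over: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flanklift)
```

## The problem

When a reference assembly is updated — scaffolds anchored, reoriented,
relocated, small ones discarded — every coordinate-based resource built on
the old version becomes stale.  Classic lift-over tools (UCSC liftOver,
CrossMap, Picard LiftoverVcf) need a *chain file*, a precomputed whole-genome
pairwise alignment, which is expensive to build for large repeat-rich plant
genomes.  `flanklift` instead treats each SNP as the single-base *child* of a
flanking *parent* window: the parent (SNP ± L bases, 2L+1 bp) is aligned to
the whole target assembly, and the child's target coordinate is read off the
alignment's coordinate map.  The idea follows annotation lift-over tools that
project parent/child feature hierarchies by aligning the parent only.

Reliability comes from repetition rather than from a global alignment: the
lift is run at several flank lengths (defaults 500, 1,000, 1,250, 1,980 bp)
and only SNPs projected to the *identical* (chromosome, position, strand) at
every length are retained.  The 1,980 bp default corresponds to half of a
typical average transcript length (a 3,961 bp parent) — a proxy for the
expected extent of locally conserved sequence; the shorter lengths probe how
stable each projection is to the amount of context given to the aligner.
A flank disagreement flags exactly the situations a chain file would have
hidden: repeats, paralogous copies, breakpoint-adjacent context.

## The projection engine

The engine is a classical seed–chain–extend aligner:

1. **Seeding.** Exact-match k-mers (k = 15) of the target are indexed once
   (every 4th position); parent k-mers (every 5th) are looked up on both the
   forward parent and its reverse complement.  K-mers occurring more than
   `max_occ` (64) times in the target are skipped — a seed-level repeat
   filter.
2. **Chaining.** Seeds are grouped per (sequence, strand) into colinear
   clusters: diagonals may drift up to the band half-width (32), and gaps
   along one diagonal may not exceed twice the parent length.  At most 16
   clusters per strand are extended.
3. **Extension.** Each cluster is extended into a *fitting* alignment —
   parent global, target window local — by a banded affine-gap (Gotoh)
   dynamic program around the centre line interpolated through the chained
   seeds.  Scoring: match +1, mismatch −1, a gap of length L costs
   `gap_open + gap_extend · L` = 2 + L.  This convention was chosen to be
   identical to `Biostrings::pairwiseAlignment(gapOpening = 2,
   gapExtension = 1)`, which the test suite uses as an independent oracle.
   When a cluster sits on a single diagonal and the implied target substring
   equals the parent exactly, the alignment is emitted directly (a memcmp),
   which makes identity lifts cheap.
4. **Choice.** Placements below 50% identity or 50% coverage are discarded
   (mirroring the documented defaults of the annotation lift-over tool this
   design follows; the source publication does not restate them).  The best
   placement must beat the runner-up *strictly* (configurable margin);
   equal-best scores at different loci are an ambiguity and the SNP is left
   unlifted.  Ties are resolved deterministically by sorting on
   (score desc, chromosome, start, strand) first.
5. **Child walk.** The coordinate map (match / insertion-to-target /
   deletion-from-parent runs) is walked until the child offset is consumed.
   A child falling in a deletion, or in a clipped end, yields no coordinate:
   we deliberately do **not** snap to the nearest surviving base — a
   fabricated position is worse than a missing one.

The whole target is searched (no chromosome-to-chromosome restriction), so
SNPs can move across chromosomes or onto newly anchored scaffolds; that
movement is *reported* via transition classes (`same_chrom`, `diff_chrom`,
`un_to_anchored`, `anchored_to_un`, `un_to_un`), with unanchored sequences
recognised by a configurable name prefix (default `"chrUn"`).

### Consensus and strand policy

"Same location" is interpreted strictly as identical (chromosome, position,
strand): a plus/minus disagreement at one coordinate signals an unreliable
region, so it counts as inconsistent.  SNPs where at least one flank length
failed to lift are `incomplete` and excluded — the strictest reading of the
all-flank-lengths rule.  The three statuses partition the input
(`consistent + inconsistent + incomplete = n`), which the tests assert on
every run.

Input SNP sets conventionally carry plus-strand alleles, so all input
features are labelled `+`.  Consistent minus-strand lifts are genuine
(inverted or reoriented segments); the default policy (`drop_minus`)
excludes them from the final VCF, reproducing the usual final-dataset
definition, while `rescue_minus` keeps them with reference and alternate
alleles complemented and the strand recorded in INFO.  Both are offered
because complementing alleles is the standard alternative; the default was
chosen to match the published practice of reporting the plus-strand set.

## The synthetic assembly-update simulator

The simulator is first-class, tested code — the oracle the real data lacks.
`generate_source()` draws i.i.d. bases at a given GC fraction (default 0.45,
a typical plant-genome value) for named chromosomes plus `chrUn_*`
scaffolds.  An edit script then emulates an assembly update with the
operation vocabulary of real assembly revisions: segment inversion, segment
relocation across chromosomes, anchoring of an unanchored scaffold into a
chromosome, dropping a scaffold, small indels, and uniform point divergence.
Every surviving source base keeps an exact target image in a piecewise
*truth map*; substitutions never alter the map, indels shift it within a
piece, dropped bases are unmapped.

What the generator does *not* emulate: repeat families, transposon nests,
segmental duplications, GC heterogeneity, exome-like SNP clustering.  A
green test therefore establishes coordinate-arithmetic and consensus
correctness under realistic *structural* change, not robustness to wheat-like
repeat content.  An optional tandem-duplication knob was considered and
rejected for the default worlds: ambiguity behaviour is exercised directly
through `choose_best`'s tie contract instead.

Defaults that define the tested world, chosen once and not tuned:
substitution divergence 0.005/base (well inside the 0.5 identity threshold —
two updates of one cultivar differ far less); the breakpoint-adjacent
exclusion zone in `evaluate_lift()` equals the longest default flank
(1,980 bp), since a SNP closer than one flank length to a structural
breakpoint can legitimately fail the consensus; the structural acceptance
world uses a ~5.15 Mb genome (3 chromosomes, 3 scaffolds) with 2,000 planted
SNPs and one op of each structural kind, sizes the criteria text left open.

## The effect classifier

A minimal re-implementation of the transcript-relative categories that
variant annotators report; it is not a full annotator (no indels, no MNVs,
no HGVS, no canonical-transcript logic).  Region precedence, most specific
first: splice donor (first 2 intronic bases of an intron in transcript
orientation) → splice acceptor (last 2) → splice region (intronic bases 3–8
or exonic bases 1–3 from a junction) → 5′/3′ UTR → exon → intron →
up/downstream (within 5,000 bp, sides per transcript strand) → intergenic.
The 5 kb window and the 3–8/1–3 splice-region convention follow the
annotation tool this classifier mirrors; both are configurable.  "Nearest
transcript" is implemented as *all* transcripts within the window — one SNP
near two isoforms yields two effects, which is why effect counts exceed SNP
counts.  UTR bases are disjoint from "exon" in the summary (the category
tables of annotation tools are ambiguous here; this choice is documented and
asserted in tests).  One effect row is emitted per (SNP, transcript,
alternate allele).

Coding effects translate the reference and substituted codon with the
standard genetic code (minus-strand transcripts via reverse complement):
`start_lost` (codon 1 loses ATG) takes precedence, then `stop_gained`,
`stop_lost`, `synonymous`, else `missense`.  Exonic bases 1–3 from a
junction classify as splice region, so a CDS variant there reports no coding
effect — the documented cost of a strict precedence.  Impact buckets:
high = start/stop effects and splice donor/acceptor; moderate = missense;
low = synonymous and splice region; modifier = everything else.  A
whole-CDS translate-and-diff oracle cross-checks 1,000 random point
mutations in the tests.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive at every file boundary (VCF, GFF3,
  truth TSV) and 0-based half-open internally; the two converters are
  inverses (property-tested).
* SNPs whose reference base is not A/C/G/T are skipped on read with reason
  `ambiguous_ref`: alignment anchoring through N runs is unreliable.
* Flank windows are clamped at sequence ends and *lifted anyway* with a
  truncation flag propagated to the output INFO (`LV_TRUNC`); windows
  shorter than the 100 bp alignability floor are emitted but never aligned
  (`too_short`).
* Parents whose every placement fails the identity/coverage thresholds are
  `unlifted_below_threshold`, distinct from `unlifted_no_alignment`.
* The banded extension can in principle miss an optimum that leaves the
  band (indels larger than the 32-base half-width); simulator indels
  default to ≤ 10 bp.  The defensive traceback aborts (placement rejected)
  rather than returning a corrupt map if the path leaves the band.
* All randomness is seed-scoped: generators save and restore the caller's
  RNG state, so library code never perturbs a session's random stream.

## Design decisions that were genuinely open

* **Parent windows include the SNP base** (2L+1): the child must be a
  sub-interval of the parent for the coordinate walk to be defined.
* **One GFF3 file per flank length** when exporting features (the
  alternative — one combined file — makes the per-flank consensus
  comparison awkward for downstream scripts).
* **Exact score ties are unlifted**, not resolved by copy-number heuristics:
  with repeat-rich targets the consensus filter, not the aligner, is the
  arbiter of reliability.
* **Genotype columns are opaque**: carried through verbatim, never parsed.
  Nothing in the lift changes a genotype call.
* **Single process.** A worker-count option was considered and dropped:
  results are deterministic and serial; the original 16-way file split it
  would have emulated was a cluster convenience, not method.
* **External aligner backends** are declared in the configuration surface
  (`aligner = "internal"`) but only the internal engine is implemented and
  tested; the Placement contract is the seam a mapper backend would plug
  into.

## What the acceptance checks establish

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch:
self-lift identity on a 10 Mb genome with 10,000 SNPs (100% consistent,
position-exact, plus-strand expected); zero mis-lifts and correct transition
labels under a structural edit script; ≥ 99% exact recovery under 0.5%
divergence; the consensus subset property across flank sets; engine/oracle
equivalence of the child projection on 200 random pairs; effect-classifier
agreement with enumeration and a translation oracle; and the counting
identities.  Each number in the report is computed at run time by the
installed package — nothing is looked up.

## Known limitations

* Repeat-rich genomes will push many SNPs into `unlifted_ambiguous`; that is
  the intended behaviour of the consensus design, not an error, but the
  simulator's i.i.d. background understates how often it happens in practice.
* Coverage counts clipped parents simply (aligned span / parent length);
  heavily gapped placements near the 0.5 threshold can flip between flank
  lengths, which the consensus then rejects as incomplete.
* The effect classifier intentionally reports no coding effect for CDS
  variants inside exonic splice-region bases (precedence), so counts of
  synonymous/missense variants are floor estimates near junctions.
* `read_vcf` materialises the file in memory; at the scale this package
  targets (millions of rows) that is a few GB — acceptable, but a chunked
  reader would be the first optimisation for larger sets.
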