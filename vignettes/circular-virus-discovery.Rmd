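---
title: "Discovering circular DNA viruses in assembly contigs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering circular DNA viruses in assembly contigs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circvirome)
```

circvirome reconstructs and characterises small circular DNA virus genomes
— papillomaviruses (~8 kb, double-stranded) and CRESS-DNA viruses (~1.7–3
kb, single-stranded, rolling-circle replicating) — from the contigs a de
novo metagenomic assembler emits. This vignette explains the models behind
each step, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the design choices made where
more than one reasonable convention exists.

## Terminal redundancy and circularization

Most metagenomic assemblers have no notion of a circular replicon. When the
template is circular, the assembler walks around the circle and stops after
overshooting its starting point, so the contig carries an exact duplicate
of its beginning at its end ("identical 3' and 5' ends"). `circularize()`
exploits this signature in three steps per contig:

1. **Low-complexity truncation.** Expanded tandem repeats (classically a
   `GTGT...` dinucleotide run) are an artefact of amplification and
   assembly and can mask the terminal redundancy, so maximal perfect
   tandem repeats with unit length ≤ 2 and span ≥ `min_run = 20` nt are
   excised *before* overlap detection. The 20-nt default is a judgement
   call — long enough that a chance run is essentially impossible
   (P ≈ L·4·4^-19 per genome for homopolymers), short enough to catch any
   run one would call "extensive" at dinucleotide scale.
2. **Overlap detection.** The largest `k` with
   `min_overlap ≤ k ≤ max_overlap_frac·L` whose prefix equals its suffix
   exactly. Mismatches are not tolerated: end duplication by the assembler
   is a copy, not a homologous alignment. `min_overlap = 10` bounds the
   chance of a spurious call at ~`4^-10` ≈ 10⁻⁶ per contig;
   `max_overlap_frac = 0.5` keeps the two copies disjoint. An optional
   `unique_ends` mode additionally requires the terminal k-mer to occur
   exactly twice, for pipelines that discard contigs with ambiguous ends.
3. **Canonical representative.** A circle is only defined up to rotation
   and strand, so comparisons need a unique representative:
   the lexicographically least string over all rotations of the sequence
   and of its reverse complement. This is deterministic, O(L) in practice,
   and makes "same circle" testable with `identical()`.

The trimming convention removes the *first* `overlap_len` bases (the 5'
copy). Removing the 3' copy instead gives a rotation of the same circle
and is indistinguishable after canonicalisation.

Contigs with more than 5% `N` are reported with a `high_n` flag and not
analysed; bases are uppercased and `U` mapped to `T` on input. All
coordinates are 0-based half-open internally; only GFF3 output is 1-based
inclusive, per that format's definition.

## Stem-loop origin scanning

CRESS-DNA viruses initiate rolling-circle replication at a conserved
nonanucleotide motif (canonically `TAGTATTAC`) presented in the loop of a
hairpin. The scanner is a composition of two searches:

* `find_nonamer_sites()` reports every 9-mer within `max_mismatch` Hamming
  distance of the canonical motif, on both strands, wrapping the
  breakpoint. The default budget of one mismatch admits the widely
  observed `TAGTATTAA` variant, which differs from the canonical motif
  only at the ninth position. Minus-strand sites are reported at their
  plus-strand interval start, so downstream arithmetic never needs
  strand-specific coordinates.
* `detect_hairpin()` models the hairpin as a **perfect inverted repeat**:
  two arms that are exact reverse complements, enclosing an unpaired loop
  that must contain the whole nonamer. Among qualifying hairpins the
  longest arm wins, ties go to the smaller loop and then the leftmost.
  Defaults (`min_arm = 5`, `max_arm = 20`, `max_loop = 15`,
  `window = 40`) bracket with margin the geometry of the origin exemplar
  this model was calibrated on — an 11-bp stem around an 11-nt loop.

A thermodynamic folding model (mfold-style free-energy minimisation) would
admit wobble pairs and bulges. We chose the perfect-stem model because it
is exactly testable against a brute-force inverted-repeat enumeration, has
no temperature or energy parameters, and the canonical origin exemplar is
itself a perfect stem. Wobble tolerance would require a scoring threshold
with no principled setting at this scale; hairpins with imperfect stems are
a known blind spot and are documented as such. Note also that a hairpin is
strand-symmetric — the reverse complement of a stem-loop is a stem-loop —
so hairpin detection runs once on plus-strand coordinates for sites from
either strand.

## Circular-aware ORF calling

`find_orfs()` scans six frames for `ATG`-to-stop ORFs (stop included in
the length). Two conventions matter and both are configurable:

* **Nested starts are suppressed**: per (stop codon, strand) only the
  longest ORF — the first `ATG` after the previous in-frame stop — is
  reported. This matches the common ORF-finder behaviour and keeps ORF
  counts stable under parameter changes.
* **`min_len = 300` nt** by default, the conventional cutoff for
  annotating small circular virus genomes ("ORFs larger than 300
  nucleotides"); "larger than" is read as ≥ 300 with the stop codon
  included. The same default applies to papillomavirus-sized and
  CRESS-sized genomes; it can be lowered per call.

Circularity is handled by scanning a tripled linearization: every ORF of
length ≤ L appears there as a contiguous in-frame run, and restricting
reported starts to the middle copy guarantees (i) full upstream context, so
the previous-stop rule is evaluated correctly even when L is not a
multiple of 3 and the reading frame "rotates" through the breakpoint, and
(ii) exactly one report per circular ORF. No ORF may exceed one full turn
(no multi-wrap). A `stop_stop` mode drops the start-codon requirement and
reports whole stop-bounded frames; this is how start-less ORFs (such as
papillomavirus E4, conventionally found with frame-translation tools) can
be recovered. ORFs are reported positionally; assigning gene names (E1,
L1, ...) requires homology evidence and is out of scope.

Minus-strand ORFs are reported in the coordinates of the
reverse-complemented linearization — the natural frame for their protein —
and `orfs_to_gff3()` converts to plus-strand 1-based intervals, splitting
breakpoint-wrapping features into two `CDS` lines with a shared `ID`, as
GFF3 prescribes.

## Pairwise identity and demarcation

`global_align()` is a Needleman–Wunsch global alignment with affine gaps
(Biostrings' aligner under the hood). Defaults: nucleotide match +1,
mismatch −2, gap open −10, gap extension −1 per gapped position; proteins
use BLOSUM62 with the same gap penalties.

The identity definition is stated prominently because it shifts reported
values by a few points and the field is not consistent about it:

> identity_pct = 100 × (columns where both rows carry the same residue) /
> (total alignment columns)

i.e. **every gap column counts against identity**, the convention of
SDT-style all-vs-all matrices used in virus classification. Protein
*similarity* is reported separately: columns whose residue pair scores
positively in BLOSUM62, over all columns.

`classify_papillomavirus()` applies the standard L1 demarcation rule to
the divergence d = 100 − identity to the closest reference: d > 10 → new
type; 2 ≤ d ≤ 10 → new subtype; d < 2 → variant. The boundaries follow the
rule's wording ("more than 10%", "less than 2%"): both 2 and 10 fall in
the subtype band. The function does not check that its inputs are L1
genes — that is deliberate, since the same machinery is useful for Rep
proteins and whole genomes, but the thresholds are only meaningful for L1.

`sliding_window_identity()` works on a pre-computed multiple alignment
(building one is Muscle/MAFFT territory and out of scope). A window column
counts as identical only when *all* rows agree, with gap treated as an
ordinary character. The window geometry behind published identity tracks
is rarely stated; the defaults (window 400, step 50 columns) are an
exposed, arbitrary choice, and the final partial window is reported at its
actual width rather than dropped.

## Candidate triage

`triage()` runs the full pipeline per contig and assigns one of five
categories from size and structural evidence alone:

| category | rule |
|---|---|
| `not_circular` | no terminal redundancy (or `high_n`) |
| `papillomavirus_sized` | 6800 ≤ L ≤ 8500 and ≥ 6 ORFs |
| `cress_sized` | stem-loop origin and 1200 ≤ L ≤ 3200 |
| `short_circular_defective_or_multicomponent` | stem-loop origin and L < 1200 |
| `circular_unclassified` | circular, none of the above |

The windows are margins around the magnitudes typical of each genome
class — papillomaviruses run ~8 kb with seven canonical ORFs; CRESS-DNA
genomes ~1.7–3 kb; sub-genomic stem-loop circles ~850 nt and likely
defective molecules or components of multipartite viruses. The category
names deliberately claim size and structure, not taxonomy: without
homology evidence (BLAST-tier searches are out of scope) a "cress_sized"
circle is a candidate, not an assignment. All boundaries are arguments.

## The synthetic data generator

`simulate_contigs()` stands in for raw sequencing data: it emits contig
sets with exactly the statistical structure the pipeline assumes, plus a
truth table, so every module can be validated end to end. The default
composition mirrors a circular-DNA-enriched faecal assembly: 4
papillomavirus-like circles (7.2–8.3 kb, seven planted ORFs of realistic
sizes on both strands), 4 CRESS-like circles (1.7–3 kb, one stem-loop
origin with the `TAGTATTAA` nonamer in an 11/11 hairpin, a Rep-sized and a
capsid-sized ORF on opposite strands), 6 short stem-loop circles (~780–950
nt, 1–2 ORFs), and 6 linear background contigs; GC 0.5; terminal
redundancy 20–60 nt at a uniform random breakpoint.

Three generator details matter for interpreting "100% recovery" results:

* **Guard bases.** Each planted hairpin gets non-pairing bases just
  outside its stem and non-pairing loop edges, so the planted arm and loop
  are *exactly* maximal; each planted ORF gets a stop codon immediately
  upstream of its start, so the planted `ATG` is always the first start
  after the previous in-frame stop. Recovery is therefore exact by
  construction, not approximate.
* **Background sanitation.** Random sequence of several kb inevitably
  contains chance ORFs ≥ 300 nt and chance near-matches to the nonamer.
  `sanitize_background()` rescans and destroys these (an in-frame stop
  written into a chance ORF; edits that push a chance motif past the
  mismatch budget), resampling planted-ORF internals when a chance feature
  falls entirely inside one. After sanitation the truth table is
  exhaustive.
* **Determinism.** One root seed drives everything; per-contig RNG
  substreams are drawn up front, so adding or reordering contigs never
  changes other contigs' sequences, and two runs with the same spec are
  `identical()`.

The mutation model (`mutate_seq()`) is substitution-dominated: each site
substitutes with probability d, uniformly over the three alternatives, so
realized divergence is exactly countable; indels are available but default
to 0. This matches nucleotide-level identity analyses, where reported
percentages are substitution-driven.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: sequencing error and coverage
variation (no read-level simulation), chimeric or misassembled contigs,
terminal redundancies with copy errors, biological codon usage and GC
skew, wobble-paired or bulged origin hairpins, and homology between
genomes (each genome's background is independent). Results on real
assemblies depend on the assembler honouring the exact-duplication
behaviour this package detects.

## Numerical and degenerate-input choices

* Ties in hairpin search: longest arm, then smallest loop, then leftmost —
  fully deterministic.
* Ties in alignment: the optimum score is unique; among co-optimal
  alignments the aligner's deterministic traceback is reported, and only
  score/identity are contractual.
* Ties in demarcation: at equal identity the first reference in input
  order is "closest".
* `gc_content()` excludes `N` from numerator and denominator and refuses
  all-`N` input; codons containing `N` translate to `X`; a trailing
  partial codon is dropped.
* Degenerate genomes: a circle shorter than the motif is an error for the
  scanner; a genome shorter than one codon is an error for the ORF caller;
  an absent overlap is `NA`, never 0 (overlap 0 means "not circular" and
  `trim_to_circle()` rejects it).
* Problem sizes used by the test-suite and the acceptance script — 100
  round-trip circles up to 8.5 kb, 20 mutation replicates per divergence
  level at 1.5 kb, 50 oracle-checked circles up to 2 kb, 66
  enumeration-checked alignment pairs up to length 7, 20-contig triage
  datasets — were chosen so each check has clear statistical force while
  the whole suite stays comfortably interactive.

## Known limitations

* Only exact terminal redundancy is detected; an assembler that leaves a
  mismatched or partial duplication will yield `not_circular`.
* The perfect-stem hairpin model misses wobble/bulged origins.
* Identity values depend on the stated gap convention; comparisons with
  tools using a different denominator can differ by a few points,
  which is why the demarcation thresholds should only be applied to
  identities computed under one convention.
* No taxonomy: homology search, phylogenetics, and gene naming are
  upstream/downstream of this package by design.
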