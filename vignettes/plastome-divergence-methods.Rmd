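---
title: "Methods: comparative plastome divergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome divergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastdiverge)
```

# Scope and model

`plastdiverge` analyses divergence among complete chloroplast genomes of
closely related plants — the setting typified by the cotton genus, where a
designated outgroup, two diploid A-genome taxa, two diploid D-genome taxa and
nine allotetraploids are compared on a single whole-genome multiple
alignment. The package operates downstream of alignment: it consumes an
aligned FASTA (one record per taxon, `-` gaps), per-taxon region tables for
the quadripartite architecture (LSC, IRb, SSC, IRa), gene features, and a
fixed rooted species tree. It never computes the alignment itself; MAFFT or
ClustalW output in aligned FASTA is suitable input.

Five kinds of quantity are computed.

**Pairwise substitution and indel accounting.** For a taxon pair, the master
alignment is projected onto the pair (columns gapped in both taxa removed).
A substitution event is a column with two distinct bases in {A,C,G,T};
columns containing N in either taxon enter neither numerators nor
denominators. An indel event is a maximal gap run in exactly one taxon; runs
touching the alignment ends are linearization artifacts and excluded.
Divergence percentages are `100 * count / alignment length` for
substitutions and `100 * summed indel length / alignment length` for indels.
Si/Sv is the transition:transversion event ratio; S/I the
substitution:indel event ratio. Per-region rates divide counts by region
length in kb; the two IR copies are pooled and divided by two, which equals a
per-copy rate under concerted IR evolution. Substitution columns adjacent to
indels are counted normally (no masking rule is applied).

**Staged indel polarization.** Indel loci are maximal column spans over
which the *set* of gapped taxa is constant; nested or overlapping gaps are
split at every pattern change so each locus carries a single
presence/absence pattern. With one outgroup and the three ingroup groups,
the staged rules assign lineage, stage and polarity: events shared by both D
genomes against everything else belong to the D lineage before the D split
(stage 1); events in a single D genome are terminal (stage 2); events shared
by the A genomes *and* all allotetraploids predate allotetraploid formation
(A stage 1); by the A genomes alone, postdate it (A stage 2); single-A
events are terminal (stage 3); events in all allotetraploids predate their
radiation (AD stage 1); events in a subset of allotetraploids are accepted
at stage 2 only when the subset is a clade of the fixed tree, otherwise
flagged as homoplasy candidates. Whether the carriers hold a gap (deletion)
or the unique sequence (insertion) is decided by the outgroup state. Two
conservative choices are deliberate: "shared" requires identical gap-run
boundaries in every sharing taxon (ragged boundaries stay unpolarized), and
any pattern matching no rule stays unpolarized with the reason recorded.
Polarized events map to the edge above the most recent common ancestor of
their carriers, giving per-branch insertion/deletion counts and lengths.

A consequence of taking the rules verbatim: inverting the outgroup state
flips insertion/deletion exactly for A- and D-lineage stage-1 events, while
allotetraploid stage-1 patterns become "A+D shared" patterns — not a lineage
under the rules — and drop to unpolarized. Polarity is therefore
outgroup-determined in all cases (never retained under a flip), which is the
property the test suite asserts.

**SSR analysis.** The scanner reports maximal perfect tandem repeats of
primitive motifs (unit 1–5 bp) in a deterministic left-to-right pass; a run
is reported at the smallest generating unit (a 10-A run is one
mononucleotide locus, never an "AA" locus), trailing partial units are
truncated, and a locus is kept when its length meets the active threshold
set: preset A = {8, 8, 9, 12, 15} bp and preset B = {10, 10, 12, 16, 20} bp
for units 1–5. Motifs are canonicalized to their lexicographically smallest
rotation; reverse-complement motifs are *not* collapsed, and both IR copies
are scanned. Loci from different taxa are homologous when their
alignment-column spans share at least one column and their canonical motifs
match; a locus absent from a taxon scores repeat length 0, so presence
polymorphism counts as polymorphism. Short (1–3 bp) pairwise indels are
attributed to SSR slippage when their span intersects a homology group that
is polymorphic for that pair.

**Ka/Ks, calibration and dating.** The package implements the Nei–Gojobori
(1986) estimator: per-codon synonymous site fractions averaged over both
sequences (changes to stop codons count as nonsynonymous), multi-hit codons
averaged over all substitution orderings with stop-codon paths excluded and
weights renormalized, and the Jukes–Cantor correction
`d = -(3/4) ln(1 - 4p/3)` with `p >= 3/4` flagged as saturated. Published
cotton analyses typically estimate Ks/Ka with maximum-likelihood codon
software; the NG86 values here are method-matched only approximately, so
per-gene values will differ slightly — the dating formula itself is
estimator-agnostic. A
synonymous rate is calibrated as `rs = Ks / (2 t)` from a user-supplied pair
and time (or supplied directly, e.g. 1.162e-9 per site per year), and
divergence times are `T = Ks / (2 rs)`, reported in MY. Calibration and
dating are exact inverses by construction.

**Tajima's relative rate test.** For lineages A, B and an outgroup O on one
alignment, `nA` counts columns where A is the odd taxon out (B agrees with
O) and `nB` the converse; `chi^2 = (nA - nB)^2 / (nA + nB)` on 1 df. Columns
with any gap or N are excluded, so the whole-genome mode effectively tests
the gap-free portion of the alignment. `nA + nB = 0` is reported as p = 1
with an `undefined` flag. P-values are reported raw (no multiplicity
correction), matching how such tables are conventionally presented.

# The simulator and what it emulates

`build_ancestral_genome()` draws a quadripartite genome whose defaults are
the study conditions for cotton plastomes: LSC 88,800 bp, SSC 20,300 bp and
IR 25,600 bp per copy (~160 kb in total), with AT content 64.8% (LSC), 68.3%
(SSC) and 57.0% (IR); IRa is the exact reverse complement of IRb. Perfect
SSR loci and stop-free CDS features can be seeded at construction.

`evolve_along_tree()` evolves the ancestor along a rooted tree while
maintaining a master truth alignment and a complete event log. Default rates
are calibrated once to the published divergences on a tree in MY units:
substitutions at 6.9e-4 /site/MY (852 substitutions per ~160 kb across
2 x 3.89 MY of the A/D split) with Si/Sv 0.45; indels at 2.1e-4 /site/MY
(~255 events across the same span) with a size distribution enriched at 1 bp
(32%) and 5–6 bp (32% combined) over sizes 1–10; 30% of insertions copy the
adjacent upstream segment (slipped-strand tandem duplication); deletions
outnumber insertions 2:1 (`ins_del_bias = 0.5`); and seeded SSR loci gain or
lose one repeat unit at 0.05 events per locus per MY. The bundled
`default_species_tree()` places the A/D split at 3.89 MY, the allotetraploid
radiation at 0.38 MY, the D5/D6 split at 0.77 MY and the A1/A2 split at
0.13 MY, with internal nodes named for branch-level assertions.

Design choices in the simulator, and why:

* **IR concerted evolution.** Mutations drawn in IRb are mirrored into IRa
  (complemented, position-reflected), and positions are never drawn in IRa
  directly. The magnitude of IR homogenization is not quantified in the
  source data, so full mirroring is an explicit assumption
  (`mirror_ir = FALSE` disables it); it reproduces the observed low apparent
  IR divergence.
* **Linearization.** Genomes are generated and emitted linearized at LSC
  position 0; no indel spans the origin or a region boundary, which keeps
  per-tip region tables contiguous.
* **Same-branch overlaps.** Events on one branch apply sequentially; an
  indel overlapping a previous same-branch indel is redrawn (up to 100
  times, then dropped), keeping the truth alignment well defined.
* **Slippage granularity.** SSR slippage changes unit count by exactly one
  per event — the simplest slipped-strand model consistent with attributing
  1–3-bp indels to SSR polymorphism.
* **Event log.** Every event is logged with stable column identities and
  converted to final master-alignment coordinates, so `replay_event_log()`
  reconstructs each tip byte-for-byte; the replay identity is asserted in
  the tests.

What the generator does **not** emulate: realistic gene content (the 112-gene
complement), intron structure, codon-aware selection on CDS (indels in genes
are not frame-preserving), base-composition evolution, rate heterogeneity
along the genome, and recombination. Passing recovery tests on synthetic
data therefore demonstrates the correctness of the accounting, polarization
and dating machinery under a known generating process — not that real
plastomes satisfy the model's assumptions.

# Validation experiments and problem sizes

The test suite scales simulations to run comfortably on one CPU; sizes were
chosen as the package's own study design.

* **Oracle equivalence.** Indel locus extraction and pairwise event
  extraction are compared against explicit per-column loop references on all
  6,399 two-taxon, four-column alignments over {A, C, -} plus 4,000 random
  four-taxon, twelve-column alignments (>10,000 cases).
* **Polarization recovery.** A 122-kb ancestor (70/16/10 kb regions) evolved
  on the 14-taxon tree with indel rate 6e-4 plants ~600 non-SSR indels;
  >=95% are required back with exact span, polarity and branch. The outgroup
  pendant is kept short because events on it (and on the ingroup stem) are
  unpolarizable under the staged rules and fall outside the denominator.
  Residual losses are collisions: events from different branches whose
  spans overlap or interleave split into mixed-pattern loci and are
  (correctly) left unpolarized.
* **Spectrum recovery.** Two lineages, 143-kb ancestor, ~550 planted indels
  from the default-shaped size distribution; the recovered locus-length
  histogram must pass a chi-square goodness-of-fit test at p > 0.01. Loci
  longer than the model's 10-bp maximum are same-branch merge artifacts
  (adjacent events fused into one gap run) and are excluded before the test.
* **SSR attribution.** 1,300 seeded loci at slippage rate 0.1 per locus per
  branch-length unit on two lineages give >=200 short indels with >=90%
  attribution. The low per-locus rate matters: at high rates, balanced
  gain/loss walks leave the two taxa with equal repeat lengths, which is by
  definition not polymorphic, so the attributable fraction has a ceiling
  below 1 outside the single-event regime.
* **Type-I error of the relative rate test.** 500 replicates of an
  equal-rate three-taxon simulation (~1.9-kb genome, ~47 expected
  lineage-specific differences per side) must reject at 5% within the 95%
  binomial envelope.
* **Replication-scale inputs.** The deposited cotton genomes cannot be
  bundled, so replication mode is exercised on an emitted synthetic dataset
  of the same shape (13 ingroup taxa + outgroup) and checked at the schema
  level only; real-data values require the user to supply the GenBank
  genomes and an alignment.

# Numerical conventions and edge cases

Internal coordinates are 0-based half-open everywhere; GFF3 stays 1-based
inclusive at the file boundary only. Gap character is `-` (``.`` is
rejected). Reported percentages reproduce printed-precision values from raw
counts; tests compare raw values within half a unit of the printed last
digit because published tables mix rounding and truncation. Si/Sv of an
identical pair is NaN with zero counts; S/I is NaN when there are no indel
events; an SSR survey of an empty locus set yields NaN conserved rates; a
saturated Ks yields no date and a propagated flag. `divergence_percent`
requires a positive alignment length. The whole-genome alignment length is
always the computed master length; the published 161,600-bp figure enters
only when reproducing printed percentages from printed counts.

# Known limitations

Polarization assumes exactly one outgroup and the four-group design;
probabilistic ancestral-state reconstruction and multi-outgroup polarization
are out of scope. NG86 with JC correction underestimates distances relative
to ML codon models at higher divergence. SSR homology via single-column
overlap can fuse distinct loci that drift into adjacency over deep
divergences. The simulator's IR mirroring is all-or-nothing. The pipeline's
dating mode slices CDS columns through the reference taxon's gene
coordinates, so codons disrupted by indels are dropped pairwise rather than
realigned.
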