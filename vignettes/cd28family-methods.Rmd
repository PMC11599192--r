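---
title: "Classifying CD28-family receptors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CD28-family receptors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd28family)
```

This vignette is the package's own account of its method: what is being
computed, under which assumptions, which knobs matter, and what the
synthetic-data generator does and does not emulate.

## The classification model

A candidate receptor is accepted into the CD28 family, and assigned to one
of its members, on two independent lines of evidence:

1. **Structure + motifs.** The protein must segment as a type-I membrane
   protein with a single IgV ectodomain (leader – IgV – stalk – TM –
   cytoplasmic tail), and must carry the family's diagnostic degenerate
   motifs *in their structural regions*: CDR3-neighborhood proline motifs,
   the G-strand GxG, the E-strand V-[N/D]-L, the transmembrane
   dimerization motif YxxxxT, and cytoplasmic tyrosine motifs (YxxM-type
   PI3K sites, YxNx-type GRB2/GADS sites, ITIM/ITSM pairs).
2. **Conserved synteny.** When gene-order context is available, the locus
   must share marker genes with the family's conserved neighborhood (for
   the cassette families the *raph1 / abi2 / cyp20a1 / wdr12 / pard3b*
   block around the ancestral three-gene *cd28–ctla4–icos* cluster; for
   the others their own blocks, e.g. *fsd1/stap2* for *cd28h*).

Evidence is additive and deliberately coarse: a REQUIRED motif matched in
its region scores 2, a SUPPORTING (lineage-restricted) motif 1, and
synteny scores 2 for two or more shared markers, 1 for exactly one. A
label is assigned when the best profile reaches the score threshold
(default 4), leads the runner-up by the margin (default 2), and — when
context was supplied — has at least one synteny evidence item. The 2/1
weighting is a convention, not a fitted quantity: the source evidence
ranks motifs only qualitatively (conserved across the family's range
vs. present in some lineages), and the threshold/margin pair (4, 2) is the
smallest under which every noise-free exemplar is accepted while a
chondrichthyan-style hybrid (CDR3 P-[P/L]-P + GxG + YxxxxT + EYxNM) is
still forced into the unresolved co-ortholog outcome rather than
mislabelled CD28 or CTLA4. Both are exposed as arguments.

Two deliberate asymmetries:

* **Missing context waives criterion 2** (transcript-only evidence is
  common); an absent marker neighborhood in *supplied* context, however,
  blocks any canonical label.
* **Cassette ambiguity collapses to the co-ortholog class.** If the top
  two profiles are both cassette families (CD28/CTLA4/ICOS/co-ortholog)
  and the margin is not met, the outcome is CD28_CTLA4_CO_ORTHOLOG — the
  biologically honest answer for chondrichthyan sequences with mixed
  CD28/CTLA4 features — instead of UNCLASSIFIED.

## The motif notation

The catalog's motifs are written in the compact consensus dialect used in
comparative immunogenetics and compiled by `compile_pattern()`: single
letters are fixed residues; `[A/B/C]` (or `[A,B,C]`) are residue classes;
`x` is one arbitrary residue, `x_N` exactly N, `x_N/M` N-to-M; `(X)_n` is
an unbounded spacer. Dashes and whitespace are cosmetic. Three notation
decisions needed fixing once:

* `(X)_n` is bounded to 0–60 residues at match time — wide enough for any
  plausible ITIM–ITSM spacing in a cytoplasmic tail.
* The shorthand class `[E/K/Q/N-polar]` is encoded as the explicit set
  {E, K, Q, N, S, T} ("N-polar" read as asparagine plus the polar
  residues); the catalog flags this interpretation in its notes.
* The ambiguity letter X in *input* sequences matches wildcards and
  spacers but never fixed or class positions, so gap-filled gene models
  cannot generate motif calls.

All coordinates are 1-based inclusive. Overlapping matches are all
reported; with an unbounded spacer the shortest match per start is kept.

## Architecture surrogates

Domain segmentation stands in for interactive domain annotation, with all
thresholds pinned so results are reproducible:

* **TM:** mean Kyte–Doolittle hydropathy over a 19-residue window,
  assigned to the window *center* (the usual hydropathy-plot convention —
  marking whole windows would overshoot each boundary by half a window),
  threshold 1.6, merged runs of at least 15 residues. The membrane anchor
  is the last such segment leaving ≥ 8 downstream residues.
* **IgV:** a framework triple — cysteines at p1 and p3 with a tryptophan
  between them, spacings p2 − p1 ∈ [10, 25] and p3 − p1 ∈ [50, 85] —
  bracketing the canonical C23/W41/C104-style geometry. The leftmost p1,
  then smallest p3 wins. An IgV-sized pre-TM span (≥ 55 residues) without
  the triple sets the *divergent IgV* flag, which only profiles that
  tolerate a degenerate V domain (PD-1 in bony fish) may overcome.
* **Motif regions:** CDR3 neighborhood = [cys2 − 5, cys2 + 30] (CDR3
  follows the second framework cysteine); G strand = last 15 residues of
  the IgV interval; E strand = [cys1 + 30, cys1 + 50]; CTERM = last 12
  residues of the protein. These localize the catalog's structural
  vocabulary without a structure model; they are intervals, not folds.

## What the generator emulates — and what it does not

`simulate_family_protein()` builds each family's exemplar on a fixed
layout (leader 1–18, IgV 19–118 with framework C41/W59/C106, stalk,
21-residue TM at 127–147, cytoplasmic tail to 190) and plants the
family's REQUIRED and SUPPORTING motifs at canonical positions in their
regions. Scaffold residues are drawn from a hydrophilic alphabet
(S/T/N/Q/D/E) chosen so that no catalog motif and no framework triple can
arise on scaffold by chance — every one of them needs at least one
residue (C, W, Y, P, G, M, L, I, V, F) the scaffold lacks. The stalk uses
a hydropathy-neutral alphabet (G/S/T) so the TM boundary stays sharp.

Wildcard and class positions inside planted motifs are *fixed* per family
(echoing named species sequences, e.g. the human ICOS cytoplasmic YMFM),
not redrawn per seed: several catalog consensi overlap (an ICOS
E-Y-M-D-M is simultaneously a valid CD28 [D/E/V/I]-Y-M-[N/D]-[M/I/V/T]
hit), so random draws would make even noise-free labels seed-dependent.
Per-seed variation comes from the scaffold.

Divergence is a stress parameter, not an evolutionary model: each
unprotected site is substituted with probability `divergence`, uniformly
over the 19 alternatives. With `protect_motifs` the planted motif
residues, the framework C/W/C and the TM span are exempt — the in-silico
analog of purifying selection on the diagnostic and structural positions;
an unprotected framework cysteine would be lost in a quarter of records
at 10% divergence, which models mutational load, not the conservation the
catalog encodes. At 10% divergence a protected exemplar sits near the
binomial expectation of ~91% identity to its noise-free twin.

Consequences for interpretation: passing tests show the *procedure* is
correct and well-calibrated on sequences whose diagnostic features are
intact and whose background is neutral. They do not show robustness to
real-world failure modes the generator does not emulate — motif decay in
real lineages (cyprinid CD28 tyrosines), compositional bias, alternative
isoforms, or shared descent between families: exemplar scaffolds are
independent draws, so between-family tree structure reflects motif
sharing only, and similarity values (~25–35% between families) are
scaffold-chance plus motifs, not phylogenetic signal.

`simulate_genome()` builds one ancestral chromosome from the catalog's
marker blocks (cassette plus one block per other family, separated by 12
filler genes — wider than the default synteny window so blocks cannot
bleed into each other), then applies full duplications (each round doubles
every chromosome), per-gene loss (optionally restricted to family genes
and/or chosen chromosomes), and Poisson-distributed adjacent
transpositions. The truth table records each gene's ancestral block and
the surviving copy counts; with zero loss these equal
`count_paralogous_regions()` exactly, and two rounds of WGD yield the
four paralogous cassette regions familiar from salmonid genomes.

## Phylogeny layer

Likelihood tree inference is out of scope; the package provides an
explicit, reproducible stand-in: neighbor-joining on Poisson-corrected
distances d = −ln(1 − p), where p is the mismatch fraction over shared
non-gap columns. Saturated pairs (p → 1) are capped at d = 10 with a
warning. NJ is exact on additive matrices (tested to 1e-9); negative
branch lengths are clamped to zero with the deficit moved to the sibling
edge. The multiple alignment for bootstrapping is a center-star
progressive merge of pairwise global alignments (BLOSUM62, gap open −11,
extend −1; a gap of length L costs −11 − (L − 1)) — a documented
simplification of full progressive aligners, adequate at the tens-of-
sequences scale used here. Bootstrap resampling depends only on the seed
and the column count, so supports are invariant to taxon order.
`clade_membership()` asks whether some internal edge of the unrooted
topology separates the candidate plus (a subset of) the reference taxa
from everything else; a star topology therefore supports no proper
subset.

## Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, chosen as the smallest
sizes at which the statistical claims are meaningful: 190-residue
proteins; 50 seeds × 10 profiles for catalog/generator consistency;
200 exemplars per family at 10% divergence for recovery (observed ≥ 99%
against the 95% requirement); 100 random additive matrices up to 8 taxa
for NJ consistency; 1000 random pattern/sequence pairs against the
brute-force matcher; 100 bootstrap replicates. Ties are broken
deterministically everywhere (catalog order for equal scores, documented
orderings in NJ and traceback), and every stochastic step takes an
explicit integer seed.

## Known limitations

* The architecture module is a hydropathy/regex surrogate; unusual TM
  topologies (multi-pass, re-entrant) and non-canonical IgV geometries
  outside the pinned spacing windows will be missed.
* The catalog encodes one evidence set per family; lineage-specific motif
  decay is handled only through SUPPORTING weights and the divergent-IgV
  flag, not through per-lineage profiles.
* Synteny windows are measured in gene ranks on curated tables; on dense
  unfiltered gene lists the default k = 10 is conservative.
* The co-ortholog cassette-position annotation requires the caller to
  name the cassette genes; positions are not inferred de novo.
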