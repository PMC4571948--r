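---
title: "Scanning and prioritizing zDHHC17/13 ankyrin-repeat-binding motifs"
author: "ARBmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning and prioritizing zDHHC17/13 ankyrin-repeat-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ARBmotif)
```

## The biological problem

The Golgi-localized S-acyltransferases zDHHC17 (HIP14) and zDHHC13 (HIP14L)
are the only two mammalian zDHHC enzymes carrying an N-terminal ankyrin
repeat (AR) domain, which recruits substrates such as SNAP25b, CSPα,
Huntingtin, CLIP3, SNAP23 and MAP6 before S-acylation. Recognition is
mediated by a short linear motif (SLiM) lying in intrinsically disordered
regions of the substrate: a six-residue consensus of the form

    [VIAP] [VIT] X X Q P
      Ψ      β

where Ψ admits the aliphatic residues Val, Ile, Ala and Pro — explicitly
not Leu — β admits the C-beta-branched Val, Ile and Thr, two positions are
unconstrained, and the terminal Gln-Pro pair is invariant. ARBmotif
implements this grammar, scans proteins for it, predicts the effect of
point mutations on motif integrity, classifies cross-species conservation,
applies a disorder filter, runs the staged candidate-prioritization
cascade, and builds neighbor-joining trees of AR-containing zDHHC enzymes.

## The motif model

Motifs are position-class patterns, not scoring matrices: a window either
satisfies every class or it does not. This is deliberate — the consensus
was defined by inspection of experimentally validated binders, and no
quantitative binding model is attached to it. Three mutually exclusive
submotifs refine the consensus:

* `[VIA][VI]XXQP` — the common form;
* `P[VI][VIL]XQP` — an additional non-variable aliphatic residue is
  required when Pro occupies Ψ;
* `Q[VI]TXXQP` — a Gln is required immediately upstream when Thr occupies
  β. The upstream Gln is a *context* requirement: reported hit coordinates
  always span six residues so that hits are comparable across submotifs,
  and the context is reported separately (`context_ok`). A window at the
  very first position of a sequence can never satisfy this submotif,
  because the required upstream residue does not exist.

Mutual exclusivity and the containment of each submotif in the general
consensus are asserted by exhaustive enumeration in the test suite (all
400 Ψ/β residue pairs; all 160,000 Gln-Pro-terminated hexamers, of which
exactly 4 × 3 × 20 × 20 = 4800 satisfy the consensus).

Residues are the 20 standard uppercase letters; lowercase input is
uppercased on ingest, and any other letter (B, Z, X, U, J, O, `*`) fails
every class silently rather than raising an error, since the consensus is
defined only over standard residues.

## Scanning and in-silico mutagenesis

`scanMotifs()` reports every matching window, overlaps included — no
deduplication is attempted, and ties are ordered by ascending start.
Coordinates are 1-based, inclusive, and expressed in *protein numbering*
via a per-record `numberingOffset`, so that the decapeptide GVVASQPARV
(SNAP25b residues 111-120) yields its hit at 112-117 with the invariant
Gln at 116 and Pro at 117.

`predictMutationEffect()` applies one substitution (multi-mutants are
composed by repeated application, mirroring one-at-a-time alanine scans),
rescans, and compares hits at the original hit spans: `retained` when a
full hit still covers the span, `partial` when only a relaxed-qualifier
hit remains, `lost` otherwise. Relaxed mode is off by default: Val or Ile
at the terminal-Pro position only *partially* restore binding
experimentally, so they are treated as a qualifier, never as a full match.

A documented limitation: the model scores motif integrity only. HTT
substitutions T496A and R500A fall on the unconstrained X positions or
outside the six-residue core and are therefore called `retained`, although
both impair binding experimentally — residues outside the consensus (and
possibly Thr phosphorylation) contribute to binding in ways a class
pattern cannot express.

## Conservation across orthologs

Cross-species conservation uses pairwise global alignment of the reference
against each ortholog rather than a progressive multiple alignment: only
the column correspondence of six motif positions is needed, and pairwise
Needleman-Wunsch is exactly specifiable. The aligner is an affine-gap
Gotoh DP (in C++) under BLOSUM62 with gap opening 10 and extension 0.5 —
CLUSTALW-like protein defaults, fixed in the configuration because no
authoritative parameter set exists for this analysis — and a deterministic
traceback (diagonal, then vertical, then horizontal on ties). A gap of
length L costs `open + ext * L`. The implementation is verified in the
tests against exhaustive enumeration over all alignments of short pairs
and against an independent implementation (`Biostrings::pairwiseAlignment`)
on longer ones.

A motif is called conserved when every ortholog's mapped six-residue
segment is gap-free and itself satisfies the *general consensus* — i.e.
class-level conservation, not residue identity, since orthologs visibly
swap within classes (V↔I, S↔T). Separately, each position is categorized
as `absolute` (identical in all sequences), `equivalent` (differing only
within Val/Ile or Ser/Thr — the bold-type convention in candidate tables),
or `other`. Column shading of aligned sets follows the display convention
of similarity figures: per column, the fraction of sequence pairs scoring
positively under BLOSUM62 (gap pairs count as dissimilar), `black` at 1.0
and `gray` in [0.6, 0.8]. The fraction-of-positive-pairs statistic is a
design choice recorded in the configuration; the legend convention it
mimics names the matrix but not the statistic.

## The disorder filter

AR-binding motifs function only in unstructured regions, so candidates are
filtered on predicted intrinsic disorder. External predictor outputs (e.g.
DISOPRED3- or PrDOS-style per-residue tracks) are ingested as TSV with
`position, residue, score, call[, coil]` columns, validated against the
sequence. For fully self-contained runs, `builtinDisorder()` provides a
windowed fold-index-style stand-in: over a window (default 21, clamped at
the termini) the mean Kyte-Doolittle hydropathy rescaled to [0, 1] and the
absolute mean formal charge combine as `I = 2.785 H − |R| − 1.151`, with
`I < 0` called disordered. This is a deliberately simple, desk-testable
score — it is *not* a re-implementation of any external predictor, and its
coil calls equal its disorder calls because it carries no
secondary-structure model.

The motif-level rule is strict by default: all six hit residues must be
called disordered. A two-track rescue mirrors the published procedure of
consulting a second predictor for motifs placed in coils without being
called disordered: a hit passes if all six residues are coil in the
primary track *and* disordered in the secondary track. Whether partial
overlap with a disordered region should suffice is not specified anywhere
authoritative; the strict all-residue rule is the default and a
`majority` rule is available in the configuration.

## The prioritization cascade

`runCascade()` reproduces the staged identification of candidate
AR-binding proteins from an annotated table:

1. **Motif stage** — keep candidates with at least one *submotif* hit, in
   either their full sequence or the printed motif-region segment (the
   provenance is recorded; printed tables typically contain only
   segments).
2. **Physiology stage** — keep candidates with any evidence of meeting
   zDHHC17 under physiological conditions: Golgi or plasma-membrane
   localization, S-acylation, zDHHC13 interaction, or homology to a
   protein with these features (a logical OR, following the published
   filter's own wording).
3. **Disorder stage** — keep candidates whose motif passes the disorder
   filter, using (in precedence order) an externally supplied per-table
   call, a supplied disorder track, or the built-in stand-in.

The final set is the union of stage-3 survivors and candidates flagged
`tested_in_this_study`: experimentally studied proteins enter the
candidate table by experiment, not by the cascade. Footnote-flag summary
counts (S-acylated; established zDHHC17 substrates; zDHHC13 interactors;
motif conserved among human/frog/zebrafish homologues) are computed over
the final set only. Stage sets are nested by construction and reports are
byte-deterministic, with rows sorted by protein id.

The bundled `table1_synthetic.tsv` fixture is a *synthetic transcription*
of the published 20-protein candidate summary: the six studied proteins
carry their printed motif segments, while the motif regions of the other
14 named interactors and the per-protein flag assignments are engineered
only to reproduce the published totals (20 final; 15 S-acylated; 10
zDHHC17 substrates; 8 zDHHC13 interactors; 12 conserved; 14 beyond the
studied six), which are the quantities the package asserts. The
intermediate cascade sizes (17 motif-positive, 15 after the physiology
filter, 14 after the disorder filter) are exercised on engineered
synthetic tables from `genCandidateTable()`, because the identity of the
dropped candidates is not published.

## Neighbor-joining trees

`njTree()` is a standard Saitou-Nei implementation: minimize the Q
criterion, join, compute branch lengths, reduce; ties are broken by the
lexicographically lowest taxon-index pair so output is deterministic, and
the final join leaves the canonical unrooted trifurcation. Distances are
1 − fractional identity over pairwise global alignments (columns with a
single gap count in the denominator) — a deliberately simple distance
matching common alignment-viewer behaviour, declared in place of the
unstated original settings; no substitution model is fitted. Negative
branch lengths on non-additive inputs are kept and flagged with a warning.
Consistency on additive matrices (50 random 5-10-taxon trees recovered
exactly, checked against `ape::nj` as an independent implementation) and
invariance of total tree length to taxon order are asserted in the tests.
Reproducing the published metazoan AR-zDHHC tree requires downloading the
UniProt sequences named in that figure; the tests instead verify the
desk-scale analogue that two anciently diverged duplicate families
("17-like" and "13-like") form disjoint subtrees.

## Synthetic data and what passing tests show

All generators are seeded (one master seed, per-generator derived streams)
and byte-deterministic. Defaults describe the study conditions the test
suite runs under: proteomes of 300-600-residue proteins with background
residues uniform over the 20 letters and an expected one implanted motif
per protein (Poisson), submotif mix 0.5/0.3/0.2; ortholog triples with a
10% substitution rate at non-motif positions; decoys violating exactly one
constrained motif position, embedded in inert Gly flanks chosen so no
alternative reading frame can match. Uniform background makes the
false-positive rate analytically checkable (general-consensus probability
per window = (4/20)(3/20)(20/20)(20/20)(1/20)(1/20) = 1.5 × 10⁻⁴). Sizes
used in the tests (e.g. 200 random 500-mers for the scanner oracle, 100
ortholog seeds, 150 proteins for the Poisson band) were chosen as the
smallest sets that exercise every code path convincingly.

Synthetic data emulate motif placement, class composition and annotation
logic — not residue composition bias, indels between orthologs, domain
structure, or real disorder profiles. Passing tests therefore demonstrate
correctness of the algorithms under controlled truth, not biological
performance on real proteomes: on real data, disorder filtering depends on
the quality of the supplied predictor tracks, and conservation calls
depend on orthology assignment, neither of which the package re-derives.

## Numerical and degenerate-input choices

* Gap cost `open + ext * L` (first gap residue costs `open + ext`),
  verified against an independent implementation.
* Alignment traceback tie order: diagonal, vertical, horizontal.
* NJ tie order: lowest taxon-index pair.
* A mapped ortholog segment containing a gap is "not conserved", not an
  error; a malformed distance matrix or an empty sequence is an error.
* Windows containing non-standard letters never match and never error.
* The disorder window is clamped (truncated) at the termini rather than
  padded.

## Session info

```{r}
sessionInfo()
```
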