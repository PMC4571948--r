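# ARBmotif

Scanning, mutational analysis and prioritization of the short linear motif
recognized by the ankyrin repeat (AR) domain of the S-acyltransferases
zDHHC17 (HIP14) and zDHHC13 (HIP14L).

These two Golgi-localized zDHHC enzymes recruit substrates — SNAP25b, CSPα,
Huntingtin, CLIP3, SNAP23, MAP6 and others — through a six-residue consensus
lying in intrinsically disordered regions:

```
[VIAP] [VIT] X X Q P        (Ψ β X X Q P)
```

Ψ admits Val/Ile/Ala/Pro (not Leu), β the C-beta-branched Val/Ile/Thr, two
positions are free, and the Gln-Pro pair is invariant. The consensus splits
into three mutually exclusive submotifs: `[VIA][VI]XXQP`, `P[VI][VIL]XQP`,
and `Q[VI]TXXQP` (a Gln required immediately upstream when Thr occupies β).

The package is aimed at researchers studying protein S-acylation and
AR-mediated substrate recruitment who want to scan candidate proteins for
this motif, predict whether a point mutation destroys it, test whether it is
conserved across orthologs, and rank interactor lists the way the original
staged cascade did. It provides:

* the position-class motif grammar with a plain-text config for custom motifs;
* a scanner with protein-numbering offsets and full/partial qualifiers;
* in-silico point mutagenesis with retained / partial / lost calls;
* pairwise global alignment (BLOSUM62, affine gaps, deterministic traceback),
  motif-position mapping, conservation categories and similarity shading;
* per-residue disorder tracks (external TSV or a built-in fold-index-style
  stand-in) and a motif-level disorder filter with two-track rescue;
* the staged candidate-prioritization cascade with footnote-flag summaries;
* neighbor-joining trees from identity distances, serialized to Newick;
* seeded synthetic-data generators (proteomes with implanted motifs, decoys,
  ortholog triples, engineered candidate tables) with attached ground truth.

## Worked example

```r
library(ARBmotif)

## the SNAP25b decapeptide, residues 111-120 of the full-length protein
rec <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
scanMotifs(rec)
#>        protein_id start end matched general submotifs context_ok qualifier
#> 1 SNAP25b_111-120   112 117  VVASQP    TRUE submotif1      FALSE      full

for (m in c("V112A", "V113A", "Q116A", "P117A"))
  cat(m, "->", predictMutationEffect(rec, m)$effect, "\n")
#> V112A -> retained
#> V113A -> lost
#> Q116A -> lost
#> P117A -> lost
```

The scan finds one hit, `VVASQP` at residues 112-117: Val112 occupies Ψ,
Val113 β, and Gln116-Pro117 are the invariant pair. The alanine scan calls
follow directly: Ala is itself allowed at Ψ, so V112A retains the motif,
while substitutions at β, Gln or Pro destroy it.

Running the cascade on the bundled candidate table (a synthetic
transcription of the published 20-protein summary; see the vignette):

```r
tab <- readCandidateTable(system.file("extdata", "table1_synthetic.tsv",
                                      package = "ARBmotif"))
runCascade(tab)
#> PrioritizationReport
#>   stage 1 (submotif hit):      20
#>   stage 2 (physiology filter): 20
#>   stage 3 (disorder filter):   20
#>   final set (incl. tested):    20
#>   flags over final set: s_acylated=15, dhhc17_substrate=10,
#>                         dhhc13_interactor=8, motif_conserved_hfz=12
```

Fifteen of the twenty final candidates are known to be S-acylated, ten are
established zDHHC17 substrates, eight also interact with zDHHC13, and twelve
have their motif conserved among human, frog and zebrafish homologues;
fourteen lie beyond the six experimentally studied proteins.

A thin command-line wrapper covers the same stages
(`inst/scripts/arbmotif scan|mutate|conserve|disorder|prioritize|tree|simulate`).

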