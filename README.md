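# tetrapolar

Genetic analysis of the tetrapolar (bifactorial) mating system of
agaricomycete fungi, built around the crossing data of natural *Pleurotus
ostreatus* (oyster mushroom) isolates, plus sequence-level analyses of the
homeodomain transcription factors encoded at the *matA* locus.

## The science

Most homobasidiomycete fungi form a fertile dikaryon only when two haploid
monokaryons carry different alleles at **both** of two unlinked mating-type
loci: *matA* (homeodomain transcription-factor cassette) and *matB*
(pheromone/receptor locus). Writing a haploid genotype as AxBy, the mating
rule for a mon–mon cross is

    compatible(AxBy, Ax'By')  ⇔  Ax ≠ Ax'  and  By ≠ By'

scored in practice as clamp connections on the mycelium. In a di–mon cross
(the Buller phenomenon) the monokaryon is dikaryotized when it is compatible
with at least one of the dikaryon's two nuclei. Meiosis of a dikaryon
AxBx + AyBy segregates the unlinked loci freely, so each fruiting isolate
yields a four-tester panel {AxBx, AxBy, AyBx, AyBy}.

A +/− crossing matrix is therefore a system of logical constraints on allele
classes: every "+" cell forces inequality at both loci, every "−" cell is a
disjunction (shared *matA* class **or** shared *matB* class), and the panel
structure adds within-panel equalities. "At least N alleles" is the minimum
number of distinct classes over all assignments consistent with every cell.
The package computes that minimum exactly: union-find unit propagation
resolves the disjunctions whose alternative branch is contradicted (this is
the formal version of deducing that two panels share their *matB* classes
from a 50%-compatible block), and a backtracking search over the residual
ambiguity — canonical colourings of the component graphs with a clique
lower bound — minimises `n_A + n_B`. A brute-force enumeration over
restricted-growth labellings serves as an independent oracle in the tests.

The protein side implements the analyses applied to the HD1/HD2 homeodomain
proteins of the *matA* cassette: wildcard motif scanning (the conserved
DNA-binding hexamer `WFXNXR` of the third α-helix, the HD1-specific
`HNPYP[TS]`), Kyte–Doolittle hydropathy profiles with a
transmembrane/globular call, a composition-based nuclear-localization-signal
screen (K/R- or P/H-rich windows), HD1-vs-HD2 length comparison, and a
gene-cassette model of the locus (`mip` – 1–3 `hd` genes – `fg`) with GFF3
export.

## Worked example

The bundled fixtures transcribe the published crossing records of the
natural-isolate study: five tester panels (M-8, M-9, M-13, M-14, M-17)
crossed mutually and against the reference panel M-38, and twelve further
dikaryotic isolates crossed di–mon against M-38.

```r
library(tetrapolar)

res <- infer_study_alleles()          # natural-isolate testers only
res
#> <allele_assignment> 20 monokaryons: n_A = 10, n_B = 8 (unique up to relabeling)

pc <- attr(res, "propagated")
pc$forced
#>   locus      m1     m2                    source
#> 1     B M-13.m1 M-8.m1 cell (M-13.m1, M-8.m1)
#> 2     B M-13.m2 M-8.m2 cell (M-13.m2, M-8.m2)

infer_study_alleles(include_reference = TRUE)
#> <allele_assignment> 24 monokaryons: n_A = 12, n_B = 10 (unique up to relabeling)
```

Ten *matA* and eight *matB* classes are the minimum consistent with the 20
natural-isolate testers; the 8 (not 10) on the *matB* side arises because
the 50%-compatible M-8 × M-13 block forces the two panels to share both
*matB* classes — propagation derives those identifications before any
search. Adding the M-38 reference panel (fully compatible with everything)
adds two classes at each locus.

The motif scanner on a printed HD2 homeobox fragment:

```r
motif_scan("MARKSMMTDRQIEVWFQNHRNSR", "WFXNXR")
#>     id start end  match
#> 1 <NA>    15  20 WFQNHR
```

The numbered scripts under `analysis/` run the full workflow (table
structure, allele inference, simulation calibration, protein battery) and
write their tables under `results/`.

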