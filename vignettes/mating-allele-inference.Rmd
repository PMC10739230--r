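---
title: "Inferring mating-type allele diversity from crossing matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mating-type allele diversity from crossing matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrapolar)
```

## The model

Tetrapolar agaricomycetes gate sexual development by two unlinked,
multiallelic loci. A haploid monokaryon has genotype AxBy; two monokaryons
dikaryotize exactly when they differ at *matA* and at *matB*, and the
dikaryon is diagnosed by clamp connections. A di–mon cross succeeds when the
monokaryon is compatible with at least one nucleus of the dikaryon (Buller
phenomenon); we adopt the either-nucleus OR rule, the standard reading of
dikaryotization, since the alternative (a specific donor nucleus) has no
support in the crossing records the package ships. Because the loci are
unlinked, meiosis of a dikaryon AxBx + AyBy returns exactly four spore
mating types; `spore_types()` is deterministic (all four types), and
per-spore stochastic sampling is deliberately left to the simulator.

Self-crosses are defined as incompatible rather than rejected as errors:
crossing matrices conventionally carry a "−" diagonal, and treating it as
data keeps parsing and symmetry checking uniform.

## From a +/− matrix to allele counts

Each scored cell of a mon–mon matrix is one constraint on the latent allele
classes:

* `+` → A(m) ≠ A(m′) **and** B(m) ≠ B(m′);
* `−` → A(m) = A(m′) **or** B(m) = B(m′);
* a four-tester panel adds m1=m2 and m3=m4 at *matA*, m1=m3 and m2=m4 at
  *matB*, and the inequality of the two classes at each locus.

"At least N alleles" is read as the minimum number of distinct classes over
all consistent assignments — the defensible formalisation of a count from
incomplete crossing evidence, since any smaller number would contradict an
observed cell and any larger one is not demanded by the data.

`propagate()` runs unit propagation to a fixpoint with a union-find over
monokaryons per locus: a disjunction whose shared-A branch is contradicted
by accumulated inequalities forces the shared-B identity (and vice versa),
and every such merge is recorded as *forced*, distinguishing deduction from
minimisation. Unsatisfiable records (a `−` cell with both branches
contradicted, or a `+` cell inside a forced class) raise errors naming the
offending cell.

`minimal_assignment()` then minimises over the residual freedom. After
propagation the problem is a pair of graph colourings — components of each
locus as vertices, accumulated inequalities as edges — coupled by the still
open disjunctions. The search is exact: canonical (restricted-growth)
colour assignment in component order, A-locus then B-locus, pruning with a
greedy clique lower bound, disjunctions checked incrementally. The
objective is `n_A + n_B`, ties broken by smaller `n_A`, then by the
lexicographically smallest labelling, which makes the output deterministic;
labels are reported by first appearance in row order. The search also
counts optimal solutions (capped) to report uniqueness up to relabelling.
An independent brute-force oracle (`brute_force_allele_counts()`), a plain
exhaustive enumeration with no propagation and no component graphs, refuses
instances above 12 monokaryons and backs the solver in the test suite over
hundreds of randomized instances, masked and unmasked.

Di–mon rows never contribute allele labels: the bundled records type only
mon–mon-crossed isolates, and an all-compatible di–mon row is weak evidence
by nature. `check_dimon_consistency()` instead enumerates every dikaryon
genotype over a bounded universe — observed alleles plus two fresh per
locus, sufficient because the compatibility predicate only distinguishes
equal-to-observed from different — and reports whether a row is satisfiable
and whether every satisfying genotype would require a novel allele.

On the bundled study this machinery reproduces the published deduction
end-to-end: the 50%-compatible M-8 × M-13 block forces the shared matB
identifications during propagation, and the minimum over the 20
natural-isolate testers is 10 *matA* and 8 *matB* classes (unique up to
relabelling; 12 and 10 with the M-38 reference panel):

```{r headline}
res <- infer_study_alleles()
res
attr(res, "propagated")$forced
```

A note on the fixtures: the panel table labels the M-13 testers B7/B8 while
the mutual-cross table's header uses B3/B4 for the same testers — the
post-deduction labels. The bundled `panels.yaml` records the post-deduction
genotypes; nothing in the inference consumes genotype labels, so the
discrepancy is display-only. The M-14/M-17 crosses are recorded in the
source only as a statement of full compatibility; the fixture
`table2_stated.csv` encodes that statement as all-`+` blocks, and the
8-class *matB* result depends on it. Footnote markers on table cells are
stripped on parse; their quantitative meaning is not documented in the
available text.

## The simulator and what passing tests show

`simulate_population()` draws dikaryotic isolates from allele pools at the
two loci (rejection sampling keeps each isolate heteroallelic at both),
derives tester panels, and predicts crossing tables under the mating rule.
Defaults — pools of 24 *matA* and 21 *matB* alleles, 17 isolates, uniform
frequencies, error rate 0 — mirror the allelic richness and sample size of
the population work the crossing study belongs to. A Dirichlet frequency
option exists because natural allele spectra are skewed; it is an
extension, not a calibrated claim. Scoring noise is a symmetric per-cell
flip, default 0, since clamp scoring is treated as reliable in the source
records.

With full pairwise crossing and no noise, recovery is exact by
construction: any two truly distinct alleles among the testers are forced
apart by some `+` cell (each panel carries both of its *matB* classes with
each *matA* class, so a distinguishing partner always exists), and the true
assignment is itself consistent, pinning the minimum to the truth. The
round-trip tests therefore demonstrate correctness of the machinery, not
robustness: real crossing series are incomplete and occasionally
mis-scored, masked-cell behaviour is exercised separately (counts are
monotone in evidence), and noisy tables may simply be inconsistent — the
package reports the offending cell rather than repairing it.

`generate_hd_protein()` emulates the features the protein analyses detect:
hydrophilic-biased composition (residue weights decay exponentially in the
Kyte–Doolittle value) with targeted resampling until no 19-residue window
exceeds the transmembrane cutoff, exactly one `WFXNXR` instance placed
uniformly in the class-specific window (125–175 for HD1, 145–200 for HD2 —
the species-specific intervals; the broader cross-species ranges of
120–190/140–195 are not used), HD1 drawn 40–50 residues longer than its
paired HD2, and an `HNPYP[TS]` instance in HD1 only. The N-terminal
variability rate (default 0.5 over the first 60 residues) is a free
parameter: no quantitative divergence level between allelic N-termini is
established, so the default is a package choice, documented here and not a
claim about real proteins. Synthetic sequences share none of the real
proteins' phylogenetic signal; tests on them validate the detectors'
contracts, not homology-scale conclusions.

## Protein analyses: parameters and conventions

* Positions are 1-based and inclusive throughout, matching residue-number
  reporting conventions.
* `kd_profile()` uses the published Kyte–Doolittle scale (shipped as a
  documented constant table) and a sliding arithmetic mean; window 19 and
  transmembrane threshold 1.6 are the conventional parameters for
  transmembrane detection and are exposed as arguments, since the method
  name alone does not fix them. `call_globular()` reports maximal
  above-threshold runs of window centres; raising the threshold can split
  or shrink regions but never creates new territory (tested as
  containment).
* `nls_screen()` is a pure composition heuristic — windows (default 7)
  with at least `min_fraction` (default 4/7) of K/R or of P/H, merged when
  overlapping. It does not reproduce trained localization predictors'
  probability outputs, which depend on their training corpora and are out
  of scope. Note that a genuinely basic stretch can still fall below the
  4/7 default — the bundled homeobox fragments peak at 2 basic residues
  per 7-mer and score no candidate at the default.
* The motif grammar is deliberately tiny: residue letters, `X` wildcard,
  one-of `[..]` sets. All occurrences are reported, overlapping included;
  scanning is case-insensitive and validates the alphabet, naming the
  first offending position.
* `locus_model()` encodes cassette order and orientation only (`mip`
  first, `fg` last, 1–3 `hd` genes between, divergent `hd1.1`/`hd1.2`);
  GFF3 coordinates are ordinal placeholders at fixed slot width because no
  base-pair coordinates are modelled.

## Problem sizes and numerical choices

The analysis scripts and tests run at the scales the data dictates: the
bundled study (20–24 testers) solves in well under a second; simulation
calibration uses one default-scale population (17 isolates, 68 testers,
~1 s) plus replicate sweeps at smaller pools; solver-vs-oracle checks use
instances of 4–10 monokaryons where exhaustive enumeration is cheap.
Degenerate inputs are defined rather than special-cased where a convention
exists (empty constraint sets give one class per locus per monokaryon set;
an empty monokaryon set gives zero counts) and errors where they signal
data problems (asymmetric records, self-compatibility, unknown symbols,
ragged tables).

## Known limitations

* Minimal counts are lower bounds by design; they cannot exceed the
  evidence, and sparse matrices can merge classes that more crossing would
  separate.
* The di–mon analysis is consistency checking, not inference; rows
  incompatible with every bounded-universe genotype are flagged, nothing
  more.
* No likelihood model of population allele frequencies is provided: the
  package counts classes, it does not estimate total population
  allelicity.
* The protein battery is sequence-composition level; alignment, secondary
  structure and trained localization predictors are intentionally outside
  its scope.
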