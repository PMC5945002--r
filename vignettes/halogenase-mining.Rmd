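---
title: "Mining metagenomes for flavin-dependent halogenases: methods and design"
author: "fhalminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metagenomes for flavin-dependent halogenases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhalminer)
```

## The problem

Flavin-dependent halogenases (FHals) install halogen atoms on aromatic
substrates with high regioselectivity, needing only FADH2, O2 and a halide
ion. Two family-wide sequence fingerprints make them findable by homology:
the Rossmann-like FAD-binding module `GxGxxG` near the N-terminus and the
`WxWxIP` motif thought to prevent the enzyme from acting as a
monooxygenase, together with a conserved catalytic lysine/glutamate pair.
The family splits into variant A (free substrates) and variant B
(carrier-protein-bound substrates); variant B proteins run roughly 70
residues shorter.

This package implements the mining procedure such a screen needs — profile
HMM construction, gene prediction, scoring, filtering and phylogenetic
classification — as ordinary, testable R functions, and pairs it with a
synthetic-metagenome generator so that the entire pipeline can be
exercised and quantified without any external downloads.

## The profile HMM and its scoring model

`buildHmm()` estimates a minimal Plan7-style profile from a multiple
alignment. Columns with non-gap occupancy at or above
`occupancyThreshold` (default 0.5, the conventional majority rule) become
match states. All estimates use a background-proportional pseudocount with
total weight `pseudocountWeight` (default 1):

$$\hat e_k(a) = \frac{c_k(a) + w\, q(a)}{n_k + w}$$

where $c_k$ are observed counts, $q$ the background and $n_k$ the number
of observed residues. Transitions are counted along each row's implied
match/insert/delete path and smoothed the same way (uniform prior per
bundle). Insert emissions are pooled across all insert columns and shared
by every insert state. The background $q$ is a fixed embedded
Robinson–Robinson-style frequency table rather than anything derived from
the training data, so bit scores are comparable across models.

Scoring uses a **single-hit local** architecture: an alignment fragment
enters at any match state $k$ and exits from any later match state $l$,
with the uniform fragment prior $P(k, l) = 2 / (L(L+1))$; flanking
residues are emitted by the null model on both sides of the odds ratio and
therefore cost nothing. `forwardBits()` reports
$\log_2 P(x\,|\,\text{model}) / P(x\,|\,\text{null})$ summed over all
paths; `viterbiAlign()` reports the best path, with ties broken
deterministically (match over delete over insert), and returns the
residue-to-match-column map that downstream motif anchoring uses.
Residues `X` score zero bits wherever they fall. The recurrences run in
C++; the test suite pins them, case by case, to an exhaustive
path-enumeration oracle on all-small models.

Rare D→I and I→D transitions observed in training alignments are folded
into the neighbouring M→I / M→D counts rather than modelled as their own
states; profile HMM builders conventionally suppress these transitions,
and keeping the state graph minimal keeps the enumeration oracle exact.

## E-values

Bit scores of unrelated sequences under a profile HMM follow a Gumbel
distribution. `calibrateHmm()` scores `nDecoys` i.i.d. background
sequences (defaults: 200 decoys of length 400 — enough for a stable ML
fit while keeping calibration to a few seconds) and fits location and
scale by maximum likelihood; `evalueFromFit()` then converts a score into
the expected number of decoy hits in a database of $N$ sequences,

$$E(S) = N\,(1 - e^{-e^{-\lambda (S - \mu)}}),$$

computed via `expm1` so astronomically small E-values remain accurate.

These E-values are internally consistent but **not numerically HMMER3's**.
The literal cutoff `1e-150` quoted in published FHal screens was defined
against HMMER3 scores; importing it verbatim into a different scorer would
be meaningless. The pipeline therefore stores that number only as
provenance (`paperEvalueCutoff`) and derives its operational cutoff from
its own calibration: `evalueMax = decoyFpr * dbSize` with
`decoyFpr = 1e-6` by default, i.e. an expected 10^-6 decoy false positives
per scored sequence. On the synthetic benchmark, planted genes sit
hundreds of bits above the decoy distribution, so any cutoff in a wide
range separates them identically; the choice is logged in every run
summary.

## Gene prediction and completeness

`findOrfs()` scans all six frames. Within one stop-bounded segment the
ORF from the earliest start codon is reported (so one ORF per segment);
segments running off a contig edge are reported as partial ORFs with
`has_start`/`has_stop` flags cleared. This deliberately moves the
complete/partial decision out of the gene finder and into the
completeness filter, which is where the mining procedure's accounting
happens. The default start-codon set is `{ATG}` with `GTG/TTG` available
by option, and the default `minAa = 100` suppresses spurious micro-ORFs
while passing every known FHal (~460–540 aa). Codons containing `N`
translate to `X` and never act as start or stop.

`assessCompleteness()` is the conjunction of four criteria, each carrying
a human-readable failure reason: start and stop present; every required
motif present (`GxGxxG` and `WxWxIP` by default — the catalytic Lys/Glu
mapping is reported but deliberately not part of the verdict, since the
family literature lists "conserved regions" without mandating which);
protein length within 460–600 aa (wide enough for variant A near 510–540
and variant B ~70 shorter — known FHal sizes anchor the window, e.g. a
1593-bp/530-aa exemplar gene); and the E-value cutoff above.

## Seed expansion and alignment

`collectHomologs()` retains database sequences reaching 50% identity and
90% coverage of a characterised reference in an exact Smith–Waterman
local alignment (BLOSUM62, gap open 11 / extend 1 — the BLAST protein
scoring family). Identity is defined as identical columns over **all**
alignment columns including gaps, and coverage is computed with the
characterised reference as the query; both choices are stated because
threshold semantics are otherwise ambiguous. The pairwise engine is
`Biostrings::pairwiseAlignment`, cross-checked in the tests against an
exhaustive enumeration of local alignments on short pairs.

`progressiveMsa()` is a single progressive pass: a UPGMA guide tree from
3-mer count distances, then profile–profile merges with sum-of-pairs
BLOSUM62 scoring and affine gaps. Iterative refinement is intentionally
absent: what the pipeline needs from this alignment is a sound profile
HMM, which the downstream discrimination tests measure directly.

## Phylogenetics and variant classification

Distances are p-distances with **pairwise deletion** (per pair, only
columns where both sequences carry residues), preserving signal on
partial-length candidates; a Poisson correction $-\ln(1-p)$ is available.
Trees come from Saitou–Nei neighbour joining (`ape::nj`), with negative
branch lengths clamped to zero and reported. Bootstrap supports follow
the classic Felsenstein procedure — resample columns, rebuild, count
bipartitions of the full-data tree — with 1000 replicates by default.
Which distance model the original MEGA7-based analyses used is not
recoverable; p-distance is this package's stated default and no claim is
made of replicating any published topology.

`classifyVariant()` assigns the class of the smallest bipartition side
containing the query and references of exactly one class. When every such
side is mixed, it falls back to the length prior: variant B runs
`deltaAa = 70` residues shorter, so the query goes to whichever class
mean reference length is closer. The evidence (`clade` or
`length_prior`) is recorded with each call.

The candidate-plus-reference alignment fed to the tree is produced by
`hmmAlign()`, which places each sequence's Viterbi-matched residues into
the model's match columns — the profile-anchored analogue of aligning
everything jointly, and consistent across candidates by construction.

## Mass utilities

`monoisotopicMass()` sums isotope masses from an embedded table
(most-abundant isotope by default, explicit choices for halogens) under
the **neutral molecule** convention with no proton or electron
adjustment; that convention matches how calculated masses for halogenated
indoles are conventionally printed. Display rounding is three decimals,
half-up (`roundHalfUp`), because R's `round` applies banker's rounding.
`halogenPattern()` enumerates Cl/Br isotope assignments, collapses mass
degeneracies, and weights peaks by natural abundances (79Br 0.5069 /
81Br 0.4931; 35Cl 0.7576 / 37Cl 0.2424), giving the diagnostic ~1.998 Da
bromine doublet at near 1:1 intensity.

## The synthetic benchmark: what it does and does not emulate

`makeReferenceModels()` builds two related family models: variant A with
535 match states carrying the canonical anchor layout (`GxGxxG` at
columns 16–21, K at 83, `WxWxIP` at 275–280, E at 349 — the coordinates
characterised FHals actually exhibit), and variant B exactly 70 columns
shorter, derived from A by deleting a C-terminal block and re-drawing a
quarter of the remaining non-motif consensus columns. Motif columns emit
their consensus with probability 0.998, plain columns 0.75; indel
transition probabilities are 0.002 per position. These choices make
planted genes behave like real family members: they score far above
decoys under the A model, occasionally lose a motif or drift slightly in
length (so filters have genuine work to do), and the two variants are
homologous yet separable.

`makeBenchmark()` plants one element per contig (so planted genes never
overlap) on i.i.d. background sequence at configurable GC, with partial
genes truncated by 35% at a contig edge so that a start or stop is
destroyed. Decoys are half shuffled planted proteins (testing the score
filter) and half "monooxygenase-like" sequences with `WxWxIP` ablated but
`GxGxxG` intact (testing the motif filter specifically, since they pass
the score filter as true homologs). Reverse translation uses uniform
synonymous codons — codon bias is irrelevant to every downstream
computation tested. The default cohort (42 complete variant-A genes among
254 planted elements) echoes a familiar published cohort shape purely as
a default; it is a simulation, not a reproduction of any published count.

What passing tests on this benchmark show: the pipeline recovers planted
homologous genes with the stated recall, rejects both decoy classes for
the stated reasons, and keeps its accounting consistent. What they do not
show: behaviour on real metagenomes with fragmented assemblies, chimeric
contigs, skewed taxonomic composition, or family members far from the
model — the generator draws from the same family models the screen uses,
which is the favourable case.

## Numerical and reproducibility choices

* All stochastic operations take explicit seeds; the package default is
  1699, and every run summary echoes seeds and thresholds.
* Internal coordinates follow the 1-based inclusive convention of
  `GRanges` end to end, which is also the GFF3 on-disk convention — one
  convention everywhere rather than a 0-based internal/1-based external
  split.
* Gumbel fitting solves the scale's ML estimating equation by
  root-finding on centred scores; degenerate (zero-variance) score
  samples are a calibration error, not a silent fallback.
* Overlapping ORF predictions are resolved best-score-wins across frames
  and strands before filtering, because the unit of interest is the gene.
* The test suite runs the full-size default benchmark (254 elements,
  ~1.2 Mb of contigs, bootstrap 200 on the classification tree) once in
  the acceptance suite and small cohorts (~15 elements, bootstrap 30–50)
  elsewhere; the unit-test sizes are chosen to exercise every code path
  in seconds while the acceptance run measures the study-scale
  behaviour.

## Known limitations

* E-values are scorer-specific; users comparing against HMMER3 must
  re-derive cutoffs (the package derives its own from calibration).
* The progressive aligner has no refinement pass and the profile HMM has
  no multihit or glocal modes — adequate for single-domain FHal genes,
  not for multidomain architectures.
* Variant classification depends on reference choice; with fewer than two
  references per class it abstains rather than guesses.
* The BrvH-like fixture shipped in `inst/extdata` is a synthetic
  stand-in constructed at the published anchor coordinates for testing
  motif and mapping machinery; it is not the biological sequence.
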