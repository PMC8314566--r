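---
title: "Curating and dissecting repetitive silk fibroin genes"
author: "fibroinArch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and dissecting repetitive silk fibroin genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroinArch)
```

## The problem

Heavy-chain fibroin (H-fibroin) genes of silk-producing Lepidoptera carry a
central repetitive domain of tandem repeat units, flanked by short unique
N- and C-terminal domains. In bagworm moths (Psychidae) each repeat unit
combines, in fixed order, four motif regions:

1. **poly-A-E** — a polyalanine run interrupted by a single central
   glutamic acid, `(A)nE(A)n`;
2. **pure GA** — alternating glycine–alanine;
3. **linker** — a short isoleucine/valine stretch;
4. **GA-S** — a second GA region carrying interspersed serines.

The poly-A-E and pure GA regions form β-sheet crystallites in the spun
fibre; the linker and GA-S region form the amorphous matrix. The balance
between these two parts — the *crystalline fraction* of a repeat unit —
co-varies with fibre mechanics across silks: species whose fibroins devote
a larger fraction of each unit to crystalline motifs tend to spin fibres
with lower tensile strength, with extensibility and toughness largely
unaffected.

Two computational obstacles stand between short-read data and this kind of
analysis. First, the repetitive domain collapses in de Bruijn graph
assemblies, so the gene must be *curated*: rebuilt base by base from the
reads, starting from a unique terminal seed. Second, the rebuilt protein
must be *segmented* into its motif regions before lengths, compositions and
crystalline fractions can be measured. This package implements both steps,
the downstream statistics, and a synthetic-data generator that makes every
stage testable against known ground truth.

## Seed-extension curation

`extendSeed()` implements consensus seed extension. Reads containing the
terminal `k`-mer of the growing sequence as an **exact** match are
harvested (both orientations) and aligned on the 3′ side of the match; the
bases one position past the 3′ end form a position-weight-matrix column,
and the column's modal base is appended iff

* the column depth is at least `minDepth` (default 3), and
* the modal fraction is at least `minDominantFrac` (default 0.9), with
  ties always failing as `AMBIGUOUS`.

Both comparisons are inclusive. One base is committed per column call and
reads are re-harvested at every appended base through a prebuilt exact
k-mer hash index, so each harvest is a constant-time lookup. The default
`k = 75` — half a 150 bp read — trades anchor specificity against depth:
large enough that a single k-mer is effectively unique outside tandem
repeats, small enough that roughly half of each overlapping read still
votes past the anchor.

Extension stops when a column fails (`LOW_DEPTH`/`AMBIGUOUS`), when
nothing anchors or nothing extends (`NO_READS`), at a hard cap
(`MAX_LENGTH`), or — the intended stop on a fibroin gene — when the
terminal `repeatWindow`-mer the next base would create already occurs
earlier in the curated sequence (`REPEAT_DETECTED`). That recurrence is the
operational signature of having entered the *second* copy of a tandem
repeat unit: the offending base is not appended, so the curated sequence
ends exactly one repeat window minus one base past the first unit
boundary. Extension is strictly 3′-ward; the C-terminal side of a gene is
curated by reverse-complementing seed and reads.

Seeds themselves come from `findTerminalSeeds()`, which scores contigs
against reference terminal sequences by Smith–Waterman local alignment
(match +2 / mismatch −3, affine gaps charged `opening 5 + 2·length`;
BLOSUM62 with 11/1 gaps across all six translated frames in `translated`
mode), strand-normalising the hits so extension always proceeds 3′-ward.

### When is consensus extension across a tandem array well posed?

A subtlety worth making explicit: in an array of `n` nucleotide-identical
units, the PWM column at the *exit* of a unit receives votes from all `n`
copies of the terminal k-mer — `n − 1` of them continue into the next unit,
one (the last copy) continues into the C-terminal domain. The dominant
fraction at that single column is therefore about `(n − 1)/n`, and the
strict default threshold of 0.9 requires roughly ten or more units for the
extension to traverse the first unit boundary and reach the repeat-entry
stop. The curation demonstrations in this package consequently use a ~3 kb
gene of 17 short units (43 aa each) rather than a few long units; real
H-fibroins, with their tens of repeat units, sit comfortably in this
regime. With fewer units the honest outcome is an `AMBIGUOUS` stop *at*
the unit boundary, which still leaves the curated prefix exactly correct.

A related boundary effect: because read start positions are uniform over
the template, coverage tapers linearly over the final read length of a
simulated molecule, so extension on a non-repetitive template ends a
handful of bases short of the very end (when the depth threshold collapses)
rather than exactly at it. The curated prefix remains exact; only the last
few, essentially uncoverable, bases are unreachable.

## Motif segmentation

`segmentRepetitiveDomain()` types every residue of a protein. An anchor
pass finds all poly-A-E regions (maximal A-runs of at least `minPolyARun =
4`, optionally interrupted by exactly one E with qualifying runs on both
sides) and all I/V linker runs (at least `minLinkerRun = 2`). Gap typing
is then *positional*: a gap from a poly-A-E anchor to the next linker is
`GA_PURE`; from a linker to the next poly-A-E is `GA_SER`. Composition
only validates the call — a gap whose canonical-residue fraction falls
below `1 − maxImpurityFrac` (default impurity 0.1), or a post-linker gap
with no serine at all (when `requireSer`), is left `UNASSIGNED` rather
than forced into a type. Residues outside the anchored span are
`TERMINAL`; after the final linker the maximal G/A/S prefix is still typed
`GA_SER` so the last unit is not lost to the C-terminal domain.

`minPolyARun = 4` is chosen so that the single alanines inside a GA
alternation can never open a poly-A anchor. One genuine ambiguity needs an
explicit rule: a GA region closes on `…GA`, so its final alanine is
swallowed by the maximal A-run of the following poly-A anchor, leaving the
gap with a dangling `G`. When an internal linker→poly-A gap ends in `G`,
the segmenter returns one alanine from the anchor to the gap (provided the
anchor's leading run stays above `minPolyARun`). This keeps segmentation
of generated proteins identical to the generator's ground truth.

All intervals are IRanges (1-based, closed) in memory; file exports use
the BED convention (0-based, half-open).

From a segmentation, `splitRepeatUnits()` opens a unit at each poly-A-E
region, `motifLengthStats()` tabulates per-species motif-length
distributions (a final partial unit contributes only the types it
contains, so type means are not deflated), `aaFrequency()` gives
20-component composition vectors, and `crystallineFraction()` scores

$$f_c = \frac{|{\rm polyAE}| + |{\rm GA_{pure}}|}{|{\rm unit}|},$$

length-weighted across units for whole proteins.

## Statistics

`pearsonR()` (product-moment correlation with the t-transform p-value on
n−2 df) is used for between-species amino-acid-frequency comparisons;
`welchT()` (unequal-variance t-test with Welch–Satterthwaite df) compares
fibre-property groups — Welch rather than pooled-variance because fibre
groups typically have unequal sizes and variances, and two-sided
throughout; `crystallinityTrend()` joins per-fibre mechanics with
per-species crystalline fractions, averages per species (one point per
species), and reports Pearson r, the least-squares slope, and a strict
monotone-decrease flag. No multiple-testing correction is applied; p-values
are reported raw.

## The synthetic-data generator

`generateFibroinProtein()` builds proteins from an
`architectureParams()` description. Defaults are the canonical bagworm
architecture: a 23-residue poly-A-E motif (`polyAHalfLen = 11`), 40-residue
pure GA, 6-residue linker, 90-residue GA-S, five units, 120 aa terminals.
Choices that go beyond those numbers, and why:

* **Jitter** (`jitter = 0.1` by default) perturbs GA and linker lengths
  multiplicatively by ±10% per unit but leaves the poly-A-E motif fixed —
  mirroring the observation that the poly-A-E length is conserved across
  bagworm species while GA lengths vary. No per-unit variance is published;
  ±10% makes length-recovery tests non-trivial without blurring the 2:1
  between-species contrasts.
* **Serine placement** is deterministic: `round(serRate · len/2)` serines
  at evenly spaced block centres of the GA-S region, with the GA
  alternation re-phasing after each serine (`…GA S GA…`) and an even
  post-serine tail so the region always closes on `…GA`. `serRate = 0.25`
  gives a serine density comparable to serine-containing GA motifs of real
  H-fibroins.
* **Terminal domains** are random sequences with alanine capped at 5% and
  never consecutive, no consecutive I/V residues, no trailing A/E on the
  N-terminal side and no leading G/A/S/E on the C-terminal side — so a
  synthetic terminal can never create or extend a segmentation anchor, and
  terminal seeds never satisfy the repeat detector.
* **Codon structure** (`generateFibroinGene()`): terminals get independent
  uniform-random codons; all repeat units share one per-unit codon stream.
  Units are therefore nucleotide-identical wherever their amino acids agree
  — emulating the nucleotide homogeneity of recently expanded silk-gene
  repeats — yet free of the short internal periodicity that a
  fixed-codon-table translation would introduce. Both properties are needed
  for repeat entry to be a well-defined, detectable event.

`simulateReads()` produces uniform-start, optionally strand-flipped reads
with i.i.d. substitution errors (no indels, no pairing, no quality model —
the curation algorithm consumes reads individually and ignores qualities;
FASTQ output carries a constant Q40 string only to be well formed).
`generateMechDataset()` draws per-fibre tensile records from normals
truncated at zero, with species-mean strength following a configurable
line in crystalline fraction. The default five species span fractions
0.20–0.50 with strengths from ~1300 down to ~700 MPa (slope −2000 MPa per
unit fraction), i.e. the spider-dragline-to-cocoon-silk range; moduli,
extensibilities and toughnesses default to lepidopteran-typical scales
(8 GPa, 25%, 150 MJ/m³).

What the generator does **not** emulate: sequencing indels and quality
decay, paired-end structure, codon-usage bias, inter-unit sequence
divergence beyond length jitter, expression-dependent coverage, or any
wet-lab variability in tensile testing. Tests passing on this generator
show that the algorithms are correct under their stated model, not that
real libraries are this clean.

## Numerical and degenerate-input conventions

* Threshold comparisons in consensus calling are inclusive; modal ties are
  always `AMBIGUOUS`, never broken arbitrarily.
* `welchT()` on two identical constant groups returns t = 0, p = 1 by
  convention; `pearsonR()` refuses constant vectors.
* `tensileSummary()` reports SD 0 with a `singleFibre` flag for n = 1.
* An anchor-free protein segments as all-`TERMINAL`; an empty anchor list
  yields an empty PWM, and a column of depth 0 ends PWM construction.
* All randomness flows through explicit seeds (`withr::with_seed`), and
  every pipeline stage derives its seed from the single configured one, so
  whole runs are bit-reproducible.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at deliberately compact
scales chosen to exercise every code path: toy single-unit proteins for
exact examples; 5-unit genes (~160 aa units) for segmentation recovery and
species contrasts (5 genes per species); a 17-unit ~3 kb gene at 30×
coverage for curation-to-repeat-entry; twenty 2 kb non-repetitive templates
at 50× / 0.5% error for noise robustness; and 100 seeded replicates
(5 species × 8 fibres) for trend recovery. These sizes are the package's
demonstration conditions, not limits of the implementation.

## Known limitations

* Curation assumes substitution-only noise; an indel in a high-coverage
  region would end extension early rather than be corrected.
* Repeat-entry detection presumes nucleotide-homogeneous units; strongly
  diverged units instead end extension with `AMBIGUOUS` at the divergence
  point (the curated prefix stays correct).
* Segmentation is rule-based and tuned to the four-motif bagworm grammar;
  fibroins with other repeat grammars will come back mostly `UNASSIGNED`.
* The crystalline fraction is a sequence-level prediction; it stands in
  for, but does not replace, diffraction- or spectroscopy-based
  crystallinity measurements.
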