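---
title: "Measuring codon usage bias: models, estimators and design choices"
author: "cubkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

Synonymous codons encode the same amino acid but are used at unequal
frequencies. Two forces dominate the explanations: mutation pressure,
which shifts base composition (most visibly at the nearly neutral third
codon position), and translational selection, which favors codons
matched to the tRNA pool, particularly in highly expressed genes. In
AT-rich genomes such as those of ants and other Hymenoptera the bias is
typically weak and tilted toward A/U-ending codons, and the interesting
question is how much of it composition alone explains. `cubkit`
implements the standard toolbox for that question on any set of
in-frame coding sequences.

## Data model

All analysis flows through two S4 objects. `GeneticCode` is a
table-driven model of the standard nuclear code in the RNA alphabet:
the 64-codon map, the synonymous families (alphabetically ordered, so
every output table is deterministic), the degeneracy classes
(2 one-fold, 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold amino
acids) and the 59-codon analysis set — all sense codons minus Met (AUG)
and Trp (UGG), which have no synonyms; the three stops (UAA, UAG, UGA)
are excluded throughout. DNA input is transcribed to RNA at read time
because the field reports codons in RNA form.

`CodonUsageSet` extends `SummarizedExperiment`: a `counts` assay of 64
codon rows by one column per gene, with per-gene statistics accumulated
in `colData` by `addComposition()` and `addCubIndices()`. Counting uses
`Biostrings::oligonucleotideFrequency(width = 3, step = 3)`, which
silently skips triplets containing ambiguity codes; the skip count is
kept per gene.

### Ingestion policy

`readCdsFasta()` assumes upstream ORF calling produced in-frame CDSs.
By default it excludes records whose length is not a multiple of 3
(`PARTIAL_LENGTH`; a permissive mode truncates to the last full codon
instead) or that contain an internal stop (`INTERNAL_STOP`), logging
every exclusion; records with ambiguity codes are kept, their affected
codons skipped at counting. Duplicate ids get ordinal suffixes with a
warning. A terminal stop codon is dropped before counting by default:
whether classic tools included it in their input is generally
unknowable from published tables, so we pick the convention that keeps
stop counts at zero and record it in the serialized run config. Genes
shorter than `minCodons` (default 30 codons) keep their counts but
receive `NA` bias indices — ENC and CAI are unstable on very short
genes, and 30 codons is the smallest length at which most degeneracy
classes are even populated.

## Estimators

**RSCU.** `RSCU_ij = X_ij / ((1/N_i) Σ_j X_ij)`: 1 means no bias within
the family; families with zero observed codons are reported `NA`
(undefined), never 0. Fully observed family sums equal the family size
by construction, which the tests assert.

**ENC.** The formula-based Wright-style estimator: per family with
`n ≥ 2` observed codons, homozygosity `F̂ = (nΣp² − 1)/(n − 1)`;
class averages `F̄_k`; `ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`.
Numerical edge rules, chosen for compatibility with the behavior of the
classic CodonW implementation: families with fewer than 2 observed
codons are skipped; a missing three-fold class (only Ile) is imputed as
`F̄₃ = (F̄₂ + F̄₄)/2`; any other missing or non-positive class average
makes ENC undefined (`NA`, logged, never an exception); results are
clamped at 61 (sampling noise can push the raw value slightly above).
The estimator carries a finite-sample correction, so ENC is only
asymptotically invariant to scaling all counts — RSCU and CAI are
exactly invariant, and the tests distinguish the two behaviors.

**Expected ENC.** `ENC_exp = 2 + s + 29/(s² + (1−s)²)` with `s = GC3s`,
the GC fraction at third positions of codons whose amino acid has at
least two synonyms. The deviation ratio `(ENC_exp − ENC_obs)/ENC_exp`
is histogrammed on fixed edges
`[−0.25, −0.15), [−0.15, −0.05), [−0.05, 0.05), [0.05, 0.15),
[0.15, 0.25), [0.25, 0.35]` (left-closed, last bin closed; values
outside tallied separately), the conventional reporting layout for this
quantity. "On or near the expected curve" is operationalized as the
central bin, `|ratio| < 0.05`.

**Permutation null.** Published analyses sometimes quote a permutation
count for the deviation ratio without defining the permutation unit. We
interpret it as a per-gene synonymous shuffle: resample the gene's
codons uniformly within each family, conditional on family totals (the
amino-acid sequence content is preserved), recomputing ENC, GC3s,
expected ENC and the ratio on each draw. This is the natural null of
"no codon preference given the protein", is seed-deterministic, and
yields a two-sided empirical p-value with the add-one correction. The
direct per-gene ratio is always reported alongside; the null is opt-in
(`nPerm` in `runConfig()`, default 0) because it costs
`nPerm × ENC` evaluations per gene.

**CAI.** Geometric mean of codon weights over a gene's codons,
excluding Met, Trp and stops. Weights are pooled-reference RSCU
normalized by the family maximum; codons absent from the reference are
floored at 0.01 (the customary smoothing that keeps the geometric mean
finite), and reference-empty families get weight 1 with a warning. No
expression data is assumed: the default reference is self-referential —
the lowest-ENC 5% of genes (at least 10), i.e. the most biased genes
stand in for "highly expressed". An external reference FASTA can be
supplied instead, and the provenance string travels with the weights.
Because the reference construction is a free choice, CAI values are
comparable within one convention only.

**CBI / FOP.** `FOP = N_opt/N_tot` over synonymous codons and
`CBI = (N_opt − N_rand)/(N_tot − N_rand)`, with `N_rand` the optimal
count expected under uniform family usage; CBI is 0 for uniform usage
by construction. The optimal set defaults to the preferred codons
(pooled RSCU > 1, strict inequality) of the analyzed set itself,
overridable — classic tools shipped fixed optimal sets per model
organism, which is not portable across taxa.

**Neutrality plot and PR2.** OLS of GC12 on GC3 with Pearson r (the
standard diagnostic; slope/r near 1 means one mutational driver moves
all positions). PR2 plots `A3/(A3+U3)` against `G3/(G3+C3)`; the
default site set is all synonymous third positions, with
`fourfold_only` available because classic parity analyses restrict to
fourfold-degenerate blocks (here: the five four-fold families plus the
CUN, UCN, CGN blocks of Leu/Ser/Arg). Points exactly on 0.5 go to an
axis bucket and are excluded from quadrant counts — a deterministic tie
rule, since published quadrant counts never state one. Quadrant I is
`(x > 0.5, y > 0.5)`, numbered counter-clockwise. Species-level GC
tables are emitted under both gene-mean and concatenated aggregation,
labelled, because published per-species GC tables rarely say which was
used. Pearson is used for the neutrality diagnostic and Spearman for
the CAI–ENC association (robust to the nonlinearity expected there);
both are reported.

## The synthetic generator

`syntheticSpec()`/`generateCdsSet()` emulate the statistical structure
the diagnostics are designed to detect, not ant biology. Per gene:
length from a rounded Gaussian (default mean 380 aa, sd 120, floor 50 —
the scale of typical transcriptome-wide mean protein lengths); a
per-gene GC3 driver from a Beta distribution (default mean 0.46, the
AT-leaning composition typical of the motivating data; sd 0.08); amino
acids iid; codons drawn within each family with GC-ending codons
sharing probability `d` and A/U-ending sharing `1 − d` — normalized per
family so the synonymous GC3 expectation equals the driver exactly for
every family (including Ile's asymmetric 2 A/U : 1 C split) — times an
exponential selection tilt `exp(strength)` on the optimal set (default:
one U- or A-ending codon per family). A terminal UAA is appended.
`gc12Coupling` tilts each gene's amino-acid frequencies (1-D
root-finding on the exponential tilt parameter) so that expected GC12
tracks the driver with the given slope: coupling 1 emulates a shared
mutational driver (neutrality r near 1), coupling 0 a pinned protein
composition (r near 0). The default 0.3 is an intermediate regime so
that no diagnostic is trivially saturated. The truth record carries the
per-gene driver and the closed-form GC3s expectation, so recovery is
checkable analytically.

What the generator does **not** emulate: expression levels and their
correlation with bias, codon autocorrelation along genes, amino-acid
composition differences between genes, isoforms, UTRs, or sequencing
error. Passing recovery tests therefore demonstrates estimator
correctness and pipeline plumbing, not that real transcriptomes behave
like the model.

```{r recovery, eval = FALSE}
rep <- recoverySuite(list(
  syntheticSpec(selectionStrength = 0, seed = 1),
  syntheticSpec(selectionStrength = 2, seed = 2),
  syntheticSpec(selectionStrength = 4, seed = 3)
))
rep$checks
```

## Problem sizes and determinism

The shipped tests run the estimators against independent brute-force
oracles on 100 random count tables, and the recovery properties on
synthetic sets of 60–150 genes (150–250 aa); the acceptance-style
checks use 500 genes at the default length. These sizes give standard
errors comfortably inside the asserted bounds while keeping the suite
fast. All randomness is seeded; `generateCdsSet()` and
`permutationNull()` save and restore the global RNG state, and
identical configs reproduce byte-identical output files.

## Known limitations

- Only the standard nuclear genetic code ships; the table-driven
  `GeneticCode` leaves room for alternatives but none are wired in.
- CAI/CBI/FOP depend on reference and optimal-set conventions; values
  from other tools (fixed E. coli/yeast references, organism-specific
  optimal sets) are not directly comparable.
- ENC is undefined on genes missing a required degeneracy class (apart
  from the Ile imputation); very short or compositionally extreme genes
  are reported `NA` rather than guessed.
- No correspondence analysis, tAI, codon-pair statistics, or
  phylogenetically corrected regressions.
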