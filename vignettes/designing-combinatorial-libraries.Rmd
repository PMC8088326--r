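---
title: "Designing degenerate and spiked codon libraries with degenDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate and spiked codon libraries with degenDesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenDesign)
```

## The design problem

Combinatorial protein libraries are usually synthesized from a single
DNA oligonucleotide in which some codon positions are *degenerate*: at a
degenerate position the synthesizer couples a mixture of nucleotides, so
one tube of DNA encodes an astronomical number of protein variants.
Classical repeats of NNN or NNK maximize coverage but give no control
over the *amino-acid composition* of the library, which is exactly the
property of interest when studying composition-driven phenomena such as
intrinsic disorder, liquid–liquid phase separation or solubility of
random-sequence proteins.

degenDesign addresses the complementary design task: given a desired
overall amino-acid distribution \(D\) (a vector of 21 non-negative
weights — 20 residues plus STOP — summing to 1) and a randomized-region
length \(l\), find an ordered multiset \(M\) of \(l\) codons whose
*mixture distribution* — the average of the per-codon amino-acid
distributions — is as close to \(D\) as possible, while guaranteeing
that no forbidden codon (stop codons, rare codons, reassigned codons)
can be produced anywhere in the template.

## Codon algebra

A codon is modelled as a 12-tuple
\((T_1,C_1,A_1,G_1,\,T_2,C_2,A_2,G_2,\,T_3,C_3,A_3,G_3)\)
of per-position nucleotide fractions, each positional 4-block summing
to 1.  The binary *base-codon* records only the support — which
nucleotides are allowed at each position.  With the empty block
excluded there are \(15^3 = 3375\) base-codons, in bijection with the
3-letter strings over the 15 IUPAC ambiguity codes:

```{r}
fromIUPAC("NNS")
nrow(enumerateBaseCodons())
```

A *degenerate* codon is a base-codon with equimolar fractions on its
support; a *spiked* codon carries arbitrary ratios.  The amino-acid
distribution of a codon follows from position independence: the weight
of residue \(s\) is \(\sum_{xyz \to s} f_1(x) f_2(y) f_3(z)\).  A
multiset cannot produce forbidden codon \(f\) iff some tuple position
required by \(f\) has zero weight — a purely combinatorial test that
`excludesCodon()` applies to every designed codon.

## The search

Distances between \(D\) and the mixture are measured by a norm of the
difference vector; the L2 norm is the default because it penalizes large
per-residue deviations strongly while tolerating many small ones (L1 and
L∞ are available; for deviations below 1 the L2 norm upper-bounds both
the mean squared error and its square root scale, so an L2 guarantee is
the most conservative of the common readouts).

The optimizer is a stochastic local search, faithful to a deliberately
simple move set:

1. Pre-select the pool: from the 3375 base-codons keep those whose
   expansion avoids every forbidden codon and encodes only residues with
   positive target weight.  Stop codons are forbidden by default so
   templates cannot encode premature terminators; residues with target
   weight exactly 0 are excluded at the codon level.
2. Initialize \(M\) with \(l\) random proposals from the pool.
3. Repeat: draw a random base-codon from the pool, make a random codon
   from it (equimolar in degenerate mode; in spiked mode each positional
   block is drawn from a flat Dirichlet over its support — the
   maximum-entropy choice given only the support), replace a uniformly
   random element of \(M\), and accept iff the distance *strictly*
   decreases (ties reject).
4. Stop after `rejectionFactor * l` consecutive rejections
   (default 1000, so \(1000\,l\) rejected mutations).

The replaced element is chosen independently of the proposal, and the
accepted-objective trace is non-increasing by construction.  Because
whole-codon redraws are the only default move, spiked mode explores
ratio space purely through fresh Dirichlet draws; an optional
`localPerturb` move that re-draws a single positional block of an
existing codon is available behind a flag for users who want finer late-
stage refinement, but it is off by default so that the default behaviour
matches the plain move set described above.  Replicate \(k\) of a
replicated run uses seed `seed + k - 1` and the best replicate (lowest
final distance, ties to the lowest index) is returned; identical
configuration and seed reproduce results bit for bit, because the
compiled search loop consumes R's own RNG stream.

```{r}
early10 <- readTargetDistribution(
  system.file("extdata", "target_early_alphabet.tsv",
              package = "degenDesign"))
res <- designLibrary(early10, length = 12, mode = "spiked",
                     replicates = 3, seed = 1)
res
```

## Tunable parameters

* `length` — codons in the randomized region.  Precision improves with
  length: more codons give the mixture more degrees of freedom.
* `mode` — `"degenerate"` restricts to the 3375 equimolar codons (what
  any synthesis provider accepts); `"spiked"` allows arbitrary ratios
  (custom nucleotide mixes) and is at least as precise in expectation
  since degenerate codons are a subset of its search space.
* `norm` — objective norm; default `"L2"` (dimensionless, on the (0,1)
  probability scale).
* `rejectionFactor` — patience of the stopping rule, in rejected
  proposals per codon; default 1000.  Larger values trade time for
  precision with quickly diminishing returns.
* `forbidden`, `forbidStops`, `maxDegeneracy` — hard constraints on the
  pool.  `codonUsage` with `minUsage` implements organism-specific codon
  preference as a *hard filter* (rare codons join the forbidden set)
  rather than an objective term, so the reported distance keeps its
  meaning; this is a deliberate interpretation of usage-aware design.
* `quantizationStep` (export) — spiked ratios are kept continuous during
  optimization and only rounded at export (default 1%, the resolution a
  synthesis order sheet typically accepts); rounding never removes a
  support nucleotide and re-normalizes each block to exactly 100%.

## In-silico validation

`sampleSequences()` draws concrete sequences from a design by sampling
every randomized nucleotide position independently according to its
fractions.  This emulates an *ideal* synthesis: exact mixing ratios,
no position coupling, no synthesis or sequencing errors.  Real
oligonucleotide batches show provider-dependent nucleotide-composition
bias, and downstream transcription/translation/purification introduce
further compositional shifts — none of which the sampler models, so
passing in-silico checks demonstrates correctness of the *design*, not
of any physical library made from it.

On the sampled set the package computes: pooled residue composition and
its deviation from the target (distance metrics on the (0,1) scale and
per-residue percentage points on the (0,100) scale), the uniqueness
fraction (distinct/total, DNA level by default), per-position nucleotide
frequencies (rows T, C, A, G — ready for sequence logos), and the
expected molecular-weight distribution.  Mass statistics exclude
stop-containing sequences — they would not yield the tagged full-length
protein — but report how many were excluded; the closed-form mode
conditions each codon on not being a stop, which matches that exclusion
rule exactly and serves as an independent oracle for the sampled mode.
Average residue masses are the default (matching linear-mode MALDI-TOF);
monoisotopic masses are available.  Exact DNA diversity is the product
of per-position support sizes, computed in arbitrary precision; protein
diversity is estimated by birthday-collision counting on a seeded
sample, and is reported as `Inf` when the sample is collision-free
(diversity beyond what the sample size can resolve).

```{r}
v <- validateTemplate(bestMultiset(res), n = 20000, target = early10,
                      seed = 1)
v$stats
v$mass$mean
```

## Numerical choices

* Acceptance uses strict floating-point comparison; equal objectives
  reject, so the search cannot drift across plateaus.
* The mixture distribution is maintained incrementally inside the
  compiled loop and re-summed every 4096 acceptances to cap round-off
  drift; the final reported distance is always recomputed from scratch.
* Degenerate-mode proposals reuse exact pre-computed pool
  distributions, so degenerate runs are unaffected by Dirichlet
  sampling noise.
* Quantization repairs block sums by decrementing the largest entries
  (never below one step on the support) and incrementing the entries
  with the largest rounding deficit.
* Empty pools after pre-selection are an error at design time; an
  all-constraining `enumerateBaseCodons()` call returns an empty matrix
  with a warning, since enumeration itself has no failure mode.

## Problem sizes in the test suite

The shipped tests exercise the published problem scales — 33-codon
designs on a 10-residue alphabet and 100-codon designs on the full
20-residue alphabet, 10 replicates each — while Monte-Carlo checks use
20 000–100 000 sampled sequences, sizes at which binomial standard
errors are far below the asserted tolerances yet runs complete in
seconds.  Larger samples change nothing qualitatively; the convergence
checks scale as \(1/\sqrt{n}\).

## Known limitations

* The optimizer controls the *overall* composition; it places no
  position-specific constraints and no covariation structure (tools
  built around integer programming serve that niche).
* Minimizing the number of distinct degenerate codons is a non-goal;
  templates typically use many different codons.
* Protein-level diversity has no exact closed form here; the collision
  estimator assumes near-uniform sequence probabilities and
  underestimates diversity for strongly skewed designs.
* The 21st distribution symbol is STOP by convention; codon
  reassignment can relabel codons (including stops) to user-defined
  symbols, but closed-form mass accounting is only defined for the 20
  canonical residues.
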