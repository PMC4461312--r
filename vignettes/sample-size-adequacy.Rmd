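---
title: "How many individuals per sample? Methods behind commsize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many individuals per sample? Methods behind commsize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commsize)
```

## The question

Multivariate community ecology works from taxon-by-sample count matrices:
one row per collected sample, one column per taxon, entries counting
individuals.  Collecting and identifying individuals costs time and money,
so a practical question is how small the *sample size* — the number of
individuals in one row, not the number of rows — can be before ordination
and matrix-correlation results stop being the results one would have
obtained with a larger collection.

`commsize` answers it by simulation.  A complete dataset is rarefied: every
sample is subsampled without replacement to a fixed proportion of its
individuals (defaults 50%, 25%, 10%, 5%, 2.5%; many replicates per
proportion), and each subsampled matrix is compared with the complete one
by two statistics:

* **Mantel R** between the Bray-Curtis dissimilarity matrices of the
  subsample and the complete data — the Pearson correlation of their
  off-diagonal entries, with a permutation test that jointly relabels the
  rows and columns of one matrix;
* **PROTEST concordance** between their two-dimensional NMDS ordinations —
  one minus the symmetric Procrustes residual after translation, rotation,
  reflection and dilation, on a 0–1 scale with 1 meaning identical
  ordinations, with a row-permutation test.

Plotting the mean (± SD) of each statistic against the mean median
subsample size produces a curve that is flat (a plateau) at large sizes and
falls off below some size.  The breakpoint of that curve is the smallest
sample size that still reproduces the full-data result.

## Models and components

### Dissimilarity

Bray–Curtis, `d(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)`, is computed on raw
counts through `vegan::vegdist()`.  No standardisation or transformation is
applied anywhere in the pipeline — ordinations run without
auto-transformation — so the analysis sees absolute abundance structure.
Euclidean and city-block distances are available for parity checks, as is
a Monte-Carlo Raup–Crick index (presence/absence; the null fixes each
sample's richness with equiprobable taxa, and the dissimilarity is the
observed-included probability of sharing at least as many taxa as
observed).  The published Raup–Crick variants differ in their null models;
since this measure only serves qualitative parity checks, the simplest
richness-preserving null was chosen.

### NMDS

Ordinations are two-dimensional non-metric MDS minimising Kruskal
stress-1, `sqrt(Σ(d_ij − d̂_ij)² / Σ d_ij²)`, where the disparities `d̂`
are the least-squares monotone (pool-adjacent-violators) fit of the
configuration distances to the dissimilarity ranks.  `isotonicFit()` and
`stress1()` expose these pieces; the iterative engine behind
`nmdsOrdination()` is `vegan::monoMDS` (global model, stress-1), wrapped
with a multi-start protocol: one classical-scaling start plus `nStarts`
random starts (default 20), keeping the lowest-stress centred solution.
Convergence is declared when the relative stress change drops below `tol`
(default 1e-6) or after `maxIter` (default 200) iterations.  Zero
dissimilarities between distinct samples would break rank ordering and are
nudged by +1e-12.  In `isotonicFit()` tied dissimilarities receive a
common disparity (the tie block is averaged); the untied treatment, which
leaves ties free, is available via `ties = "untied"`.  `monoMDS` uses the
free-tie treatment internally, so for data with many ties the stress
reported by `nmdsOrdination()` can sit slightly below `stress1()` on the
same configuration; Bray–Curtis values on count data are almost always
tie-free.

### Procrustes and PROTEST

`procrustesFit()` computes the least-squares superimposition (SVD of the
cross-product; reflections permitted; optimal dilation) either
symmetrically (both configurations centred and scaled to unit sum of
squares — the default, making the residual symmetric in its arguments) or
as the classical asymmetric best fit.  `protestTest()` reports
`concordance = 1 − ss` from the symmetric fit.  The community literature
reports this quantity as an "m²-value" oriented so that values near 1 mean
near-identical ordinations, which is the opposite orientation of the
classical Procrustes m² residual; `commsize` follows the 0–1,
1-is-identical orientation and exposes the raw residual alongside.

Both permutation tests use the observed-included convention
`p = (hits + 1) / (permutations + 1)`, so p is never exactly zero and the
test is valid at any permutation count.

### Subsampling

`subsampleCounts()` draws k individuals uniformly without replacement from
one sample's pool (a multivariate hypergeometric draw), implemented as
sequential conditional hypergeometric draws per taxon rather than explicit
pool shuffling; `subsampleMatrix()` vectorises the same scheme across
rows.  Each row's target is `k = max(1, round(p × rowsum))` with
round-half-up: the floor of one individual keeps every row defined for
Bray–Curtis at the smallest proportions (2.5% of a 20-individual sample
would otherwise be empty), and rows are never dropped so subsample and
complete matrices stay paired.  Taxa left unobserved everywhere are
dropped, which cannot change Bray–Curtis values.

### Threshold detection

Published analyses of plateau-then-decline curves typically read the
breaking point off the figure.  `detectThreshold()` formalises it: the
pooled (mean statistic, mean median size) points are fitted with a
continuous two-segment piecewise-linear model in log10(size), the
breakpoint grid-searched over the observed sizes.  A breakpoint is only
declared when the two-segment fit improves the residual sum of squares by
at least `minImprovement` (default 5%), the right segment is flat
(|slope| ≤ `plateauSlopeTol`, default 0.1 per log10 unit) and the left
segment rises.  Otherwise the curve is flagged as having no breakpoint and
the plateau value falls back to the overall mean.

## The synthetic datasets

### Gradient-simulated communities

`simulateGradientDataset()` emulates sampling along a one-dimensional
environmental gradient of length G.  Each taxon has a Gaussian response
curve — optimum `mu ~ Uniform(1, G)`, niche breadth
`sigma ~ Uniform(0.05 G, 0.25 G)`, peak abundance `~ Uniform(1, 100)` —
and each sample sits at a distinct integer position (unique integers in
1..G; designs with more samples than positions fall back to uniform real
positions).  The count of a taxon in a sample is its curve height at the
sample's position, rounded half-up.  The sigma and peak ranges are design
choices: they put median sample sizes for G = 100 designs in the hundreds
to low thousands, the same order as the designs this generator emulates.
The 22-row design grid (`gradientDesignTable()`) crosses 15–200 samples,
15–200 taxa and gradient lengths 100–5000; desk-scale runs cap G at 100
because long-gradient rows produce samples of tens of thousands of
individuals whose subsampling dominates runtime without changing the
plateau behaviour.

### Evenness-controlled ("selected abundance") communities

`buildSelectedDataset()` builds datasets of 200 individuals per sample —
chosen so the five proportions give subsample sizes 100, 50, 20, 10, 5 —
with per-sample Pielou evenness controlled by a geometric rank-abundance
series whose decay is solved numerically (then integerised by largest
remainder, every taxon kept at one individual or more) so that realised J
hits its target.  Class targets are J = 0.58 (low) and J = 0.79 (high);
`"mixed"` datasets alternate the two.

Samples within a dataset differ along a *dominance gradient*: per-sample J
targets are spread symmetrically around the class target, so each sample
is a different community but the class mean stays on target.
`structureId` (1–9) sets the compositional range of the gradient — the
Bray–Curtis distance between the first and last community,
`0.20 + 0.05 × structureId` — and the J half-width needed to traverse that
range is solved per class.  This calibration is deliberate: low- and
high-evenness datasets then cover the *same* dissimilarity range, so
comparisons between the classes isolate within-sample evenness (and the
subsampling noise it induces) from between-sample structure.  During
design we found that schemes which instead rotate or slide taxon
identities across samples make steep rank-abundance distributions saturate
the dissimilarity matrix (most pairs nearly equidistant), which destroys
the Mantel signal for low-evenness data and inverts the evenness
comparison; the dominance-gradient construction avoids that confound.

What these generators do *not* emulate: spatial autocorrelation, species
interactions, skewed (non-Gaussian) response curves, patchiness, or the
hand-picked idiosyncrasies of real published tables.  Passing tests on
these data show that the pipeline recovers the plateau behaviour and
evenness effects for gradient-structured and dominance-structured
communities; they are not evidence about, say, zero-inflated or strongly
clustered field data.

## Reproducibility and numerical choices

Every stochastic component takes a seed; suite generation, the replicate
stream and the permutation tests derive per-unit seeds deterministically
from (master seed, indices), so any dataset or replicate can be rebuilt in
isolation and any execution order gives identical aggregated output.
Failed replicates (e.g. a subsample collapsing below two observed taxa)
are recorded with a flag and excluded from aggregation rather than
aborting a run.  Medians of even-length size vectors use the mean of the
two middle values.  Pielou's J for a single-taxon sample is undefined
(ln S = 0) and reported as `NA`, excluded from means, rather than coerced.

Dataset-level summaries report the mean of per-sample J values; computing
J on pooled counts is the plausible alternative, and for strongly
heterogeneous datasets the two differ.

## Problem sizes used in the packaged checks

The experiment shipped with the tests and the acceptance
script uses one dataset per design row (22 datasets), five proportions,
100 replicates per proportion, 199 Mantel permutations, and NMDS from the
classical-scaling start only.  These sizes were chosen as the package's
desk-scale standard: they keep a full regeneration in the ten-minute range
on a single core while leaving Monte-Carlo error on per-point means near
±0.01.  The evenness comparison uses 24 low- and 24 high-evenness datasets
(structure ids 1–4) at the 25% proportion (subsample size 50) with 50
replicates.  The full-scale protocol (10 replicates per design row, 1000
subsample replicates, 999 permutations, 20 random NMDS starts) is a
parameter change away and alters none of the code paths.

## Known limitations

* NMDS inside the replicate loop starts from classical scaling only by
  default; rugged stress surfaces (rare at these sizes) could leave a
  replicate in a local optimum.  Raising `nmdsStarts` trades time for
  assurance.
* The Raup–Crick implementation is one of several published dialects and
  is intended for qualitative parity checks only.
* Threshold detection assumes one plateau and one decline; curves with
  multiple regimes will return the best single breakpoint with the
  no-breakpoint flag cleared only if the fit genuinely improves.
* With 100 replicates, per-point mean statistics carry Monte-Carlo noise
  of roughly ±0.01; borderline points near a threshold can flip between
  runs with different master seeds.
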