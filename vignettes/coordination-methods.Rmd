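---
title: "Measuring transcriptome coordination with the composite correlation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptome coordination with the composite correlation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`coordpc` asks, for every gene, whether its pattern of co-expression with the
rest of the transcriptome is the same in two conditions. Within each
condition the gene's *coordination profile* is its vector of Pearson
correlations with every other analysed gene, estimated across the condition's
samples. The *composite correlation index* Pc is the Pearson correlation of
the two profiles across conditions. Pc is a per-gene, whole-transcriptome
summary: it does not require choosing modules, thresholds or networks first,
and it is insensitive to the gene's own expression level (Pearson correlation
is invariant to positive affine transforms of the gene's expression).

The approach assumes that (i) within-condition expression covariance is
informative, i.e. the samples are biological replicates whose
inter-individual variation reflects shared regulation — the method is at its
best in genetically diverse (outbred) cohorts, where this variation is large;
(ii) the two conditions are measured on a common gene universe; and (iii)
linear association is an adequate summary of co-expression (the package is
deliberately Pearson-only; rank alternatives would measure a different
quantity and are out of scope).

### Estimation and its noise floor

With `S` samples per condition, each correlation in a profile is estimated
with standard error of roughly `1/sqrt(S - 1)`. Pc correlates two such noisy
vectors of length `G_analyzed - 1`, so its own sampling noise is small, but
the *attenuation* of Pc toward zero is substantial at small `S`: partners
whose true correlation with the focal gene is 0 contribute pure noise to both
profiles. At the reference depth of this field (n = 6 animals per age group)
even fully retained genes rarely exceed Pc ≈ 0.3 on raw CPM; the meaningful
readout is the *relative* position of genes and cohorts, not the absolute
magnitude. This is also why the negative-Pc fraction at n = 6 exceeds the
true inverted fraction — a point quantified by the synthetic generator below.

## Pipeline choices

**Normalisation.** Counts are scaled to counts per million (CPM) per sample;
correlation is computed on raw CPM by default. `log2(CPM + pseudocount)` is an
explicit opt-in (`log_transform = TRUE`, pseudocount default 1): the log
stabilises heavy-tailed expression and typically strengthens correlation
estimates, but it changes what is being correlated, so the default stays on
the raw scale. No expression filter is applied by default; `min_mean_cpm`
exists because very low, noise-dominated genes dilute profiles, and setting
it is a legitimate analysis decision we leave to the user (default 0 = off).

**Gene universes.** When the two conditions were quantified separately their
gene sets can differ. `harmonize_genes()` keeps the intersection (in the
first table's order) and reports what was dropped. Zero-filling absent genes
was rejected: a gene absent from one condition's quantification has no
defined correlation there, and zero-filling would fabricate perfect negative
or positive structure.

**Degenerate genes.** Pearson correlation is undefined for constant vectors.
Genes with zero variance in either condition are excluded both as focal genes
and as partners, and flagged (`zero_variance_young` / `zero_variance_old`)
with `pc = NA` — never an imputed value. Assigning such genes r = 0 would
bias every other gene's Pc toward 0. Partners whose correlation is undefined
in only one condition are dropped pairwise from both profiles
(`n_partners_used` records the remainder); a focal gene left with fewer than
3 usable partners is flagged `insufficient_partners`.

**Self-correlation.** A gene's correlation with itself is identically 1 in
both conditions; including it would add a guaranteed matching point to every
profile and mechanically inflate Pc toward +1. The diagonal is therefore
excluded, and profiles have exactly `G_analyzed - 1` entries.

**Blocking.** Profiles are computed from row-standardised expression via
crossproducts, in blocks of `block_size` focal genes (default 1024), so peak
memory is O(G × block_size) rather than O(G²). The result is exactly
independent of `block_size` (asserted by test); blocking is purely an
execution detail. A 5,000-gene, 6+6-sample dataset completes in seconds on
one core, and ~20,000 genes remain comfortably tractable.

**Numerical tolerances.** Correlations are computed in double precision and
clipped into [-1, 1] with tolerance 1e-12 (crossproduct rounding can exceed
|1| by a few ulps). The blocked engine agrees with a naive full-matrix
computation to < 1e-10 elementwise on every fixture tested.

### Exact and approximate invariances

Several identities are exact and tested: identical conditions give Pc = 1
everywhere; reflecting one gene's expression about its mean in one condition
gives that gene Pc = -1, flips every correlation involving it, and leaves all
*other gene-pair correlations* untouched; positive affine transforms change
nothing. One caution: reflecting gene *g* does perturb other genes' Pc
*values* slightly, because each other gene's profile contains the single
flipped entry r(·, g). The perturbation is one coordinate out of
`G_analyzed - 1` and vanishes with transcriptome size, but "all other genes
unchanged" is exact only at the level of pairwise correlations, not of their
Pc summaries.

## Comparing cohorts

`summarize_pc()` reports mean and median Pc and the percentage of genes with
Pc < 0 — the fraction whose coordination inverted. Both mean and median are
always reported: cohort differences are conventionally quoted as averages
while distribution figures show medians, and the two can disagree for skewed
Pc distributions.

`compare_cohorts()` tests the difference between two cohorts' Pc
distributions with a two-sided Mann–Whitney U test by default (Pc is bounded
in [-1, 1] and typically non-normal; a Welch t-test is available via
`test = "welch"`). Because two transcriptomes rarely have the same number of
analysed genes, and the test's power grows with gene count, a
*size-normalised* comparison is reported alongside the raw one: the larger
cohort's Pc values are subsampled without replacement down to the smaller
cohort's size, the test recomputed over `n_draws` seeded draws (default
100), and the median statistic/p-value reported with the across-draw
interquartile spread. Subsampling is the most conservative reading of
"normalising for transcript number"; when the cohorts are equal-sized it
reduces to the raw test exactly. `quartile_report()` compares the top and
bottom 25% tails (floor(G/4) genes each, deterministic lexicographic
tie-break), which is where "few but drastic" and "many but subtle"
coordination changes separate.

`relative_expression_test()` reports the old/young fold change of mean CPM
with a two-sided Welch t-test — used to show that a coordination inversion is
not simply an expression change. Arithmetic means match how relative
expression bar plots are drawn; a geometric-mean option exists for skewed
genes. A zero young mean flags the fold change undefined rather than
reporting infinity.

## The synthetic generator

`simulate_coordination()` exists so the pipeline can be validated against
known truth without any external download. The model: genes belong to `M`
modules; gene g loads on its module factor with loading `±sqrt(rho)` (sign
random, fixed per gene); per sample, module factors and idiosyncratic noise
are standard normals, giving a latent
`z = lambda·factor + sqrt(1 - rho)·eps + noise_sd·eta` with unit-scale
variance. In the second condition, *inverted* genes flip their loading sign,
*decorrelated* genes load on a fresh private factor, and *retained* genes are
unchanged. Counts are negative-binomial with mean `exp(mean_log_expr + z)`
and dispersion `disp` (Poisson at `disp = 0`). Everything derives from one
seed; identical parameters give bit-identical datasets.

Decorrelated genes load on a *fresh independent factor* rather than
re-drawing the sign on the same module factor: a re-drawn sign would yield
either retention or inversion, whereas moving to a private factor makes the
gene's new profile orthogonal to the old one — which is what "loss of
coordination without inversion" means. Correspondingly the class ordering
mean(Pc | inverted) < mean(Pc | decorrelated) ≈ 0 < mean(Pc | retained)
holds at informative depth and is tested.

**Inversion is relative.** Flipping *every* gene's loading
(`f_invert = 1`) is a global sign change of each module factor and preserves
every pairwise correlation — the dataset reads as fully retained. More
generally, a gene's Pc is driven by the fraction of its partners whose flip
status differs from its own, so the median Pc across all genes is never
negative under this construct; what inversion produces is a *negative-Pc
class* when the inverted genes are a minority. Tests therefore assert class
separation at `f_invert < 0.5` and the sign-symmetry identity at
`f_invert = 1`, not a globally negative median.

**Defaults** (chosen once, as study conditions): `S = 6` samples per
condition, matching the cohort design this method targets; `f_invert = 0.25`
(observed inverted fractions in brain aging were 23–27%); `rho = 0.7`, a
strong but realistic within-module correlation; `G = 400` at desk scale;
`M = 10`, i.e. modules of ~40 genes, the scale of typical co-expression
modules; `noise_sd = 0.1`; `mean_log_expr = 5` (~150 reads); `disp = 0.1`, a
typical bulk biological dispersion. Two presets reproduce the qualitative
two-cohort contrast: `"bw"` (smaller universe G = 300, rho = 0.8, 23%
inverted, 10% decorrelated — fewer but more drastic changes, hence higher
median Pc and wider Pc range) and `"ll"` (G = 400, rho = 0.55, 27% inverted,
30% decorrelated — broad but subtle reorganisation, lower median, tighter
range).

**What the generator does not emulate:** species-specific annotation,
alignment and counting artifacts, batch effects, library-composition biases,
uneven module sizes (equal by default), inter-module correlation, and
condition-dependent expression *level* changes (latent means are equal by
construction, so fold changes are null). Passing recovery tests demonstrates
that the statistic and its implementation behave as designed under a known
covariance model — not that any particular biological dataset has this
structure.

**Power at the study's depth.** At n = 6 per group, recovery degrades
visibly: retained genes' Pc spreads enough that the negative fraction
overshoots the planted inverted fraction (~40% observed vs 25% planted at
the defaults), while class *ordering* persists in most seeds. At n = 12 the
negative fraction falls to ~30% and class separation is essentially complete
(AUC ≈ 0.97). This doubles as a statement about the design's power: per-gene
Pc values at n = 6 are noisy; cohort-level contrasts are the robust readout.

## Problem sizes in the test suite

Unit and property tests run at G = 4–50 with exhaustive or hand-computed
oracles; recovery and preset-contrast properties use G = 120–400 over 6–20
seeds; the scalability check runs G = 5,000 at 6+6 samples. These sizes were
chosen so the full suite exercises every code path, including blocking, at
desk scale; full transcriptomes (~20,000 genes) run through the identical
code with a larger gene count.

## Limitations

Pc compares correlation *profiles*; it cannot distinguish loss of
coordination (profile → noise) from genuine sign inversion at the level of a
single pair — the distinction emerges only across the whole profile.
Pearson on raw CPM is sensitive to heavy tails and outlying samples;
`log_transform = TRUE` is the first lever when profiles look
outlier-driven. At very small n the per-gene Pc is noisy and should be read
distributionally. Finally, the statistical comparison of cohorts treats
genes as exchangeable observations; genes are in reality correlated, so
p-values are calibrated for ranking and contrast, not as literal
gene-independent error rates — the same caveat that applies to any
transcriptome-wide distribution test.
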