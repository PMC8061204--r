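# coordpc

Whole-transcriptome expression **coordination** analysis between two
conditions, built around the **composite correlation index (Pc)**.

## The problem

Differential expression asks whether individual genes change their *level*
between conditions. In genetically diverse (outbred) cohorts, inter-individual
variation often drowns out level changes — but that same variation powers a
different question: does each gene keep its *pattern of co-expression* with
the rest of the transcriptome? During aging, for example, a gene's expression
level may barely move while the set of genes it rises and falls with is
completely reorganised, or even inverted. `coordpc` quantifies this for every
gene at once, without pre-selecting modules or networks.

## The statistic

For a gene *g* and condition *c* (say, young and old animals), let

    R_c(g, j) = Pearson correlation of g's expression with gene j's,
                across the samples of condition c, for every j ≠ g.

The vector `(R_c(g, j))_{j≠g}` is *g*'s coordination profile in condition
*c*. The composite correlation index is the Pearson correlation of the two
profiles:

    Pc(g) = cor( (R_young(g, j))_{j≠g}, (R_old(g, j))_{j≠g} )

- `Pc ≈ 1` — the gene's co-expression profile is retained (robustness),
- `Pc ≈ 0` — the profile dissolved (reorganisation / plasticity),
- `Pc < 0` — the profile inverted: partners that tracked the gene
  positively now track it negatively, and vice versa.

Inputs are RNA-seq counts normalised to counts per million (CPM); the
correlation engine works in blocks of focal genes so the full gene × gene
correlation matrix is never materialised and transcriptome-scale runs
(~20,000 genes, 6 samples per group) stay within ordinary memory.

The package also ships a seeded synthetic-count generator (latent-Gaussian
modular correlation structure → negative-binomial counts) with controllable
fractions of inverted and decorrelated genes, so the whole pipeline can be
validated against known truth.

## Worked example

Simulate a two-condition dataset in which a quarter of 400 genes invert their
coordination (6 samples per group, the depth typical of animal aging
cohorts), then recover the structure:

```r
library(coordpc)

sim <- simulate_coordination(sim_params(G = 400, S = 6, seed = 2024))
fit <- composite_pc(cpm_normalize(sim$counts_young),
                    cpm_normalize(sim$counts_old))
fit
#> <pc_fit> 400 genes analysed (of 400 input), 6 + 6 samples
#> # A tibble: 1 × 4
#>   mean_pc median_pc fraction_negative_percent g_analyzed
#>     <dbl>     <dbl>                     <dbl>      <int>
#> 1  0.0234    0.0286                      41.5        400
```

Mean Pc is positive — most genes keep their coordination — while 41.5% of
genes have negative Pc: the planted 25% of inverted genes plus retained genes
whose profiles are noisy at n = 6 (at n = 12 this fraction drops to ~30%;
the generator exists precisely to make such power statements checkable).

```r
top_ranked(fit, k = 5, direction = "lowest")
#> # A tibble: 5 × 3
#>   gene_id     pc  rank
#>   <chr>    <dbl> <int>
#> 1 G00188  -0.241     1
#> 2 G00032  -0.229     2
#> 3 G00259  -0.225     3
#> 4 G00340  -0.223     4
#> 5 G00068  -0.207     5

recovery_score(fit, sim$truth)$by_class
#> # A tibble: 2 × 4
#>   label        n mean_pc median_pc
#>   <chr>    <int>   <dbl>     <dbl>
#> 1 inverted   100 -0.0419   -0.0409
#> 2 retained   300  0.0452    0.0538
```

Known inverted genes average negative Pc, retained genes positive; the
rank-based separation between the classes is 0.75 (1 = perfect, 0.5 =
chance) at this sample size.

Downstream helpers cover the rest of the workflow: `compare_cohorts()`
(raw and size-normalised Mann–Whitney comparison of two cohorts' Pc
distributions, with top/bottom-quartile reports), `top_ranked()` /
`export_go_candidates()` (gene lists for external enrichment tools),
`gene_r_profiles()` + `plot_gene_profiles()` (per-gene young-vs-old
correlation violins), and `autoplot()` on fits and comparisons.

A command-line wrapper (`inst/scripts/coordpc`) exposes the same pipeline as
`simulate` / `pc` / `compare` subcommands for file-based runs; every stage
writes a manifest (parameters, seed, file hashes) for reproducibility.

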