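# regenatlas

Stage-resolved expression atlases for regeneration (and other
time-course) bulk RNA-seq experiments, with gene-set enrichment against
an explicit random-set null.

## The problem and the method

Regeneration time courses typically profile an uncut control and a
handful of post-amputation timepoints with 2–3 replicates each. The
question is *when* each gene is on, and which pathways are active at
each stage. `regenatlas` answers it in three steps:

1. **Pairwise differential expression.** After a low-count filter
   (keep a gene if ≥ 2 samples have ≥ 5 reads) and median-of-ratios
   normalisation, every pair of timepoints (optionally every pair of
   disjoint contiguous timepoint groups) is tested with a moderated
   negative-binomial Wald test: `log2FC = log2((m_b + ½)/(m_a + ½))` on
   normalised group means, SE from `Var(K/sf) = μ/sf + αμ²` with the
   gene-wise method-of-moments dispersion shrunk toward a fitted
   mean–dispersion trend, t reference, Benjamini–Hochberg FDR within
   each comparison.

2. **Binary pattern assignment** (the core algorithm). A gene's
   significant calls (FDR < 0.05) form a *hierarchy* of directed
   relations "higher at *a* than at *b*". Every binary pattern
   `b ∈ {0,1}^T` (1 = dynamically high at that timepoint) is scored
   against the hierarchy — each relation's "up" and "down" label scores
   +1 when matched, −1 when contradicted — and the maximum-scoring
   pattern is assigned (ties: fewest 1s, then lexicographic). The result
   is a binary gene × timepoint matrix, the atlas.

3. **Gene-set enrichment curves and ORA.** A curated gene set of
   effective size `s` is profiled along the atlas: at each timepoint the
   raw active percentage is compared with drawing `s` genes at random
   from the `N`-gene universe with `K_t` active — baseline `100·K_t/N`,
   one-SD band `100·sqrt(s·(K_t/N)(1−K_t/N)·(N−s)/(N−1))/s` (quantile
   bands available). Baseline and band are subtracted and floored at
   0%. Over-representation is additionally tested with the exact
   hypergeometric upper tail, `P(X ≥ k)`, BH-corrected across sets.
   Symbol-keyed sets are first translated to species gene ids through a
   homology map (unmapped symbols dropped, one-to-many expanded).

A negative-binomial simulator with planted binary patterns and planted
gene sets (`simulate_counts()`, `simulate_genesets()`) generates data
with known truth for validating every stage.

## Worked example

```r
library(regenatlas)

cfg <- sim_config(n_genes = 4000, seed = 42)   # default: control + 2/7/14/21 dpa
sim <- simulate_counts(cfg)
flt <- filter_genes(sim$counts)
flt
#> count_matrix: 3997 genes x 12 samples over 5 timepoints (control < 2dpa < 7dpa < 14dpa < 21dpa)

bmat <- binarize_all(run_de(flt))
table(rowSums(bmat))                 # genes by number of "high" timepoints
#>    0    1    2    3    4
#> 2629  328  420  423  197

g <- rownames(bmat)[rowSums(bmat) > 0][1]
rbind(recovered = bmat[g, ], truth = sim$truth$pattern[g, ])
#>           control 2dpa 7dpa 14dpa 21dpa
#> recovered       1    0    1     1     1
#> truth           1    0    1     1     1
```

About 70% of genes are flat (all-zero rows: no significant contrast
anywhere); the rest get a binary activity profile, here recovered
exactly for the first dynamic gene. Planting a 7 dpa-specific gene set
and profiling it:

```r
gs <- simulate_genesets(sim$truth, n_sets = 1, set_size = 20,
                        target_timepoint = "7dpa", purity = 0.8, seed = 7)
curve <- enrichment_curve(bmat, gs$planted[[1]], name = "planted@7dpa")
print(curve[, c("timepoint", "raw_percent", "baseline_percent",
                "adjusted_percent", "band_high")], digits = 3)
#>   timepoint raw_percent baseline_percent adjusted_percent band_high
#> 1   control           0             16.5              0.0      8.28
#> 2      2dpa           0             15.7              0.0      8.12
#> 3      7dpa          85             16.1             68.9      8.20
#> 4     14dpa           5             16.3              0.0      8.24
#> 5     21dpa           0             16.0              0.0      8.19
```

At 7 dpa 85% of the set is active against a ~16% random-set baseline:
adjusted enrichment 68.9%, far above the one-SD band (8.2%); everywhere
else the set is at or below baseline, so the floored adjusted value is
0%. `run_pipeline()` chains all stages from files to files (TSV/GMT in,
TSV/JSON plus a checksummed manifest out); see the vignette in
`vignettes/pattern-atlas.Rmd` for the model, parameter and design
discussion.

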