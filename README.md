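# fwdfungi

Fungal communities drive the decomposition of fine woody debris (FWD —
deadwood under 10 cm diameter, the bulk of the deadwood stock in managed
European forests). `fwdfungi` implements the quantitative analysis of
fungal community succession on decomposing beech (*Fagus sylvatica*) and
fir (*Abies alba*) branches in a factorial field design — tree species ×
canopy openness (open gap vs closed forest) × decomposition year — from
ITS-amplicon OTU tables through to community statistics and deadwood stock
estimates. It is aimed at microbial ecologists working with amplicon count
tables from time-series deadwood or litter experiments.

Everything is data-frame in, tibble out, and pipe-friendly. The package
covers:

* **Table preparation** — species-level OTU aggregation (97% identity /
  95% coverage best-hit rule, "`<genus>` sp." demotion, host-plant
  removal), rarefaction to a fixed depth (default 2,000 reads),
  relative abundances, Hellinger transformation, abundance filter presets
  and ecological guild profiles.
* **Diversity** — per-sample richness *S*, bias-corrected Chao1
  $S + F_1(F_1-1)/(2(F_2+1))$, Shannon–Wiener $H = -\sum p \ln p$ (nats),
  Pielou evenness $J = H/\ln S$.
* **Succession statistics** — per-taxon habitat specificity
  $S = \sum_{\text{ref}} p / \sum_{\text{all}} p$ (1 = beech- or
  closed-canopy-exclusive, 0.5 = indifferent, 0 = exclusive to the
  alternative), specialist classification at the inclusive 0.95/0.05
  thresholds, abundance-weighted succession time
  $T = \sum_y y\,w_y / \sum_y w_y$, and occurrence duration — the
  shortest contiguous run of years covering 90% of a taxon's relative
  abundance.
* **Permutation multivariate statistics, written from scratch** —
  PERMANOVA (distance-based linear model with Gower-centred sums of
  squares; one- or two-way with Type II term tests; free, restricted or
  exhaustive permutations), Mantel tests, vector fitting onto
  ordinations, variation partitioning with adjusted $R^2$, and 2-D NMDS
  minimising Kruskal stress-1 with isotonic regression and
  Guttman-transform updates.
* **Deadwood census** — per-hectare FWD stock by size class from
  2 × 2 m plot records (dry mass = wet mass × dry fraction, scaled by
  2,500 to the hectare) and the CWD-equivalent conversion (FWD turns over
  ~5× faster than coarse woody debris).
* **A synthetic-data generator** — reproduces the factorial design
  (4 blocks × 2 canopies × 8 samples × 6 years = 384 samples) with known
  per-taxon tree/canopy affinities and Gaussian temporal niches, so every
  estimator can be validated against recoverable ground truth.

## Worked example

```r
library(fwdfungi)

design <- generate_design()                       # 384 samples, 6 years
taxa   <- generate_taxa(200, seed = 1)            # known affinities
sim    <- generate_community_counts(design, taxa, depth = 2000, seed = 1)

rel  <- relative_abundance(sim$counts)
succ <- succession_table(rel, design)
head(succ, 3)
#> # A tibble: 3 x 7
#>   taxon_id s_tree class_tree s_canopy class_canopy succession_time duration
#>   <chr>     <dbl> <chr>         <dbl> <chr>                  <dbl>    <int>
#> 1 OTU0001   0.757 unspecific    0.271 unspecific              2.66        3
#> 2 OTU0002   0.391 unspecific    0.816 unspecific              1.17        2
#> 3 OTU0003   0.748 unspecific    0.668 unspecific              2.86        4
```

`s_tree = 1` flags a taxon found exclusively on beech deadwood;
`succession_time` is its mean position (in years) along decomposition,
and `duration` how many consecutive years hold 90% of its reads. On
simulated data these recover the generator's ground truth: mean
|Ŝ − π_tree| ≈ 0.04 for the most abundant quartile of taxa at the default
sequencing depth.

Community-level testing follows the same grammar:

```r
hel <- hellinger(sim$counts)
d   <- pairwise_distances(t(counts_matrix(hel)), "euclidean")
fit <- permanova(d, design, c("tree", "canopy"), n_perm = 999, seed = 1)
tidy(fit)
#> # A tibble: 3 x 6
#>   term           df    ss pseudo_f     r2 p_value
#>   <chr>       <int> <dbl>    <dbl>  <dbl>   <dbl>
#> 1 tree            1  20.6     31.1 0.0664   0.001
#> 2 canopy          1  23.1     34.9 0.0746   0.001
#> 3 tree:canopy     1  14.5     22.0 0.0470   0.001
```

The census module reproduces the stock arithmetic: a census averaging
5.3 t/ha of FWD corresponds, in yearly-production terms, to
`cwd_equivalent(5.3)` = 26.5 t/ha of coarse deadwood.

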