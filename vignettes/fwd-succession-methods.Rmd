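---
title: "Models and methods: fungal succession on fine woody debris"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fungal succession on fine woody debris}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwdfungi)
```

## The problem

Fine woody debris (FWD, deadwood under 10 cm diameter) decomposes within
roughly a decade, much faster than coarse deadwood, and carries its own
fungal community. `fwdfungi` analyses how those communities assemble and
turn over under a factorial field design: two host trees (beech, fir),
two canopy treatments (open gap vs closed forest, a microclimate
surrogate), four spatial blocks, six annual samplings. Each block ×
canopy stratum holds two pure-beech, two pure-fir and two mixed plots;
every composite sample comes from a branch of a single tree species, so
the mixture is a plot-level flag only. That yields 64 samples per year
and 384 in total at the defaults.

This vignette explains the statistical machinery, the choices behind it,
and what the simulation-based tests do and do not demonstrate.

## The synthetic-data generator

The generator is first-class: it encodes the study conditions as a
recoverable ground truth so every estimator can be validated end to end.

Each taxon *t* carries a tree affinity $\pi_{tree} \in [0,1]$, a canopy
affinity $\pi_{canopy}$, a temporal niche (peak year $\mu_t$, width
$\sigma_t$) and a base abundance scale. The expected (unnormalised)
abundance in sample *s* is

$$
\lambda_{ts} = base_t \cdot w_{tree} \cdot w_{canopy}
  \cdot \exp\!\left(-\frac{(year_s - \mu_t)^2}{2\sigma_t^2}\right),
$$

with $w_{tree} = \pi_{tree}$ on beech and $1-\pi_{tree}$ on fir
(analogously for canopy). The Gaussian kernel is a modelling choice: it
gives each taxon a single interpretable peak (its true succession time)
and width (its true duration), which is what the downstream statistics
estimate. Real successional niches can be skewed or multimodal; the tests
therefore demonstrate estimator correctness under a single-peak model,
not the shape of real niches.

Sample compositions are perturbed with a Dirichlet draw whose
concentration is the expected proportions divided by an `overdispersion`
parameter (total concentration $1/\text{overdispersion}$; default 0.05,
a moderate compositional noise typical of amplicon replicates), and reads
are drawn multinomially at a fixed depth, so every sample column sums
exactly to the sequencing depth. A hard specialist ($\pi = 1$ or $0$)
receives a zero concentration on the wrong substrate and can never
produce reads there.

By default 30% of taxa are hard specialists ($\pi \in \{0,1\}$ with
equal probability) and the rest draw affinities from Beta(2, 2). These
are generator conventions, not estimates: deadwood surveys commonly find
roughly a third of abundant fungi restricted to one host, which motivates
the default specialist share.

Wood chemistry follows fixed decomposition trajectories: pH linear 5.3 → 4.0
over years 1–6 in both trees; ergosterol (fungal biomass, µg per g dry
mass) 31 → 110 in beech over years 1–6 and 10 → 48 in fir over years
1–5 then flat; year-1 N 0.27% (beech) and 0.16% (fir). The remaining
trajectories are package choices: C starts at the year-1
C:N anchors (41.6% and 43.2%) and rises modestly, N is held flat, and
moisture rises with beech above fir. Within-year
noise is a free parameter, so noise
is Gaussian with standard deviation `noise_sd` × the variable's
year-1→year-6 range: one knob that behaves sensibly across units
(pH units vs µg/g vs %). Default `noise_sd = 0.05`; values are clipped
at physical bounds.

Every generator function derives its own RNG stream from the master seed,
so modules can be re-run independently and all outputs are byte-identical
under a fixed seed.

## Table preparation

* **Species aggregation.** OTUs whose best hit reaches 97% identity and
  95% coverage merge under the hit's binomial; others merge under
  "\<genus\> sp."; host-plant and non-fungal OTUs are discarded first.
  The aggregation key is the printed binomial string — no name
  harmonisation against external nomenclature services.
* **Rarefaction** draws reads without replacement to a common depth
  (default 2,000). Samples below depth are dropped and logged, not
  resampled with replacement — resampling would fabricate reads.
  Rarefaction order relative to species aggregation is a genuinely open
  choice; the pipeline aggregates first (so that
  counts merged across OTUs are subsampled once), and both orders are
  available by calling the functions directly.
* **Hellinger transformation** is the square root of relative
  abundances; each sample vector then has unit Euclidean norm, making
  Euclidean distances appropriate for species data.
* **Abundance filters.** Three presets mirror the displays they feed:
  `ordination` (relative abundance > 0.5% in ≥ 3 samples),
  `succession` (yearly abundance > 1% in ≥ 3 treatment-years, or a
  yearly maximum > 2%) and `specificity` (the ordination rule plus
  > 1% in ≥ 1 sample, hence always a subset). All comparisons are
  strict (abundance strictly over the threshold). A "yearly
  observation" is the mean relative abundance over the samples of one
  year within one tree × canopy treatment; the within-treatment mean is
  the convention adopted here.

## Succession statistics

For a taxon with per-sample relative abundances $p_{ts}$:

* **Specificity** $S = \sum_{s \in \text{ref}} p_{ts} / \sum_s p_{ts}$,
  with beech (closed canopy) as reference. Relative abundances — not raw
  counts — enter the sums, so unequal library sizes cannot bias $S$.
  A taxon absent everywhere is reported missing, never 0 or 1.
  Classification is inclusive at the bounds: $S \in [0.95, 1]$ is
  reference-specific, $S \in [0, 0.05]$ alternative-specific.
* **Succession time** $T = \sum_y y\,w_y / \sum_y w_y$ with $w_y$ the
  mean relative abundance across the samples of year $y$. Scale
  invariant; years are integers 1…6 and $T$ is a real.
* **Occurrence duration** is the length of the shortest *contiguous* run
  of years holding ≥ 90% of $\sum_y w_y$, earliest window on ties. Two
  conventions exist for such occupancy spans (contiguous-minimal window
  vs central percentile interval); the contiguous window is the
  default because it reads directly as "time span", and a
  central-interval variant (years between the 5th and 95th percentile of
  the cumulative profile) is available via `method = "central"`.
* Yearly profiles pool across treatments by default; computing them per
  treatment is a matter of subsetting the metadata before the call.

## Permutation multivariate statistics

All permutation machinery is implemented in the package (the established
community-ecology implementations serve as independent cross-checks in
the test suite, never as the computation path).

* **PERMANOVA** follows the distance-based linear model: the distance
  matrix is squared, halved, sign-flipped and double-centred (Gower);
  term sums of squares come from projections of the dummy-coded design.
  On Euclidean distances of 1-D data the pseudo-F equals the classical
  ANOVA F — an identity the tests verify to 10⁻⁹. Two-way designs use
  Type II term tests (each main effect adjusted for the other) with the
  residual from the full model; permutations shuffle sample identities
  freely by default; within-block restricted permutation, which the
  blocked field design can justify, is available via `strata`. For tiny
  one-way designs `permutations = "exact"` enumerates every label split.
  All permutation p-values use $(b+1)/(m+1)$ counting the observed
  statistic, so $p \ge 1/(m+1)$.
* **Mantel** correlates off-diagonal distances under simultaneous
  row/column permutation (default 99,999 permutations).
* **Vector fitting** regresses a covariate on the two ordination axes;
  the arrow is the unit coefficient vector, R² the explained fraction,
  significance by permuting the covariate (default 999 permutations).
* **Variation partitioning** uses redundancy-analysis R² with the
  Ezekiel adjustment $1-(1-R^2)(n-1)/(n-p-1)$; fractions satisfy
  $a+b = \text{adj}R^2(X_1)$, $b+c = \text{adj}R^2(X_2)$ by
  construction. Pure fractions are tested by permuting response rows
  and recomputing the semipartial R².
* **NMDS** minimises Kruskal stress-1 by alternating isotonic regression
  (primary treatment of ties) with Guttman-transform updates. A start
  stops as soon as an update fails to lower stress, so the reported
  stress path is non-increasing; restarts combine one metric-scaling
  (principal coordinates) start with random configurations, and the best
  solution is returned, rotated to principal axes for a reproducible
  orientation. Non-convergence within `max_iter` flags the result
  rather than failing.

## Diversity

Richness, Shannon–Wiener $H$ (natural log), Pielou evenness
$J = H/\ln S$ ($J = 1$ at $S = 1$ by convention), and Chao1 in the bias-corrected form
$S + F_1(F_1-1)/(2(F_2+1))$, which stays defined when no doubletons
exist; the classic form is available by flag.

## Deadwood census

Per plot and size class (0.5–1.5, 1.6–5.0, 5.1–10.0 cm), dry mass is wet
mass × dry-mass fraction, scaled by 10,000/area (2,500 for the 2 × 2 m
default) and averaged over plots. The field rule for edge pieces
(collected on the eastern/southern borders, discarded on the others) is a
sampling protocol, documented but not computable from the records. The
CWD equivalence multiplies a stock by the FWD:CWD turnover ratio
(default 5, from ~7-year vs 25–38-year half-lives); volume conversions
via wood density are out of scope.

## Numerical choices and degenerate inputs

* Zero-total samples error in normalisation (naming the sample); all-zero
  expected compositions error in the generator (naming the samples).
* Permutation p-values never fall below $1/(m+1)$; every result records
  its seed and permutation count.
* Spearman correlations use mid-ranks with the t approximation on
  $n-2$ degrees of freedom; zero rank variance reports missing.
* Kruskal–Wallis on an all-ties response reports $H = 0$ (no evidence)
  rather than NaN.
* Two-way ANOVA uses Type II sums of squares via residual-sum
  comparisons; a perfect fit reports infinite F where the term's SS is
  positive instead of dividing by zero.
* The duration window uses a $10^{-12}$ tolerance at exact 90% coverage
  so that a year holding exactly 90% counts as covering it.

## Problem sizes in the checks

The test suite and the acceptance script validate estimator calibration
at the design's full scale where it matters (384 samples × 200 taxa × depth
2,000, ten generator seeds for recovery; 1,000 null simulations at
n = 20 for PERMANOVA size) and at toy scale for the closed forms and
algebraic identities. At those settings the specificity estimator
recovers $\pi_{tree}$ with mean absolute error ≈ 0.04 for the most
abundant quartile, succession time within ≈ 0.14 years for narrow
temporal niches, and the PERMANOVA type-I error sits within [0.03, 0.07]
at α = 0.05.

## Known limitations

* The generator has no spatial autocorrelation among blocks, no
  copy-number variation, and no chimeras or clustering artefacts — it
  emulates the design, not the sequencer. Passing recovery tests shows
  the estimators are consistent under the stated model, not that real
  communities satisfy it.
* Field-data community statistics (PERMANOVA F values, variance
  fractions, specificity–time correlations) depend on the underlying
  sequencing data and cannot be checked from simulations; the package
  validates the machinery by calibration and algebraic identity, and
  reproduces the census and design arithmetic exactly.
* Linear mixed models and post-hoc letter displays are deliberately out
  of scope; standard packages cover them.
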