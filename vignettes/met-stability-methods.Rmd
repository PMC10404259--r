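---
title: "Methods: AMMI and GGE stability analysis for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AMMI and GGE stability analysis for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

Crop genotypes evaluated in several environments (years, locations,
seasons) rarely rank the same way everywhere. The non-additive part of
their performance — the genotype-by-environment interaction (GEI) —
determines whether a variety is broadly adapted or only wins in specific
conditions. `metstab` implements the standard analysis chain used in
plant-breeding multi-environment trials (METs) laid out as randomised
complete block designs (RCBD) repeated across environments: the AMMI
model, rank-based stability selection, and GGE biplot analytics,
together with a synthetic trial generator so each stage can be tested
against known truth. The motivating application is rainfed trials of
drought-tolerant groundnut cultivars, where yield and rain-water-use
efficiency (RUE) vary enormously between seasons.

## The AMMI model

For genotype $i$, environment $j$ and replicate $k$,

$$Y_{ijk} = \mu + G_i + E_j + \sum_{n=1}^{K} \lambda_n \alpha_{in}
\gamma_{jn} + d_{ij} + e_{ijk},$$

with grand mean $\mu$, centered main effects $G_i$ and $E_j$, and the
interaction written as the singular value decomposition of the doubly
centered cell-mean matrix
$Z_{ij} = \bar m_{ij} - \bar m_{i\cdot} - \bar m_{\cdot j} + \bar m$:
singular values $\lambda_n$ and interaction principal component (IPCA)
scores $\alpha_{in}$, $\gamma_{jn}$. With all $K = \min(g-1, e-1)$ axes
retained, the decomposition reconstructs every cell mean exactly (the
test suite asserts this to $10^{-10}$ relative error), and
$r \sum_n \lambda_n^2$ equals the interaction sum of squares.

### ANOVA conventions

The strata of the balanced layout are Environment ($e-1$ df),
replicates nested in environments Rep(E) ($e(r-1)$), Genotype ($g-1$),
GEI ($(g-1)(e-1)$) and Residuals ($e(g-1)(r-1)$); for the 30 × 3 × 2
design these are 2, 3, 29, 58 and 87. The sums of squares come from
`stats::aov()`; the design is orthogonal, so they equal the
from-definition deviation sums the test oracle computes with nested
loops. Two conventions are fixed where the literature is loose:

* **F denominators.** Environment is tested against the Rep(E) mean
  square — the standard choice when blocks are nested within
  environments — and every other effect, including each IPCA axis,
  against the pooled residual mean square.
* **IPCA df.** Axis $n$ receives the Gollob allocation
  $g + e - 1 - 2n$ (30 and 28 above, summing to the 58 interaction df).
  No permutation or cross-validation axis selection is offered.

The `%SS` column expresses the five main strata as percent of their
summed SS (so the shares add to 100); IPCA rows are instead expressed
as percent of the GEI SS, matching how such tables are printed.
Percentages are computed unrounded and rounded to two decimals only in
reports.

### Signal and noise

A purely random interaction stratum would accrue roughly its df times
the residual mean square, so the interaction SS is partitioned as

$$SS_{noise} = df_{GEI} \times MS_{resid}, \qquad
SS_{signal} = SS_{GEI} - SS_{noise}.$$

A noise estimate exceeding $SS_{GEI}$ is clamped with a warning. A high
signal share (above ~90%) indicates the multiplicative model is worth
interpreting.

## Stability indices

The modified AMMI stability index for genotype $i$ over the first $N'$
axes is

$$MASI_i = \sqrt{\sum_{n=1}^{N'} PC_{in}^2\, \theta_n^2},$$

where $PC_{in}$ is the genotype's IPCA score and $\theta_n$ the
proportion of interaction SS on axis $n$. Smaller is more stable. The
simultaneous selection index is the rank sum
$SSI = r_{MASI} + r_{mean}$, ranking MASI ascending and the genotype
marginal mean descending; the genotype with the lowest SSI combines
stability and performance.

Choices made here:

* **Score scaling.** MASI uses the symmetric-partition scores
  (singular-vector entry × $\sqrt{\lambda_n}$), which is what the
  common AMMI software reports; raw singular vectors are exported
  alongside.
* **$N'$ defaults to all $K$ axes.** With three environments only two
  axes exist, so the default and the "significant axes only" variant
  coincide in the motivating design; `n_axes` overrides it.
* **$\theta$ as proportions.** By scale equivariance (tested), a common
  rescaling of $\theta$ rescales MASI and leaves all ranks and the SSI
  unchanged, so the proportion convention is harmless.
* **Ties.** Ranks are consecutive integers with ties broken by input
  order, and every tie group is recorded and logged. Published tables
  print ranks computed from unrounded values; when re-ranking a table
  printed at two decimals, entries tied *by printing* can legitimately
  come out in either order, which is why the consistency tests compare
  rank sets inside printed-value tie groups.
* **"Adjusted mean"** is implemented as the genotype marginal mean of
  cell means; for a balanced design this equals the least-squares mean.

## GGE biplots

The GGE fit centers each environment column of the cell-mean matrix
(`centered = means - colmean`, i.e. genotype main effect plus
interaction, G + GE) and takes its SVD. Defaults are locked to the
common figure conventions: data untransformed and unscaled, environment
centering, and the **column-metric preserving** partition (`svp = 2`),
which assigns singular values to environment coordinates; `svp = 1`
assigns them to genotypes. The rank-2 coordinate product — and hence
every result defined through inner products — is identical either way,
and the four analyses are invariant under rotation of the 2-D solution
(tested). The percent of G + GE explained is
$100(\lambda_1^2+\lambda_2^2)/\sum\lambda_n^2$.

* **Which-won-where.** Convex hull of the genotype points; boundary
  rays perpendicular to hull edges; each environment is won by the hull
  vertex maximizing the dot product with its vector — on exactly rank-2
  data this provably equals the argmax of the environment's centered
  column, which is the independent oracle in the tests. An environment
  exactly on a boundary goes to the counter-clockwise sector. Collinear
  or numerically rank-1 geometry (e.g. purely additive data, where one
  genotype wins everywhere) raises a geometry error rather than
  fabricating sectors; the pipeline skips the view and flags it.
* **Mean vs stability.** The average environment coordinate (AEC) axis
  is the unit vector toward the mean environment point. A genotype's
  projection on it proxies mean performance; the perpendicular
  component is instability. Projection² + deviation² equals the squared
  distance from the origin (tested).
* **Discriminativeness vs representativeness.** Vector length and
  cosine to the AEC. The type-1/2/3 classification is this package's
  operationalization of qualitative descriptions in the biplot
  literature: type-2 (long vector, angle ≤ 45° to the AEC), type-3
  (long vector, wider angle), type-1 otherwise. Both thresholds
  (median length, 45°) are configurable and recorded in the output.
* **Ideal genotype.** The ideal point sits on the AEC axis at the
  maximal observed projection; genotypes are ranked by Euclidean
  distance to it.

## The synthetic trial generator

`generate_met()` simulates the AMMI model generatively:
$Y_{ijk} = \mu + G_i + E_j + \sum_n \lambda_n \alpha_{in}\gamma_{jn} +
b_{jk} + \varepsilon_{ijk}$ with replicate-within-environment block
effects $b_{jk}$ and i.i.d. Gaussian noise. Two construction details
matter:

* **Planted interaction validity.** The score vectors are drawn
  standard-normal, centered, and orthonormalized, so the planted
  multiplicative term has exactly zero row and column sums — otherwise
  planted $\lambda$ would leak into the main effects and "truth
  recovery" would be ill-defined. The exact planted components are
  returned alongside the data so tests assert recovery directly
  (noiseless recovery to machine precision is tested).
* **Exact-magnitude main effects.** The drawn, centered main-effect
  vectors are rescaled so their sum of squares is exactly
  $(n-1)\,sd^2$. With as few as three environments, i.i.d. effects
  would make the realized environment variance — and hence every SS
  share — wildly variable from seed to seed (about a 20-point standard
  deviation in the environment share, and a Monte Carlo mean pulled
  ~10 points below the design value by the skew); fixing the planted
  magnitude makes the generator's variance components deterministic
  while the replicate and residual strata stay stochastic.

`groundnut_trial_config()` encodes the emulated study conditions:
30 genotypes (named after released Indian groundnut cultivars reported
drought-tolerant) × 3 rainy seasons × 2 replicates, seasonal cumulative
rainfall 504.1, 228.0 and 538.2 mm. Its effect scales were derived
analytically from expected mean squares so the expected SS shares match
a rainfed groundnut pod-yield trial dominated by season effects:
solving $E[SS]$ equations for target shares of roughly 82%
(environment), 4% (genotype), 13% (GEI, split ~85/15 over two planted
axes) and 1% (residual) gives `noise_sd = 21.5`, `rep_sd = 1.9`,
`genotype_sd = 28.8`, `environment_sd = 158.3`,
`gei_singular_values = c(434.5, 182.5)` and `mu = 188` g/m².
A 200-dataset Monte Carlo run by the acceptance script confirms the
mean environment share lands within a fraction of a point of the
design value.

What the generator does *not* emulate: non-normal plot errors, spatial
field trend, genetic relatedness among cultivars, or unbalancedness.
Passing tests therefore demonstrate algorithmic correctness under the
stated model, not robustness to messy field data.

## Derived RUE trait

RUE divides each yield observation by its environment's cumulative
seeding-to-harvest rainfall (mm), optionally times a positive `scale`
(default 1, i.e. the definition exactly as usually printed). As a
positive per-environment rescaling it preserves genotype rank order
within every environment. Published RUE summary tables are sometimes on
an undocumented working scale; the `scale` argument accommodates this,
and no package guarantee depends on absolute RUE magnitudes.

## Numerical choices and degenerate inputs

* SVD axis signs are fixed by orienting each axis so the
  largest-magnitude genotype entry is positive — output is identical
  across linear-algebra backends and repeated runs.
* Zero interaction gives a zero spectrum; $\theta$ is then defined as
  all zeros, MASI is 0 for every genotype, and the axis-share operation
  returns a flagged `NA` rather than 0/0.
* Unbalanced data are rejected with the list of missing or duplicated
  (genotype, environment, replicate) triples, never imputed: all the
  df bookkeeping above presumes completeness.
* Values are carried at full double precision end to end; CSV output
  uses shortest round-trip notation, so write/load cycles are exact.
  Rounding (two decimals for percentages and indices) happens only in
  printed reports and logs, never before ranking.

## Problem sizes used in the test suite

Unit and property tests run on small designs ($g, e, r \le 5$, at least
100 random datasets against the loop oracle), 60–200 simulated
30 × 3 × 2 trials for the Monte Carlo calibration and planted-axis
recovery checks, and 100 random rank-2 matrices for the
which-won-where oracle; the whole suite completes in well under a
minute on one core. These sizes give the Monte Carlo assertions
comfortable margins (e.g. planted-axis dominance observed in 200/200
datasets against a ≥95% requirement).

## Known limitations

* Only balanced RCBD-across-environments layouts; no lattice or alpha
  designs, covariates, or spatial models.
* No alternative stability statistics (ASV, ecovalence, Shukla
  variance) and no AMMI axis-selection procedures beyond Gollob tests.
* GGE analyses are reported as tables (with a thin plotting layer);
  publication-grade biplot styling is out of scope.
* The type-1/2/3 environment classification thresholds are a pragmatic
  operationalization, not a community standard; treat borderline
  classifications accordingly.
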