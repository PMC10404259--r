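# metstab

Genotype-by-environment stability analysis for balanced
multi-environment trials (METs): the AMMI model, GEI signal/noise
partitioning, MASI/SSI stability selection, rain-water-use efficiency,
and the four standard GGE biplot analyses — all as reproducible tables,
with a synthetic trial generator for ground-truth testing.

## Who it is for

Plant breeders and biometricians analysing yield (or any plot-level
trait) from a set of genotypes grown across several environments in a
randomised complete block design, who want the classical
stability-analysis chain as scriptable, tested R functions rather than
GUI biplot software.

## The models

**AMMI.** For genotype *i*, environment *j*, replicate *k*:

    Y_ijk = mu + G_i + E_j + sum_n lambda_n * alpha_in * gamma_jn + d_ij + e_ijk

Main effects come from the balanced ANOVA (Environment tested against
Rep(Environment); everything else against the residual mean square);
the interaction is the SVD of the doubly-centered cell-mean matrix,
with Gollob df `g + e - 1 - 2n` per IPCA axis. The interaction SS is
further split into noise (`df_GEI * MS_resid`) and signal.

**Stability.** `MASI_i = sqrt(sum_n PC_in^2 * theta_n^2)` (smaller =
more stable, `theta_n` = share of interaction SS on axis *n*), and the
simultaneous selection index `SSI = rank(MASI) + rank(mean)` (smallest
= jointly stable and high-performing).

**GGE.** SVD of the environment-centered cell-mean matrix (G + GE),
column-metric-preserving partition by default: which-won-where convex
hull sectors, mean vs stability along the average-environment axis,
environment discriminativeness/representativeness, and ideal-genotype
ranking.

See `vignettes/met-stability-methods.Rmd` for conventions, thresholds
and the generator's calibration.

## Worked example

```r
library(metstab)

cfg <- groundnut_trial_config(seed = 42)   # 30 cultivars x 3 seasons x 2 reps
sim <- generate_met(cfg)                   # data + planted truth
fit <- fit_ammi(sim$data)
fit
#> AMMI fit: 30 genotypes x 3 environments (r = 2)
#>   grand mean: 187.531
#>   singular values: 406.93, 219.15
#>   interaction shares (theta): 77.52%, 22.48%
#>
#>             source df      ss        ms         f         p sig   pct_ss
#> 1      Environment  2 3121935 1560967.4 4620.1653 5.847e-06 *** 83.39041
#> 2 Rep(Environment)  3    1014     337.9    0.8473 4.718e-01      0.02707
#> 3         Genotype 29  158875    5478.4   13.7383 1.090e-21 ***  4.24372
#> 4              GEI 58  427241    7366.2   18.4723 8.639e-31 *** 11.41210
#> 5              PC1 30  331190   11039.7   27.6841 7.088e-33 *** 77.51816
#> 6              PC2 28   96052    3430.4    8.6025 3.767e-15 *** 22.48184
#> 7        Residuals 87   34693     398.8        NA        NA      0.92669
```

The season main effect dominates (83% of SS — the signature of rainfed
trials with very different seasons), the interaction is significant and
PC1-dominated, and the residual is small. Is the interaction worth
interpreting?

```r
an <- fit$anova
partition_signal_noise(an$ss[an$source == "GEI"], an$df[an$source == "GEI"],
                       an$ms[an$source == "Residuals"])
#>   ss_signal ss_noise pct_signal pct_noise
#> 1   404113.   23129.       94.6      5.41
```

95% signal — yes. Who is stable *and* high-yielding?

```r
stab <- ssi_table(fit, sim$data)
head(stab[order(stab$ssi), ], 3)
#>   genotype       masi r_masi     mean r_mean ssi selected
#>       GG 2 0.06198397      1 236.2110      1   2     TRUE
#>     DRG 17 0.34090072      2 231.7165      2   4    FALSE
#>     R 8808 1.10265126      8 229.8340      3  11    FALSE
```

In this simulated season triplet, GG 2 is both the most stable (lowest
MASI, rank 1) and the highest yielding, so its SSI of 2 is the
theoretical minimum. Which genotype won which season?

```r
g <- gge_fit(fit$means)   # environment-centered SVD, svp = 2
g
#> GGE fit: 30 genotypes x 3 environments
#>   SVP: column-metric preserving (2)
#>   2-D view explains 84.57% of G+GE
which_won_where(g)$winners
#>   environment winner
#> 1 2017        SPANISH IMPROVED
#> 2 2018        KADIRI 5
#> 3 2019        KADIRI 5
```

The whole chain — including a derived RUE trait when rainfall metadata
is supplied — runs as one call writing every table as CSV plus a run
log:

```r
run_pipeline("met.csv", "results/", trait = "pod_yield",
             env_meta = "rainfall.csv")
```

or from a shell via `inst/scripts/metstab.R`
(`simulate` / `ammi` / `stability` / `gge` / `report` subcommands).

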