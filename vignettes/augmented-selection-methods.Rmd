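---
title: "Methods: augmented-block adjustment, genetic parameters and rank-sum selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmented-block adjustment, genetic parameters and rank-sum selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augselect)
```

## The problem

Early-generation fruit-breeding trials evaluate hundreds to thousands of new
genotypes, each available as a single plant or plot. Full replication is
impossible at that scale, so the field's standard answer is Federer's
augmented block design: a small set of replicated *check* cultivars appears
in every block, while each *test* genotype appears exactly once. The checks
do double duty — they estimate the experimental error and the block effects
that the unreplicated test values must be corrected for.

`augselect` implements the complete analysis chain for such trials: trait
derivation from fruit-level measurements, block adjustment and ANOVA,
genetic-parameter estimation, multi-trait rank-sum selection, and
multivariate characterization of the selected genotypes, plus a synthetic
trial generator with known genetic architecture used to validate the whole
chain by parameter recovery.

## Model and estimators

The plot model is additive:

$$Y_{ij} = \mu + \tau_i + B_j + \varepsilon_{ij},$$

with treatment effects $\tau_i$ split between checks and test genotypes,
fixed block effects $B_j$ and i.i.d. errors. Because the checks form a
complete randomized-block layout inside the trial,

* the error variance $\hat\sigma^2_e$ is the residual mean square of the
  two-way (checks x blocks) ANOVA on check plots, with $(b-1)(c-1)$ degrees
  of freedom;
* the block effect $\hat B_j$ is the mean of the checks in block $j$ minus
  the grand mean of all check plots (the classical Federer estimator; these
  sum to zero by construction);
* the adjusted value of a test genotype grown in block $j$ is
  $Y_{gj} - \hat B_j$.

We deliberately use the fixed-effect estimator rather than a mixed-model
BLUP: it matches the additive variance decomposition the genetic-parameter
panel is built on, and on instances small enough to check exhaustively the
adjusted genotype contrasts and the error mean square coincide with a direct
least-squares fit of the model (the test suite verifies this to 1e-8 against
`lm()`).

A missing check plot aborts that trait's analysis rather than being imputed:
the error estimate is only valid for the complete check layout. Missing test
plots are excluded from the affected trait only (pairwise deletion, logged).

### Genetic parameters

Per trait, from the adjusted test values:

* phenotypic variance $\hat\sigma^2_p$ = sample variance ($n-1$) of the
  adjusted values — the test genotypes are treated as a sample from the
  population of crosses;
* genotypic variance $\hat\sigma^2_g = \max(\hat\sigma^2_p -
  \hat\sigma^2_e, 0)$, truncated at zero with a logged warning because a
  variance is a non-negative parameter;
* broad-sense heritability $h^2 = V_g / V_f$, stored as a proportion and
  rendered as a percentage in reports;
* coefficients of variation $CV_g = 100\sqrt{\sigma^2_g}/\bar{X}$,
  $CV_e = 100\sqrt{\sigma^2_e}/\bar{X}$ and their mean-free ratio
  $\sqrt{\sigma^2_g/\sigma^2_e}$; a ratio above 1 signals genetic variation
  exceeding environmental noise;
* expected gain from truncation selection $GG = (X_s - X_o)\,h^2$ and
  $GS\% = 100\,GG/X_o$, with $X_s$ the selected-set mean.

**The reference mean $X_o$.** Two conventions circulate: the mean of the
candidate (test) population, and the mean of the checks. The gain formula
operates on the candidate population, so the package defaults to the
adjusted test mean and exposes `xo_reference = "checks"` as a switch. The
report layout also carries the error CV against three means (checks, tests,
combined), since all three are found in published tables of this kind.

The Federer replication-weighted mean ($\mu_F$) is reported alongside the
grand mean: entry means weighted by replication ($b$ plots per check, one
per test). It reduces to the grand mean when everything is equally
replicated, and is never used downstream.

### Trait derivation

Plot-level production and post-harvest traits derive from fruit-level
records: total fruit mass and count (TFM, TFN), their means (AFM), the
marketable counterparts (CFM, CFN, ACFM) restricted to fruits whose diameter
exceeds 35 mm *strictly* (the threshold is a configuration knob), firmness
as the mean of all supplied penetrometer readings, and CIELab color traits.
Hue angle uses the two-argument arctangent mapped to $[0, 360)$ — the
single-argument $\tan^{-1}(b/a)$ form is ambiguous outside the first
quadrant, though ripe-strawberry chromaticity ($a>0$, $b>0$) makes the two
agree on realistic data. Chroma is $\sqrt{a^2+b^2}$. Hue and chroma are
computed per fruit from that fruit's mean $(a, b)$ and then averaged, not
computed from averaged coordinates.

### Rank-sum selection

Genotypes are ranked per trait in the breeder's direction of improvement
(rank 1 = best; average ranks for ties by default, `min` and `first`
available) and the per-trait ranks are combined into the Mulamba–Mock index

$$I_i = \sum_j p_j\, r_{ij},$$

lower is better. The default economic weights are $p_j = CV_{g,j}$ (in
percent): traits with more exploitable genetic variation weigh more. Ranking
makes the index invariant to any strictly increasing transform of a trait
and to common positive rescaling of the weights; both invariances are
property-tested. Missing trait values rank worst rather than being imputed.

Truncation keeps the `round(n * intensity)` best genotypes with *half-up*
rounding (870 genotypes at 5% intensity select 44; 1500 at 3% select 45);
ties at the cutoff break deterministically by genotype id and are logged.
Directions for lightness and hue carry no universal convention — whether
lighter or redder fruit is "better" is a breeding decision — so the default
trait registry ships them with `NA` direction and ranking refuses to proceed
until the breeder sets one.

The pipeline screens traits before ranking: a trait whose adjusted-genotype
F-test (against the check-derived error, $\alpha = 0.01$ by default) is not
significant carries no usable genetic signal and is dropped from the index
and the multivariate stages, with a log entry; `keep_nonsignificant = TRUE`
overrides this.

### Multivariate characterization

All multivariate steps operate on column Z-scores (sample SD, $n-1$) of the
selected genotypes' adjusted values; standardization absorbs per-trait
affine scale, which is property-tested. The clustered heatmap uses
Euclidean distance and UPGMA (average linkage, via `hclust`) on both axes —
genotypes on the rows, traits on the transposed matrix. The dendrogram cut
defaults to two clusters. PCA is the eigen-decomposition of the Z-score
matrix (equivalently, of the trait correlation matrix); per-trait
contributions to a component are 100 x squared loading, summing to 100.
Because eigenvector signs are arbitrary, each loading vector is flipped so
its largest-magnitude element is positive, making outputs reproducible
across runs and platforms. The trait network reports *all* pairwise Pearson
correlations; the display threshold (default $|r| \ge 0.3$) only
de-emphasizes weak edges visually and never removes data.

## The synthetic trial generator

The generator draws data from exactly the model the analysis assumes:
$Y = \mu_t + g_{it} + B_{jt} + e_{ijt}$ with genotypic effects multivariate
normal across traits (configured variances and genetic correlation matrix,
positive semi-definiteness enforced), fixed block effects drawn normal and
centered to sum to zero per trait (the identifiability constraint of the
fixed-effect model), and residuals independent across traits unless a
residual correlation matrix is supplied. Checks receive one fixed genotypic
draw each and are replicated in every block; tests are assigned round-robin.
Everything is reproducible from one master seed, with per-replicate
sub-streams derived deterministically.

`table1_preset()` pins the generator to published trial scale: 5 blocks, 13
checks, 870 test genotypes in five cross-derived populations
(194/171/163/152/190), and nine traits whose means and variance components
have the magnitudes reported for strawberry production and post-harvest
traits. The genetic correlation structure is a mildly positive production
block (TFM/CFM/CFN, $r = 0.7$) and a negative hue–yield tie
($r_{\text{Hue,TFM}} = -0.4$), qualitatively mimicking the correlation
pattern of such trials; block-effect SDs default to
$0.3\sqrt{\sigma^2_e}$, a modest between-block heterogeneity. All
directions are set to +1, an explicit choice for lightness and hue. What
the generator does *not* emulate: non-normal trait distributions, skewness
of count traits, residual correlation between traits measured on the same
fruit, spatial trend within blocks, and genotype-by-environment structure —
so passing recovery tests validate the estimators under the model's own
assumptions, not robustness to their violation.

## What the validation experiments show

`recovery_experiment()` re-runs the full chain (simulate, adjust, estimate,
weight, rank, select) per replicate and summarizes bias and RMSE for the
heritability and variance estimates, plus the *realized* response to
selection — the mean true genotypic value of the selected set — against the
expected gain $GG$. Two subtleties matter when interpreting it:

* **Adjustment noise inflates $\hat h^2$ slightly.** An adjusted test value
  carries the block-estimation error of variance
  $\sigma^2_e (1 - 1/b)/c$, which the sample phenotypic variance attributes
  to genotypes. At the preset's scale that is about 6% of $\sigma^2_e$,
  biasing $\hat h^2$ upward by well under the 0.05 recovery tolerance; the
  same term makes the expected gain over-predict the realized response by
  the factor $(\sigma^2_g + \sigma^2_e(1-1/b)/c)/\sigma^2_g$. The
  acceptance suite verifies the breeder's equation *after* this derived
  correction, under genetically independent traits, where the identity
  $E[\text{realized}] = h^2 (X_s - X_o)$ is exact for any selection rule.
* **Correlated response.** With genetically correlated traits, index
  selection produces gains the per-trait formula cannot see: selection
  pressure on a correlated trait moves this trait's genotypic values too.
  Under the preset's $r = 0.7$ production block the realized response on
  those traits exceeds the per-trait expectation — the formula is
  conservative there. The recovery summary reports both quantities so the
  gap is visible rather than hidden.

## Numerical choices and degenerate inputs

* Variance truncation at zero (and hence $h^2 = 0$) warns and is flagged in
  the panel.
* $\sigma^2_e = 0$ makes the CV ratio undefined (`NA` with a warning), not
  infinite.
* Zero error degrees of freedom disables F-tests with a warning instead of
  failing.
* A constant trait refuses standardization (named error) and yields `NA`
  correlations (warning) rather than silent zeros.
* Single-genotype heatmaps degrade to a tree-less layout; rank-deficient
  PCA reports zero-variance trailing components; explained percentages
  always sum to 100 over returned components.
* Problem sizes in the validation suites: oracle equivalence uses
  instances up to 4 blocks x 3 checks x 6 tests (least squares), 6
  genotypes x 3 traits (exhaustive rank sums) and 6 leaves (brute-force
  average linkage); Monte-Carlo recovery uses 200 replicates at the full
  preset scale (5 x 13 + 870), which the estimators' standard errors make
  ample for the +/- 0.05 heritability check.

## Known limitations

* The fixed-effect Federer adjustment is less efficient than REML/BLUP when
  block effects are truly random and numerous; the package intentionally
  stays with the classical estimator (no mixed models, by design).
* Gains are broad-sense: no narrow-sense heritability, no pedigree or
  marker information, no multi-environment analysis.
* The F-test screening step inherits the low power of small check layouts;
  with few checks and blocks the error degrees of freedom, $(b-1)(c-1)$,
  are the binding constraint and genuinely variable traits can fail the
  screen.
* Selection counts use half-up rounding; other conventions differ at
  half-integer boundaries (e.g. 43.5).
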