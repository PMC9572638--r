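---
title: "Models and methods behind metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

`metstab` implements the statistical chain used to screen perennial forage
genotypes in staged-harvest trials under water stress. This vignette
explains each model, its assumptions, the parameters that matter, and the
design choices made where the methodology literature leaves the choice
open. No empirical claim is made here beyond what the package's tests and
acceptance script themselves compute.

## The trial model

Observations are long-format records `(genotype, regime, harvest,
replicate, trait, value)`. Three regimes are recognized: rainfed `wet`,
moderate (`MWS`) and severe (`SWS`) dry-season water stress. The factorial
analysis fits the balanced fixed-effects model

$$Y = \mu + G_i + T_j + H_k + (GT)_{ij} + (GH)_{ik} + (TH)_{jk} +
(GTH)_{ijk} + \varepsilon,$$

with genotype $G$, stress treatment $T$ and harvest round $H$.
Assumptions: a complete balanced layout (equal cell counts — the package
refuses unbalanced data rather than silently switching sum-of-squares
types), independent homoscedastic Gaussian errors (screened with
Bartlett's test), and fixed factor effects. Every term is tested against
the residual mean square. Wet-season data carry no treatment contrast, so
single-regime fits drop $T$ and its interactions. On constant input the
decomposition is reported as exactly zero with undefined F statistics
(`NA`), rather than the floating-point residue a naive fit produces.

Mean separation uses the least significant difference
$\mathrm{LSD} = t_{1-\alpha/2,\ \mathrm{df}_e}\sqrt{2\,MS_e/n}$ with
$\alpha = 0.05$ by default, the significance convention of this
literature. Letters are assigned by maximal runs on the descending-sorted
means, so two groups share a letter exactly when their difference is at
most the LSD (a property the tests verify against an all-pairs oracle).

## Genetic variation

Variance components come from expected mean squares on one regime's data:
an additive genotype + harvest ANOVA gives $\hat\sigma^2_e = MS_e$ and
$\hat\sigma^2_g = (MS_G - MS_e)/r$, where $r$ is the number of
observations behind each genotype mean. Negative moment estimates are
truncated at zero and flagged. From these,

$$\mathrm{GCV} = 100\,\frac{\sqrt{\sigma^2_g}}{\bar X},\qquad
\mathrm{PCV} = 100\,\frac{\sqrt{\sigma^2_g + \sigma^2_e}}{\bar X},\qquad
H^2 = 100\,\frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e}.$$

Two choices deserve note. First, the phenotypic variance is the
*plot-basis* sum $\sigma^2_g + \sigma^2_e$; no genotype-by-harvest
interaction component is added, because the coefficient formulas above
contain none. Mean-basis heritability (dividing the error by $r$) would be
systematically higher; plot basis is the conservative reading and is what
the package implements. Second, genotype-by-harvest interaction is pooled
into the residual of the additive fit, consistent with that plot-basis
definition — under a purely additive simulation the estimator is unbiased,
which the recovery tests confirm (mean $\hat\sigma^2_g$ within 10% of the
planted 4 over 200 replicates of a 100-genotype, 4-observation design).
Both GCV and PCV are scale invariant, and $H^2$ is bounded by 100; these
are asserted as properties.

## Drought indices and tolerance classification

Water-use efficiency is the pure ratio dry weight / irrigation volume; the
irrigation volume per plant is a configuration input (its units determine
WUE's units, and the package deliberately does not guess them). The stress
tolerance index is

$$\mathrm{STI} = \frac{Y_p \, Y_s}{\bar X_p^2},$$

where $Y_p$ is the genotype's wet-season mean yield, $Y_s$ its mean yield
under the stress regime, and $\bar X_p$ the wet-season grand mean. High
STI requires high yield under *both* conditions; the index is invariant to
rescaling all yields by a common factor.

Tolerance groups come from average-linkage agglomerative clustering under
Manhattan distance on {STI, WUE, stress TDW}, cut at $k = 3$. The three
features live on incommensurate scales (STI is dimensionless and small,
TDW can be tens of t/ha), so they are z-scored before the distance is
computed; unstandardized city-block distance would be dominated by the
largest-scale feature. Group labels (`highly_tolerant`,
`moderately_tolerant`, `susceptible`) are attached by descending
group-mean STI. The clustering path is verified against an explicit
$O(n^3)$ reference implementation (identical merge heights and cophenetic
distances); with continuous features, distance ties have probability zero,
so the tree is deterministic. A fully degenerate input (all genotypes
identical) is classified with a warning rather than an error.

## AMMI, ASV and YSI

The stability analysis treats harvest rounds within a regime as the
environments. The genotype-by-environment cell mean matrix is decomposed
as

$$Y_{ij} = \mu + g_i + e_j + \sum_k \lambda_k \alpha_{ik} \gamma_{jk} +
r_{ij},$$

where $g$ and $e$ are row/column deviations from the grand mean (summing
to zero by construction) and the multiplicative part is the SVD of the
doubly-centered residual: $\lambda_k$ the singular values,
$\alpha$/$\gamma$ orthonormal genotype and environment scores. Missing
cells are a hard error — the method is defined for complete tables, and
no EM imputation is attempted. The interaction sum of squares satisfies
$SS_{GEI} = r\sum_k \lambda_k^2$ (Frobenius identity), IPC axes carry
Gollob degrees of freedom $n + m - 1 - 2k$, and full-rank reconstruction
returns the cells exactly; all three facts are tested, as is recovery of
a planted rank-1 interaction up to the inherent joint sign flip of an SVD
axis.

The AMMI stability value is

$$\mathrm{ASV} = \sqrt{\left(\frac{SS_{IPC1}}{SS_{IPC2}}\,
\mathrm{IPC1}\right)^2 + \mathrm{IPC2}^2},$$

computed on symmetric-scaled genotype scores
$\alpha_{ik}\sqrt{\lambda_k}$. Two conventions vary across the applied
literature: the axis-weight ratio (sums of squares vs. mean squares) and
the score scaling. The package defaults to the SS ratio with symmetric
scaling — the most common published form — and exposes the mean-square
variant via `asv(weight = "ms")`. A degenerate second axis
($SS_{IPC2} = 0$) is an error rather than an infinite weight. The yield
stability index is $\mathrm{YSI} = \mathrm{rank}(\mathrm{ASV}) +
\mathrm{rank}(\text{yield})$ with yield ranked descending (rank 1 = top
yielder) and ASV ascending (rank 1 = most stable), ties averaged; low YSI
is desirable, and its minimum of 2 is attained by a genotype that is both
top yielder and most stable.

## Annual accumulation

Annual TDW sums the per-harvest genotype means over the wet-season and
dry-season harvests; annual CPY multiplies accumulated CP by annual TDW.
Published tables of this kind are ambiguous about the CPY unit (t/ha
headers over kg/ha-scale numbers), so both the per-hectare scale factor
and the CPY output multiplier are explicit configuration rather than
hidden conversions. The packaged 84-genotype table stores every cell
exactly as printed, with the Fisher-LSD letter suffixes split off by the
parser; the table's footnote markers are mapped `*` → top CPY under MWS,
`**` → top CPY under both regimes (the printed footnote is garbled on this
point, and this is the only reading consistent with two distinct marks).

## The synthetic trial generator

`generate_met()` draws
$Y = \mu + g_i + h_k + \sum_r \lambda_r \alpha_{ir}\gamma_{kr} +
\varepsilon$ with $g \sim N(0, \sigma^2_g)$, harvest effects with spread
`env_effect_sd`, and $\varepsilon \sim N(0, \sigma^2_e)$. Three
implementation details make it a usable ground truth rather than just a
noise source:

- effects are *exactly* centered after sampling (the downstream models
  assume sum-to-zero, which sampling alone gives only in expectation);
- the interaction is built from Gaussian draws that are column-centered
  and then QR-orthonormalized, so the planted matrix is exactly doubly
  centered with exactly `interaction_rank` nonzero singular values, and
  the planted scores are the SVD's scores up to sign;
- each call uses its own seeded stream and restores the caller's RNG
  state.

Default conditions mirror a realistic staged-harvest screening trial: 84
genotypes, 6 harvests, 2 replicates, grand mean 10 t/ha per harvest with
residual variance 1 — roughly the scale of wet-season Napier grass
biomass data.

`generate_paired_stress_trial()` emulates paired wet/stress screening:
stress-season expectations are the wet expectation times a regime
multiplier (defaults MWS 0.45, SWS 0.30, matching the roughly 55–70% dry
season biomass decline such trials report), and a planted 20% of
genotypes escape 90% of the penalty (`tolerance_attenuation = 0.9`). Its
default spec uses genotypic variance 1 (t/ha)² rather than 4: the
scenario is built so that *tolerance*, not constitutive yield potential,
is the dominant signal — with a very large genotypic variance, STI
legitimately ranks genotypes by yield potential instead, which is a
property of the index, not a failure of the screen. These defaults were
fixed at design time as the package's definition of the screening
scenario. `generate_feed_quality()` draws per-genotype trait vectors from
a multivariate normal whose correlation matrix encodes the negative
fiber-protein association (defaults: CP with NDF −0.6, ADF −0.55, ADL
−0.4; means and spreads at typical wet-season Napier grass values);
positive semi-definiteness of the implied matrix is validated, and the
matrix square root is taken by eigendecomposition so exactly singular
targets remain usable.

What the generator does **not** emulate: spatial field trend (real trials
of this design are spatially pre-corrected before analysis), unbalanced
or partially replicated layouts, non-Gaussian or heteroscedastic errors,
temporal autocorrelation between harvest rounds, and genotype-by-treatment
interaction beyond the tolerant/susceptible dichotomy. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to those real-data features.

## Numerical conventions

- Balanced-design checks and duplicate-key checks fail loudly with the
  offending cells named; there is no silent repair.
- Letter-run assignment uses a `1e-12` slack on the LSD comparison so
  exactly-equal means compare as equal under floating point.
- Exact-zero decompositions (constant data) are reported as zero, with
  undefined statistics as `NA`; heritability on zero phenotypic variance
  is `NA`, not 0 or 100.
- Singular values below `1e-10` are treated as zero in rank assertions;
  SS identities are tested at `1e-8` relative tolerance.
- Sub-seeds for multi-replicate simulations are derived additively from
  the user seed and stay below $2^{31}$.

## Problem sizes used in the test and acceptance suites

The suites size their simulations to be decisive yet quick: 200
replicates of the 100-genotype variance-component recovery, 100
replicates of the 84-genotype STI screen, 50 random datasets (n ≤ 25)
for the clustering oracle, 1000 null replicates for the Bartlett type-I
rate, and 10×6 tables for the AMMI identities. The full test suite runs
in well under a minute on one CPU.

## Known limitations

- Only balanced data are analysed; partially replicated designs must be
  averaged or completed upstream.
- All ANOVA factors are fixed effects; no REML/mixed-model machinery.
- The per-genotype results of the study whose data table this package
  ships (its ANOVA tables, heritabilities, cluster memberships and ASV
  ranks) depend on raw plot data that was never deposited and are not
  reproducible; the packaged table supports only the annual-yield
  summaries.
- No multiple-testing correction is applied to correlation matrices or
  trait-wise ANOVAs, matching field practice in this literature.
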