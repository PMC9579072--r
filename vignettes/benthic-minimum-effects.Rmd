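---
title: "Methods: minimum-effects testing and survey simulation for benthic biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum-effects testing and survey simulation for benthic biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthme)
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, what the synthetic
survey generator does and does not emulate, the numerical choices, and
the design decisions taken where more than one defensible option
existed.

## The survey setting

The package targets a nearshore benthic monitoring design used in gray
whale feeding grounds: two station lines along the 9 m and 13 m
isobaths (52 planned stations each, ~2 km spacing), divided alongshore
into North, Middle and South zones, visited in three summer–fall
periods with 3 replicate van Veen grabs per station, plus feeding
"hotspots" sampled with 12 grabs each. The default
`design_spec()` encodes the realized per-period station counts
(Period 1: 22/32/14, Period 2: 42/41/18, Period 3: 21/21/12 across the
zones). Wet tissue biomass (g/m²) is recorded per grab for seven
characteristic macrofaunal groups plus a pooled remainder; the six
groups occurring in gray whale diets define total prey biomass.

## Minimum-effects hypothesis tests

For each ANCOVA effect the classical null (no difference, λ = 0) is
replaced by the interval null that the true effect does not exceed a
boundary effect size *f*. With percent variance
$PV = f^2/(1+f^2)$, the boundary noncentrality is approximated as

$$\lambda = DF_{err} \cdot \frac{PV}{1-PV} = DF_{err}\, f^2,$$

appropriate for large samples. The test refers the observed F to the
noncentral $F(df_1, df_2, \lambda)$ distribution:
$H_{ME}: F_{obs} \le F_{crit}$ is rejected when
$F_{obs} > F_{crit}$, the $(1-\alpha)$ quantile. Three boundaries are
used by default — small $f = 0.2$ (natural variability of benthic
communities, deliberately larger than Cohen's 0.1), medium $f = 0.5$
(change indicating transition across an ecological boundary), large
$f = 0.8$ (disturbance-scale change) — and each effect is graded by
the largest boundary rejected (`classify_effect()`). Because critical
values increase with *f*, rejections always form a prefix of the
boundary sequence and the grade is monotone in $F_{obs}$.

Three small points of care:

- **The λ formula.** A circulated form of the approximation reads
  $DF_{err} \cdot PV/(1/PV)$, i.e. $DF_{err}PV^2$. That expression is
  dimensionally implausible and inconsistent with the framework it
  cites; the package uses $DF_{err} \cdot PV/(1-PV)$ by default and
  retains the literal form behind
  `me_noncentrality(..., form = "printed")` purely for audit.
- **The PV of f = 0.5.** The analytic conversion gives
  $PV = 0.25/1.25 = 20\%$; a sometimes-quoted "≈ 23%" for the same
  boundary is inconsistent with the conversion and is not reproduced.
  Similarly $f = 0.8$ gives 39.0%, conventionally rounded to "≈ 40%".
- **Tie rule.** $F_{obs}$ exactly equal to $F_{crit}$ does *not*
  reject (the null is stated with ≤); `rejected` is equivalent to
  `p_me < alpha` because the noncentral F distribution is continuous.

`post_hoc_power()` gives the classical-power companion:
$P[F(df_1, df_2, \lambda) > F_{crit}(\lambda = 0)]$, which equals α at
λ = 0 and increases to one. Noncentral-F quantiles and tail
probabilities use R's `qf()`/`pf()` with the `ncp` argument — the
established special-function routines — and are validated in the test
suite against 10⁷-draw ratio-of-chi-squares Monte-Carlo oracles.

## Mixed-model ANCOVA

Per taxon, on detailed-grid grabs only:

$$\ln(Y_{ijkl}+1) = \mu + zone_i + period_j + (zone{\times}period)_{ij}
  + \beta_1 z + \beta_2 z^2 + b_{station} + \varepsilon$$

with $b \sim N(0, \sigma_s^2)$ and
$\varepsilon \sim N(0, \sigma^2)$. Depth is standardized to sample
mean 0 / SD 1 (n−1 convention; constants are stored in the fit for
reproducibility) and enters with a squared term to capture nonlinear
response; standardization prevents collinearity between the linear and
quadratic terms. Fitting uses REML via `lmerTest`, marginal
(Type-III-style) F tests with sum-to-zero contrasts, and Satterthwaite
denominator degrees of freedom.

Decisions worth recording:

- *Contrasts and SS type.* The design is nonorthogonal (unequal cell
  sizes), and a single p-value per effect is reported; marginal tests
  with sum-to-zero contrasts are the convention that makes main
  effects interpretable in that situation.
- *One station effect across periods.* "Replicates nested within
  station" is implemented as a station random intercept with
  replicate-level residual error; a station re-visited in a later
  period keeps the same random effect, because the physical station
  (its sediment, depth, local regime) is the persistent unit. No
  period-within-station random term is added.
- *Zeros included.* Zero-heavy taxa (the schooling fish group) are fit
  on the full data including zeros; the sample size is large enough
  for the F approximation, and this matches how such surveys are
  analysed in practice. The null-calibration simulations in the test
  suite check the resulting p-values only under the hurdle-free model.
- *Convergence.* If the optimizer reports non-convergence the fit is
  restarted from a grid of variance-ratio starting values
  (θ ∈ {10⁻⁴, 10⁻², 1, 10, 100}) and fails loudly after that.
  Singular fits (station variance estimated at zero) are accepted:
  with a true zero component the REML estimate lands on the boundary
  and the mixed fit then coincides with the fixed-effects ANCOVA, a
  property the tests assert against an OLS oracle.

`ancova_report()` assembles the table consumed by the ME layer: one
row per (taxon, effect) with F, df, p, a significance flag at α =
0.05, and the ME grade rendered as asterisks (one per boundary
exceeded).

## Community analysis

`build_community_matrix()` averages replicate grabs to one row per
station visit on the ln(X+1) scale. The order of operations is
ambiguous in common practice ("transform prior to the dissimilarity"
vs "average by station"); the package defaults to
**transform-then-average** — transform each replicate, then average —
because it is the order under which the ANCOVA transform and the
community matrix see the same per-grab quantities. The alternative is
available (`transform_first = FALSE`) and documented in the object.
Rare groups are dropped below a prevalence threshold (default: present
at ≥ 5% of station visits; "rare" is otherwise undefined in field
practice, so the threshold is configurable). Hotspot visits are
excluded by default: the ordination describes the detailed grid.

`bray_curtis()` computes
$d_{ij} = \sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})$ (via
`vegan::vegdist`). Although such analyses are often phrased in terms
of "similarity coefficients", the ordination and partitioning operate
on dissimilarity $d = 1 - s$; that is what the package returns. Pairs
of all-zero rows are 0/0 under the formula and are set to 0 with a
warning. Symmetry, zero diagonal and unit range are asserted on every
construction.

`nmds()` wraps `vegan::metaMDS` on the dissimilarity matrix: Kruskal
stress-1, monotone regression, `n_starts` random starts (default 20),
convergence declared by Procrustes agreement between starts;
coordinates are centered and reproducible by seed. `centroids_ci()`
returns per-group centroids with per-axis
$t_{n-1} \cdot s/\sqrt{n}$ confidence half-widths, the numeric
version of a centroid-inset plot.

`npmanova()` is authored in the package rather than delegated: the
Gower-centered inner-product partition of the squared dissimilarities
(the McArdle–Anderson construction) with *sequential* (entry-order)
sums of squares, pseudo-F against the full-model residual, and free
(unrestricted) row permutations with
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, reproducible by
seed. Implementing it directly keeps the permutation contract exact —
including an exhaustive mode (`permutations =`) under which the
p-value is the exact proportion over a supplied permutation set,
verified in the tests against a brute-force within/between-group
oracle on 6-row problems. `vegan::adonis2` serves as an independent
cross-check of the F and R² partition, never as the implementation.
Depth enters as the two-level isobath factor (9 m vs 13 m) here, even
though the ANCOVA uses continuous depth: the community model treats
habitat strata, the univariate model a gradient. Default terms are
`period, zone, sediment, depth, period:zone`, in that order; with
sequential SS the per-term attribution depends on entry order but the
total does not (asserted to 10⁻⁸).

`pairwise_permutation()` runs two-group permutational pseudo-F tests
on every pair of period×zone combinations and applies the Holm
step-down adjustment (`stats::p.adjust`), flagging pairs at the 0.05
family-wise level.

## The synthetic survey generator

No field data are distributed with surveys of this kind, so the
generator is a first-class, tested component: it produces tables with
exactly the statistical structure the analysis assumes, which is what
makes every downstream stage testable.

The generative model per group g, zone z, period p is a hurdle /
shifted lognormal:

$$Y = 0 \text{ w.p. } \pi_g, \quad \text{else } \ln(Y+1) =
  \mu_{gzp} + \beta_{1g} z_d + \beta_{2g} z_d^2 + b_{s} +
  \varepsilon,$$

with $b_s \sim N(0, \sigma_{s,g}^2)$ per station (shared across
periods and across a hotspot's 12 grabs) and
$\varepsilon \sim N(0, \sigma_{gzp}^2)$ per grab; biomass is floored
at zero. The form mirrors the analysis model (the ln(X+1) ANCOVA with
station random effects) with a zero-inflation component motivated by
the many zero catches of schooling fish; no generative model is
prescribed by field practice, so this is the simplest one consistent
with the analysis.

**Calibration.** `default_sim_params()` inverts the hurdle-lognormal
analytically so that each group's marginal mean and SD in every
zone-by-period cell (grabs pooled over both isobath lines) match the
survey's published dominance-ranking values
(`reference_biomass_summary()`). Writing $a = e^{m + s^2/2}$ and
depth-correction factors $c_1 = E[e^{\beta_1 z + \beta_2 z^2}]$,
$c_2 = E[e^{2(\beta_1 z + \beta_2 z^2)}]$ (computed by quadrature over
the truncated-normal depth mixture), the target conditional moments
give closed forms $a = (\mu_1 + 1)/c_1$ and
$e^{s^2} = (E_1[Y^2] + 2ac_1 - 1)/(a^2 c_2)$. The test suite verifies
the round trip analytically for every published cell and by
Monte-Carlo simulation at ~10,000 grabs for representative cells.

Parameter choices and their reasoning:

- *Reference moments.* The published top-five rankings cover 45
  (group, cell) pairs; combinations outside the top five get synthetic
  fill values (half the smallest reported mean in the cell, SD 1.5×
  the mean), labelled `source = "fill"`.
- *Variance split.* A single per-group residual SD cannot reproduce
  nine different per-cell SDs, and a per-cell *station* SD would
  contradict the one-station-effect-across-periods structure. The
  resolution: the station SD is a per-group scalar (25% of the group's
  smallest cell variance), and the residual SD varies by cell.
- *Depth structure.* Slopes on standardized depth encode the observed
  habitat associations — Amphipoda and Isopoda biased shallow/fine
  sand, Bivalvia (strongest), Echinoidea, Actinopterygii and
  Polychaeta biased deep/medium sand. Station depths are jittered
  N(nominal, 0.5 m) truncated to 7–15 m (vessels occasionally sampled
  7 m water); sediment is medium sand with probability 0.8 on the
  13 m line and 0.2 on the 9 m line, both configurable.
- *Zero inflation.* π = 0.30 for the fish group, 0.02–0.30 for the
  invertebrate groups. π and the depth slopes are jointly bounded by
  the reference moments: the hurdle and the across-line spread impose
  a variance floor, and cells with low CV (notably Isopoda and the
  fish peak cell) admit only moderate values. The defaults are the
  largest ecologically sensible values for which every published cell
  remains calibratable.
- *Staggered sampling.* Periods 1 and 3 could not cover the full
  grid; which stations were skipped is not recoverable, so the plan
  draws stations uniformly without replacement within each zone,
  seeded, reproducing the printed counts exactly.
- *Hotspots.* Each hotspot is one station-level random effect with 12
  grabs split across the two isobath depths; hotspot rows are
  labelled period 2 (they were sampled between the first two periods)
  and carry `design = "hotspot"` so every summary keeps them
  separate. Replicate grabs within a station are treated as
  exchangeable — nothing in the design records their relative
  positions.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: spatial autocorrelation along the lines
(stations are exchangeable within zones), the actual stagger pattern,
tidal/oceanographic forcing, within-zone gradients (e.g. proximity to
the bay mouth), taxon-level composition within groups, and
correlations between taxa beyond those induced by shared depth and
station structure. The floor at zero biomass also biases the smallest
fill cells slightly upward (the probability mass below −1 on the
ln-scale is truncated); this is negligible for the dominant-group
cells the calibration targets.

## Numerical choices and test scales

- Noncentral-F quantiles/CDF: `stats::qf`/`pf(ncp=)`; validated
  against 10⁷-draw Monte-Carlo oracles (quantile to 0.01 absolute,
  power to 1.5×10⁻³).
- Permutation comparisons use a 10⁻¹² slack on
  $F_{perm} \ge F_{obs}$ so that exhaustive-mode ties (including the
  identity permutation) are counted deterministically.
- Null calibration: 500 simulated no-effect surveys (48 stations × 3
  replicates) for the ANCOVA and 500 exchangeable-row community
  matrices for the NPMANOVA, each checked for p-uniformity by a
  Kolmogorov–Smirnov test at level 0.01. Parameter recovery uses 200
  stations × 3 replicates with a wider depth jitter (1.2 m) so the
  quadratic depth coefficient is identifiable. These problem sizes
  are the package's chosen compromise between statistical resolution
  and a test suite that runs in minutes.
- The exceedance summaries are computed over replicate-level values
  (the convention for bubble-plot style reporting); a station-mean
  mode is available. The two isobath lines are pooled.
- Confidence intervals for biomass summaries are t-intervals on the
  untransformed scale, matching how such figures are drawn; a
  log-scale interval is deliberately not the default.

## Known limitations

- The mixed ANCOVA assumes homoscedastic lognormal-ish residuals;
  heavy zero inflation (π well above ~0.3) distorts its p-values, and
  the package does not provide hurdle/GLMM alternatives.
- NPMANOVA uses free permutations; no restricted permutation schemes
  (e.g. within-period) and no dispersion-homogeneity (PERMDISP)
  companion test are provided, so significant terms can reflect
  dispersion as well as location differences.
- NMDS convergence is declared by Procrustes agreement between random
  starts; for very small matrices the procedure may report
  non-convergence while returning an adequate configuration — the
  flag is informative, not fatal.
- The simulator's exchangeability assumptions preclude its use for
  studying spatial interpolation or areal habitat extrapolation;
  geographic coordinates and mapping are out of scope.
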