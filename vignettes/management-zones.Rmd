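---
title: "Delineating soil-fertility management zones: models, choices and limits"
author: "agrizone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating soil-fertility management zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrizone)
```

## The problem

Smallholder fields are rarely homogeneous: pH, organic carbon and available
nutrients vary over tens of metres, so a single blanket fertilizer dose
over- and under-feeds different parts of the same field. Site-specific
nutrient management (SSNM) addresses this by partitioning the field into a
few *management zones* (MZs) — contiguous regions of relatively uniform
fertility — and prescribing a soil-test-based dose per zone. `agrizone`
implements the complete workflow on geo-referenced point samples: spatial
structure estimation, interpolation, dimension reduction, fuzzy zoning,
statistical validation, and targeted-yield fertilizer recommendation with
an economic summary. A synthetic-field generator with known ground truth
makes every stage testable without field data.

## Spatial structure: the semivariogram

For a property $Z$ observed at locations $x_i$, the empirical semivariance
at lag $h$ is the method-of-moments estimator

$$\hat\gamma(h) = \frac{1}{2N(h)} \sum_{i=1}^{N(h)}
  \left[ Z(x_i) - Z(x_i + h) \right]^2,$$

computed omnidirectionally over unordered pairs binned by separation
distance. Two numerical choices matter here:

* **Lag centres are mean pair distances.** On gridded samples the first
  bins are populated only near their upper edge (nothing is closer than
  the grid spacing); evaluating a model at nominal bin centres would then
  systematically inflate the fitted nugget. Empty bins keep their nominal
  centre and carry `NA`.
* **Defaults.** `lag_width` defaults to `max_distance/15` and
  `max_distance` to half the maximum inter-point distance, the usual
  active-lag convention; the pipeline passes the grid spacing as lag width.

Three isotropic models are fitted: spherical, exponential
($\gamma = c_0 + c\,(1 - e^{-3h/a})$) and Gaussian
($\gamma = c_0 + c\,(1 - e^{-3h^2/a^2})$), with nugget $c_0$, partial sill
$c$ and **effective** range $a$ — the exponential and Gaussian forms reach
95 % of their sill at $h = a$, the convention under which ranges are
tabulated in applied soil-science work. $\gamma(0)$ is defined as the
nugget: the discontinuity at the origin is carried entirely by the nugget
term.

Fitting minimizes $\sum_h N(h)\,(\hat\gamma_h - \gamma(h;\theta))^2$
(weights switchable to uniform) under bound constraints, from five
deterministic starting points. Because sills and ranges live on wildly
different scales, the optimizer works on parameter-scaled coordinates;
without that, finite-difference gradients stall near the start. When a
pure-nugget model attains the same weighted error as the best structured
fit (a flat empirical variogram puts nugget, partial sill and range on an
equivalent-fit ridge), the pure-nugget solution is preferred.

The nugget-to-sill ratio classifies spatial dependence in the Cambardella
scheme: `< 0.25` strong, `0.25–0.75` moderate (bounds inclusive — the
source literature uses inclusive prose ranges), `> 0.75` weak.

## Kriging and its cross-validation

Ordinary kriging solves, per target, the semivariance system augmented by
the unbiasedness constraint ($\sum_i \lambda_i = 1$) and a Lagrange
multiplier. The matrix diagonal is $\gamma(0) = 0$ plus a $10^{-10}$
jitter, making the predictor exact at sample sites. Up to 300 samples the
full system is factorized once for all targets; beyond that each target
uses its 32 nearest neighbours. Prediction surfaces default to 5 m cells
over the sample bounding box and serialize as ESRI ASCII grids.

Leave-one-out cross-validation reports

$$\mathrm{nRMSE} = \frac{100\,\mathrm{RMSE}}{\lvert\bar Z\rvert}, \qquad
  R^2 = \mathrm{cor}(Z, \hat Z)^2,$$

classed `< 20 %` good, `20–30 %` fair (inclusive), `> 30 %` poor. Two
conventions deserve a note. First, LOOCV for log-transformed properties is
computed on the log scale, matching how such fits are usually tabulated;
the absolute value in the denominator matters exactly there, because the
log-scale mean of a property with values below 1 (e.g. EC in dS/m) is
negative. Second, the model-selection rule for a property is lowest LOOCV
nRMSE across the three families, ties broken by higher $R^2$.

Log-kriged surfaces are back-transformed by plain exponentiation by
default; the lognormal correction $\exp(\hat Z + \sigma^2_K/2)$ is
available behind `lognormal_correction = TRUE`.

## PCA and component retention

The PCA basis is the **covariance** matrix of the mean-centred properties
(the correlation basis is available via `basis = "correlation"`).
Components with eigenvalue $\ge 1$ are retained. Two caveats are
deliberate and documented rather than silently "fixed":

* The eigenvalue-1 threshold on a covariance matrix is scale-dependent
  (Kaiser's rule presumes a correlation basis); with nutrient variances in
  the thousands it retains essentially every component above measurement
  noise. The threshold and basis are both configurable; the defaults
  reproduce the published choice.
* Reported loadings are property–score correlations
  ($v_{jk}\sqrt{\lambda_k}/s_j$, bounded by 1), the convention under which
  published loading tables are readable; communality is the row sum of
  squared loadings over retained components. Eigenvector signs are fixed
  (largest-magnitude loading positive) for cross-platform reproducibility.

Before clustering, retained score columns are standardized to zero mean
and unit variance by default. Covariance-basis scores differ by orders of
magnitude across components; unstandardized, the first component would
fully dominate the Euclidean metric of the clustering. Strict replication
of raw-score clustering is available with `standardize = FALSE`.

## Fuzzy C-means zoning

The zoning engine is Bezdek's alternating optimization with the
Management-Zone-Analyst parameterization: fuzziness $m = 1.5$, tolerance
$10^{-4}$ on the maximum membership change, at most 300 iterations,
Euclidean distance, cluster counts swept over 3–8. Memberships update as
$u_{ik} = 1/\sum_j (d_{ik}/d_{jk})^{2/(m-1)}$; a sample coinciding with a
centroid gets membership 1 there. Ten seeded restarts from uniform-simplex
initial memberships guard against local minima; the best objective wins,
and identical data, configuration and seed give identical results.

Cluster-count selection minimizes two validity indices,

$$\mathrm{FPI} = \frac{C}{C-1}\Bigl(1 - \frac{1}{n}\sum_{i,k} u_{ik}^2\Bigr),
\qquad
\mathrm{NCE} = \frac{n}{n-C}\Bigl(-\frac{1}{n}\sum_{i,k}
   u_{ik}\ln u_{ik}\Bigr),$$

both 0 for a crisp partition and minimized over $c$; FPI is 1 and NCE is
$\tfrac{n}{n-C}\ln C$ at uniform membership ($0\ln 0 := 0$). A printed
variant of FPI that reverses the scale (1 = crisp) circulates in the
applied literature; it is available behind `convention = "as_printed"` but
contradicts the accompanying "lower is better" selection rule, so the
standard form is the default. When the FPI and NCE minimizers disagree,
the smaller count wins (parsimony) and a warning records both minima. On
diffuse, unimodal score clouds FPI can decline monotonically over the
sweep while NCE rises; the parsimony rule then effectively follows NCE.

Crisp zones are the argmax memberships, renumbered by decreasing area so
MZ 1 is always the largest; exact ties go to the lowest original cluster
index and are counted in the output.

## Validation and recommendation

Per property, a one-way ANOVA across zones provides $F$ and $p$; compact
letter displays come from Tukey HSD at $\alpha = 0.01$ (configurable) via
insert-and-absorb, with the highest zone mean lettered `a`. A
non-significant omnibus test letters every zone `a`. The post-hoc test is
a package choice — the source workflow names none — and the ANOVA ignores
spatial autocorrelation of the samples, a known caveat of zone validation
that inflates significance; treat the letters as descriptive.

The variability ledger compares the whole-field CV of each property with
the **unweighted arithmetic mean** of per-zone CVs (the only reading under
which the published worked examples recompute), reporting
$100\,(CV_{field} - \overline{CV}_{zone})/CV_{field}$ to two decimals.

Zone doses use the PJTSAU targeted-yield calibration for maize at target
yield $T$ (quintal/ha):

$$F_N = 4.25\,T - 0.24\,SN,\quad
  F_{P_2O_5} = 0.9\,T - 0.3\,SP,\quad
  F_{K_2O} = 1.41\,T - 0.05\,SK,$$

evaluated at each zone's mean soil-test values, floored at zero with a
flag (doses are linear and decreasing in fertility, so savings against a
reference practice rise with zone fertility — and can be negative when a
zone tests below the reference assumption). Economics are the identities
gross = yield × price, net = gross − cost, B:C = gross/cost; the grain
price is always an explicit input. With the published zone yields and
costs, a price of 18.7 per kg reproduces the published gross returns to
the rupee, but no price is hard-coded.

## The synthetic generator: what it emulates, and what it does not

`telangana_maize_config()` encodes the study conditions of a 4-ha maize
field sampled at 200 points on a 14.2 m grid: eleven properties with
published means and CVs, variogram families, effective ranges and
nugget/sill fractions, log-normal marginals where the source data were
log-transformed, and a near-collinear correlation structure with Zn
anti-correlated to the fertility block (the printed correlation matrix is
positive definite and is used as-is; user matrices are repaired by
eigenvalue clipping when needed). The true field outline is unknowable, so
a rectangular 20 × 10 grid is assumed.

The construction draws, per property, a latent unit-variance Gaussian
random field with covariance $C(h) = \mathrm{sill} - \gamma(h)$
(second-order stationarity), realizing the nugget as independent
per-location noise. Cross-property dependence comes from mixing one shared
set of Gaussian innovation factors through a Cholesky factor of the target
correlation matrix *before* each property's spatial factor is applied.
Each property therefore keeps its configured variogram exactly — the
property that makes parameter-recovery tests meaningful — while observed
correlations attenuate relative to their latent targets by three
compounding factors: spatial-structure mismatch between the pair (the
spatial factor is the symmetric matrix square root precisely to keep this
factor near 1; it is ≥ 0.93 for the preset's worst pair, against ≈ 0.81
for a Cholesky factor), the nugget share of each latent field, and the
log-normal transform. A target of −0.95 between a Gaussian-structured and
an exponential-structured log-normal property realizes near −0.82. This is
a modelling fact, not a defect: two stationary fields with very different
ranges cannot be near-perfectly correlated at every site under any valid
joint model. Marginal moments use population parameters (exact log-normal
moment matching), so realized means and CVs fluctuate around their targets
as real fields do.

What the generator does **not** emulate: anisotropy (all fits are
omnidirectional), terrain or management covariates, temporal dynamics,
non-Gaussian copulas beyond the log-normal marginal, and measurement
error beyond the nugget. Passing recovery tests on these fields therefore
shows the estimators are correct under the stated model, not that real
fields satisfy the model.

## Problem sizes and numerical tolerances

Stochastic suites use fixed seeds and published-scale problems chosen to
balance statistical resolution against runtime: marginal fidelity on
1 024-point fields averaged over 5 seeds; spatial-structure and
dependence-class recovery on 1 000-point fields over 20 seeds with the
fitting window held at the 200-point study field's value (150 m, half its
maximum inter-point distance); exponential-range recovery on 2 000-point
fields, where that smoother family first becomes identifiable within
±30 % — at 14.2 m spacing a 32 m effective exponential range is close to
the identifiability limit, which is why short-range exponential
properties are the last to classify correctly. Kriging weights must sum
to 1 within $10^{-8}$; kriging variances are clipped at zero below
$-10^{-9}$; covariance factorizations carry a $10^{-10}$ diagonal jitter;
duplicate coordinates (within $10^{-9}$ m) are rejected at load because
they make the kriging system singular.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(
  simulate = telangana_maize_config(seed = 42),
  seed = 42, out_dir = "mz_run",
  grain_price = 18.7,
  zone_yields = c(7789, 7925, 8018),
  zone_costs  = c(57349, 57035, 56598))
res <- run_pipeline(cfg)
res$sweep          # FPI/NCE sweep and optimal cluster count
res$anova          # per-zone means, F, letters
res$plan           # per-zone doses and savings vs 240/80/80
```

Every artifact (descriptives, correlation matrix, Table-2-style variogram
records, kriged ASCII grids, sweep table, zone map, ANOVA, CV-reduction
ledger, fertilizer plan, economics, and a machine-readable manifest of the
decisions in effect) is written under `out_dir`, and reruns with the same
seed are byte-identical.
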