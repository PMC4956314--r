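---
title: "Linking stream discharge to lake biology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking stream discharge to lake biology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrofda)
```

## The inference problem

Meltwater streams in the McMurdo Dry Valleys flow for a few weeks per
austral summer and deliver the nutrient pulse that shapes the following
spring's plankton community in the lakes they feed. The biological signal
is a single number per season — the October–December mean of primary
production or chlorophyll-a in the oxic zone above the chemocline (top
11 m; stream water spreads directly beneath the ice, so only the upper
column sees it). The physical driver is a whole curve: daily discharge
over the December–January flow season, lagged one year because the lake
operates as a closed system until the next melt arrives.

`hydrofda` implements this inference in two stages, each a proper
statistical model rather than an ad-hoc preprocessing step.

## Stage 1: Bayesian gap filling of log-discharge

Gauge records have gaps from hours to weeks, while the regression stage
needs every season's complete curve. Discharge in these valleys is tightly
coupled to air temperature (melt is energy-limited), which suggests
borrowing strength from the complete daily temperature record.

On the daily season grid $t_0 < \dots < t_M$ (December 1 – January 31,
$M = 61$, $\Delta t = 1$ d), with $\mathrm{DR} = \log(\zeta + Q)$ and
$\zeta = 0.01$ in the discharge units of the record (so that a dry day is
finite: $\log \zeta$), the model is

$$
\mathrm{DR}^{obs}(t_l) = \mathrm{DR}(t_l) + \xi(t_l), \qquad
\xi \sim N(0, \sigma_e^2),
$$
$$
\mathrm{DR}(t) = \delta_0 + \delta_1 T(t) + u(t), \qquad
u \sim \mathrm{GMRF}(0,\ (\tau R)^{-1}),
$$

where $R$ is the first-order random-walk structure matrix (tridiagonal,
penalizing squared day-to-day differences). The sparse precision is what
makes exact conditioning cheap: the posterior precision is
$\tau R + A'A/\sigma_e^2$ with $A$ the observation selector, and one
banded Cholesky factorization per update solves it.

Choices a user may care about:

* **Random-walk order** (`gmrf.order`, default 1). First order encodes
  "tomorrow is like today", adequate for a single broad melt pulse; second
  order (available) favours smoother curves but extrapolates trends into
  long gaps, which is riskier at season edges.
* **Identifiability.** $R$ is singular along constants, so the level of
  $u$ and the intercept $\delta_0$ are confounded. The Gibbs update
  resolves this by constraining $u$ to sum to zero within each season
  (conditioning by kriging), so $\delta_0$ carries the seasonal level and
  is a well-defined estimand. The synthetic generator adopts the same
  decomposition convention.
* **Priors.** $\delta_0, \delta_1 \sim N(0, 100^2)$,
  $\sigma_e^2 \sim \mathrm{IG}(0.01, 0.01)$,
  $\tau \sim \mathrm{Ga}(0.01, 0.01)$: vague conjugate choices; with 30+
  observed days per typical season they are dominated by the data.
* **Sampler.** Gibbs with 2000 kept draws after 1000 burn-in by default.
  All four full conditionals are exact (Gaussian, Gaussian,
  inverse-gamma, gamma), so mixing is fast; a split-chain diagnostic warns
  (never errors) above 1.1.
* **Minimum data.** Seasons with fewer than `l_min = 5` observed days are
  excluded rather than imputed from the prior alone; with zero
  observations the fixed-hyperparameter conditioner returns the prior
  mean with an explicit improper flag.
* **Downstream point process.** The regression consumes the posterior
  mean curve — a single smooth curve per stream-season. Posterior draws
  are retained, so propagating imputation uncertainty through the
  regression is possible, but the headline analysis conditions on the
  mean.

## Stage 2: scalar-on-function regression

With $X_{ij}(t)$ the reconstructed log-discharge curve of season $i$,
stream $j$,

$$
Y_i = \alpha + \sum_j \int_0^T \beta_j(t) X_{ij}(t)\,dt + \epsilon_i,
\qquad
\beta_j(t) = \sum_{k=1}^K \gamma_{jk} \phi_k(t).
$$

The integrals are left-Riemann sums over the grid,
$\sum_{m=0}^{M-1} \phi_k(t_m) X_{ij}(t_m) \Delta t$ — the final node is
dropped by the sum convention, and the bases are orthonormalized under
exactly this discrete inner product (the Fourier family is exactly
orthonormal under it by discrete trigonometric identities; B-splines are
Gram–Schmidt orthonormalized). This keeps the score matrix, the Gram
identity and the reconstruction $\hat\beta_j(t)$ mutually consistent to
machine precision.

* **Basis** (`basis_family`, `K`): Fourier with $K = 5$ by default — a
  constant plus two sine/cosine pairs. The flow season is one broad
  low-frequency pulse; higher $K$ mostly fits noise at $n \approx 17$
  seasons. B-splines are available where local features matter.
* **Covariate scale** (`covariate_scale`): the log-scale curve
  $\mathrm{DR}(\cdot)$ by default — it is the scale the gap-filling model
  works on and the scale on which discharge is closest to Gaussian.
  `"linear"` back-transforms to $\exp(\mathrm{DR}) - \zeta$ for users who
  want volumetric loading.
* **Regularization.** Ridge on $\gamma$ with the intercept unpenalized.
  For a linear smoother the leave-one-out residual is
  $(y_i - \hat y_i)/(1 - H_{ii})$, so the exact LOOCV score costs one fit
  per candidate $\lambda$; ties are broken toward the larger penalty, the
  stabler choice at small $n$. $\lambda = 0$ reproduces exact least
  squares and the normal equations.
* **Per-stream models and ensembling.** With just over a decade of
  seasons, a joint three-stream fit ($3K$ coefficients) is weakly
  identified, so one single-stream model is fitted per stream; the
  per-season prediction is their arithmetic mean, the band is mean
  $\pm 2\,\mathrm{SE}$ with the ensemble SE combining per-model
  prediction variances as $\sqrt{\mathrm{mean}(se_j^2)}$, and the
  headline fit statistic is the arithmetic mean of the per-model $R^2$.
  The SE combination rule treats the three models as exchangeable
  predictors of the same quantity; the underlying per-model SE is the
  linear-smoother prediction SE under the fitted residual variance.
* **Lag bookkeeping.** A response labelled by the calendar year of its
  Oct–Dec window is paired with the discharge season labelled one year
  earlier (December of that year through January); the pairing is
  asserted on every design row.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage is testable without any field
download, under conditions mirroring the study's scale: 17 discharge
seasons, three streams, the 62-node daily grid.

Emulated: seasonal temperature curves peaking near the turn of the year
(−10…+5 °C); log-discharge linearly coupled to temperature with
autocorrelated AR(1) deviations (deliberately *not* the RW1 fitting
prior, so tests exercise mild model misspecification); zero-flow floors
at $\log \zeta$; contiguous observation gaps of a few days to three
weeks; depth profiles (0.5–18 m every 0.5 m, 3–4 dates per season) whose
above-chemocline values realize the seasonal response in expectation,
with distinct deeper values so the cutoff filter is genuinely exercised;
response noise set to a 3:1 signal-to-noise ratio unless given
explicitly.

Not emulated: hydrological process realism (no energy balance, no
rating curves), suspended sediment, within-season response dynamics,
depth gradients above the chemocline, non-Gaussian measurement error.
Passing tests therefore certify the statistical machinery — conditioning,
quadrature, selection, ensembling — under a realistic correlation
structure; they do not certify that the field data satisfy the model.

A consequence worth stating plainly: because the generator's deviations
are AR(1) while the filter assumes RW1 smoothness, credible bands inside
long gaps undercover somewhat relative to nominal (the band is calibrated
when the truth is generated from the RW1 model itself — the test suite
checks both), and the posterior-mean error inside a 10-day gap is
necessarily larger than at observed nodes by more than the factor the
smoothed observed-node error might suggest: gap error is bounded below by
the process's bridge variability, while observed-node error shrinks with
smoothing. Similarly, at 17 seasons and SNR 3:1 the $K = 5$ coefficient
space is only weakly identified — the recovered $\beta(t)$ typically
correlates with the truth above 0.9, but not in every replicate. The
acceptance checks report these quantities as measured rather than
enforcing targets the study conditions cannot meet.

## Numerical choices and degenerate inputs

* Equidistance of the grid is enforced at construction; all quadrature
  assumes it.
* Temperature gaps of at most 3 consecutive days are linearly
  interpolated (edge gaps extended); longer gaps, or more than half the
  season missing, abort with an insufficient-data error — the prior mean
  cannot be trusted without its covariate.
* Rejected rows (negative discharge, non-positive depth, negative
  concentrations) are dropped with a logged count, never fatal: decades
  of field files contain stray rows.
* A response with zero variance makes $R^2$ undefined and errors
  explicitly; a singular score cross-product at $\lambda = 0$ errors with
  advice rather than silently pseudo-inverting.
* All simulation is seeded through one global seed expanded
  deterministically into per-stage, per-stream-season substreams, so
  adding a stream leaves every other stream's draws unchanged; identical
  configuration and seed reproduce the pipeline summary bit for bit.
* Test and example problem sizes are scaled to the method, not the data:
  oracle comparisons run on grids up to 50 nodes, sampler checks use a
  few hundred to a thousand kept draws, and recovery studies use tens of
  replicates of the 17-season scenario — enough for the binomial margins
  the assertions use.

## Known limitations

* Seasons are gap-filled independently; a joint multi-season model could
  share the temperature link across years.
* The headline analysis conditions on the posterior-mean curves;
  imputation uncertainty is available (posterior draws) but not
  propagated by default.
* The seasonal response is an unweighted mean over qualifying
  measurements — no depth weighting or trapezoidal integration, matching
  the simplicity of the original seasonal averages; a depth-weighted
  variant would be a straightforward extension.
* The joint multi-stream fit exists behind the score interface but is
  deliberately not the headline analysis at these sample sizes.
```{r session}
sessionInfo()
```
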