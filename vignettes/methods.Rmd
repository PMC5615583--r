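---
title: "Dynamic spatial factor modelling of speciated PM2.5 with linked birth-defect outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic spatial factor modelling of speciated PM2.5 with linked birth-defect outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Speciated fine particulate matter (PM2.5 constituents such as ammonium,
nitrate, sulfate, carbon and crustal metals) is measured at two sparse
monitoring networks — the urban STN and the rural IMPROVE network — every
three to six days.  Constituent concentrations are strongly
cross-correlated (ammonium and nitrate, or sulfur and sulfate, can
correlate above 0.95 in weekly data), so regressing a health outcome on
the individual species is hopeless: the species must be reduced to a
small number of latent pollution *factors*.  At the same time, exposure
must be evaluated at each pregnant woman's residence (including
mid-pregnancy moves), not at the nearest monitor, and the health question
is about *critical windows*: which gestational weeks (3–8, the
embryologic window for lip and palate formation) carry the exposure
effect for cleft lip and cleft palate, two correlated binary outcomes.

`dsfm` implements the full joint Bayesian machinery for this problem:
a multivariate dynamic spatial factor model for the monitoring data, a
Gaussian-process interpolation of the latent factors to residences, and a
bivariate probit model with smoothly varying weekly exposure
coefficients, all fit in a single MCMC.

## The pollutant model

Let $Y_{tp}(s)$ be the weekly mean log concentration of pollutant
$p = 1,\dots,P$ at monitor $s$ in week $t = 1,\dots,T$.  With $M \le P$
latent factors $\delta_t(s) \in \mathbb{R}^M$,

$$Y_t(s) = \mu_t(s) + \Lambda(s)\,\delta_t(s) + \epsilon_t(s), \qquad
  \delta_t(s) = \Gamma(s)\,\delta_{t-1}(s) + w_t(s),$$

a dynamic linear model whose every spatial ingredient varies smoothly
over space:

* **Mean structure** $\mu_{tp}(s) = \bar\mu_{0p} + \bar\mu_{1p}
  \mathbb{1}\{s \in \text{STN}\}$: network-specific intercepts absorb the
  systematic urban/rural difference.  An optional annual harmonic pair
  per pollutant can be switched on (`seasonal = TRUE`); it is off by
  default because the latent factors themselves absorb slowly varying
  seasonal structure.
* **Errors** $\epsilon_{tp}(s) \sim N(0, \sigma^2_{\text{net}(s),p})$
  with network-specific variances (the variance is $\sigma^2_{STN,p}$ at
  an STN site and $\sigma^2_{IMP,p}$ at an IMPROVE site).
* **Loadings** $\Lambda(s)$ is $P \times M$ with the standard
  lower-triangular identification: $\lambda_{pf}(s) = 0$ for $f > p$,
  $\lambda_{pp}(s) = \exp\{g_p(s)\} > 0$ with $g_p \sim
  GP(0, s^2_{\lambda}R(\phi_\lambda))$, and free sub-diagonal entries
  with their own GP priors.  With $M = 1$ every pollutant loads on the
  single factor.
* **Propagation** $\Gamma(s) = \mathrm{diag}\{\gamma_1(s), \dots,
  \gamma_M(s)\}$ with each $\gamma_f$ a Gaussian process *truncated to
  $(-1,1)$* so the temporal dynamics stay stationary at every site.
* **Innovations** $w_{tf} \sim GP(0, s^2_w R(\phi_w))$, independent over
  weeks and factors, spatially correlated across sites; the initial state
  $\delta_{0f} \sim GP(0, s^2_{\delta f} R(\phi_{\delta f}))$.

All spatial kernels are isotropic exponential, $R(d, \phi) =
\exp(-d/\phi)$, on equirectangular-projected kilometre coordinates (a
Matérn-3/2 alternative is available).  The exponential is the
conventional default for irregular monitoring networks: the latent
fields need continuity, not differentiability.  The functional form is a
modelling choice here, as is the projection; over a region of a few
hundred kilometres the projection distortion is below one percent.

## Exposure interpolation

Conditional on the station-site draw, the latent factor path at any
other location follows from the model itself: the initial state and each
week's innovation are *kriged* (exact Gaussian conditionals) to the new
location, the local propagation coefficient comes from its
truncated-normal conditional, and the AR recursion rebuilds the path.
Each residence location is treated as conditionally independent of the
others given the station path; this "composition sampling" matches the
synthetic-data generator exactly and keeps the per-mother Metropolis
corrections of the feedback sampler tractable.  Cross-residence
correlation of the kriging residuals is thereby ignored — a documented
approximation that matters only when two subjects live very close to
each other and far from all monitors.

A subject's exposure $\delta_{i\ell m}$ for gestational week $\ell \in
\{3,\dots,8\}$ is the factor value at the residence she occupied in that
week (movers contribute week-specific addresses), at the calendar week
`conception_week` $+\,\ell - 1$.  `exposure_mode = "sample"` (default)
draws from the conditional law each sweep, so exposure uncertainty
propagates into the health model; `"mean"` gives deterministic kriging.

## The health model

With $\tilde Y_{i1}$ (cleft palate) and $\tilde Y_{i2}$ (cleft lip),

$$Z_i = \beta^\top x_i + \sum_{m=1}^M \sum_{\ell=3}^{8}
  w_{\ell m}\,\delta_{i\ell m} + \epsilon_i, \qquad
  \tilde Y_{ij} = \mathbb{1}\{Z_{ij} > 0\},$$

with per-defect coefficient columns in $\beta$ (twelve dummy-coded
covariates: maternal age, education, fetal sex, high blood pressure,
prediabetes, smoking, alcohol; reference levels "19 and under", "less
than high school", male, and absence of each indicator) and per-defect
weekly curves $w_{\cdot m j}$ given a GP prior over the week axis
(exponential kernel, unit variance, range 2 weeks by default — the model
states smoothness between adjacent weeks; the range is configurable).

**Identification of the latent scale.**  A probit with a free latent
covariance is identified only up to a per-outcome scale.  We fit the
identified model directly: $\epsilon_i \sim N(0, R)$ with $R$ a
*correlation* matrix, so $P(\tilde Y_{ij} = 1) = \Phi(\eta_{ij})$
exactly.  The correlation $\rho$ takes a uniform prior over a fine
symmetric grid (step 0.005 on $\pm 0.99$) and is drawn from its exact
discrete full conditional, which depends on the latent residuals only
through three sufficient statistics — a one-line, provably exact
update.  This design was reached after rejecting two alternatives
empirically: the naive free-covariance Gibbs sampler (inverse-Wishart
prior on an unrestricted $\Omega$, coefficients reported after
rescaling) drifts along the unidentified scale ridge, where the
$N(0, I)$ coefficient prior attenuates every identified effect — the
unit-variance statement of the defect probabilities and a
free-covariance prior cannot both hold literally; and a
parameter-expanded correlation update in the style used for
multivariate probit models proved numerically fragile here, with the
working-scale random walk occasionally amplifying the latent utilities
without bound.  The joint-distribution validation below covers the
grid update as implemented.

## The sampler

One sweep cycles: FFBS for the stacked-site factor path (state dimension
$nM$, spatially correlated innovations, missing cells skipped; the hot
loop is compiled C++), inverse-gamma error variances, normal-normal mean
offsets, site-block Gaussian draws for free loadings and elliptical
slice sampling for the log-diagonal loading fields (tuning-free; three
repetitions per sweep to traverse the loading/factor scale ridge),
coordinate-wise truncated-normal Gibbs for the propagation field, probit
data augmentation, a joint Gaussian draw of $(\beta, w)$, the
parameter-expanded correlation update, exposure re-interpolation, and
inverse-gamma/discrete-grid updates of the GP hyperparameters (ranges
live on a ten-point log-spaced grid spanning 5%–200% of the network
diameter).  The propagation-field hyperparameters
$(s^2_\Gamma, \phi_\Gamma)$ are *fixed* (defaults: variance 0.25, range
half the network diameter): the box-truncated GP prior has an
intractable normalising constant in its hyperparameters, and updating
them while ignoring it targets the wrong posterior.  All other variances
get IG(2, 1) hyperpriors and the mean offsets N(0, 100) — weakly
informative, conjugate choices.

**Two exposure-coupling modes.**  By default (`feedback = FALSE`)
exposures are re-drawn each sweep from their conditional law given the
station path with no feedback from the outcomes — the two-stage
"interpolate from the prior distributions" scheme, in which exposure
uncertainty still propagates into $(\beta, w)$.  With
`feedback = TRUE` the sweep is an exact MCMC kernel for the coherent
joint model: the state path, the discrete range moves and the
state-variance moves are proposed jointly with *recentred* exposures
(the retained exposure residuals are translated/rescaled onto the
proposed conditional law, so the Hastings ratio reduces to the
outcome-likelihood ratio), per-location independence-Metropolis moves
refresh the exposure draws, and the propagation-field update carries the
exposure-site Gaussian terms plus a Metropolis correction for the
truncated-normal normalising constants.  The recentring construction is
what keeps acceptance rates high even when a residence sits next to a
monitor (where the naive prior-density ratio degenerates).

Everything runs from a single master seed (one RNG stream), making runs
bit-reproducible.

## Validation

* **Oracle equivalence.**  The FFBS smoother means and marginal
  covariances, and the kriging interpolator, are compared against
  brute-force conditioning of the full joint Gaussian on instances of
  state dimension $\le 12$ (agreement to $10^{-8}$).
* **Conjugate updates.**  Inverse-gamma, normal-normal,
  inverse-Wishart and truncated-normal full conditionals are compared
  with their closed forms by Kolmogorov–Smirnov distance at 20,000
  draws.
* **Joint-distribution ("getting it right") test.**  A
  marginal-conditional simulator (prior and data draws) and a
  successive-conditional simulator (Gibbs sweep in exact feedback mode
  alternated with data re-draws) are compared on ~24 tracked moments of
  the micro model (3 stations, 8 weeks — the smallest span hosting one
  full gestational window — 2 pollutants, 1 factor, 20 mothers).
  Z-scores within ±4 across all moments are required; the chain-side
  standard errors use batch means with an AR(1) correction on the
  batches.  Because the IG(2, 1) priors give the exponentiated loading
  fields no prior moments, potentially heavy-tailed quantities are
  tracked through bounded transforms, and level summaries of the
  latent and observed fields use medians — mean-|field| functionals are
  dominated by rare prior spikes whose recurrence time in the chain
  exceeds any practical run length.  The validation model uses `mu_prior_var = 2`:
  with the analysis prior variance of 100 the successive-conditional
  chain's mean offsets mix over the prior with an integrated
  autocorrelation time in the thousands, which starves the test of
  power without changing the code paths being validated.
* **Parameter recovery.**  Twenty replicates of a synthetic study (15
  stations, 52 weeks, 4 pollutants, 1 factor, 300 prospectively sampled
  subjects, 900 sweeps) check that the 95% credible intervals cover the
  true covariate coefficients at their nominal rate, and that the
  weekly-effect curve has the right sign at its largest-|truth| week.
  Two design choices make interval coverage a *calibrated* diagnostic:
  the covariate coefficients are drawn from the fitted prior each
  replicate (at a fixed truth, shrinkage priors make nominal coverage
  unattainable for large rare effects, e.g. a prediabetes-sized effect
  observed in ~15 subjects), and the cohort is sampled prospectively
  (the uncorrected probit fit to outcome-selected data targets a tilted
  estimand).  The weekly curve stays at its small study-condition
  magnitudes: the two-stage scheme re-draws exposures without outcome
  feedback, which acts like covariate measurement error whose
  attenuation grows with the weekly-effect size — with prior-scale
  weekly effects the attenuation becomes severe — a limitation of the
  cut scheme rather than a sampler defect (the joint-distribution test
  above validates the exact-mode sampler).  The
  case–control design is retained for the model-comparison and
  classification studies, matching the analysis design.  These problem
  sizes are the package's test-scale choices; the generator defaults
  mirror the full study (40 stations, 20 in the study subregion, 9
  pollutants, 208 cases / 358 controls, 15% movers).
* **Model-order selection.**  On data generated with one factor, the
  health-likelihood DIC prefers $M = 1$ over $M = 2, 3$ in the majority
  of replicates.

## The synthetic-data generator

`generate_stations()` scatters monitors over an abstract
California-like lon/lat box (~800 × 900 km) with a denser central study
subregion and urban-biased STN labels.  `make_truth()` fixes the
generative parameters: the `"study_scale"` preset carries the nine
speciated-PM2.5 constituents with near-duplicate loading rows for
ammonium/nitrate and sulfate/sulfur (small error variances for those
species), reproducing weekly cross-pollutant correlations above 0.9;
annual harmonics; ammonium collected only at STN sites.  Covariate
effects default to magnitudes of the reported posterior summaries for
this outcome pair, covariate frequencies to realistic category shares,
the weekly exposure curve peaks at gestational week 6, and the
defect correlation is 0.51.  Where the study conditions do not pin a
value (GP ranges ~200–400 km, innovation variance 0.6, AR level ~0.6,
within-network noise) the defaults were chosen once as field-realistic
values and are documented in `make_truth()`.

Raw records carry the weekly value (sampling every 3–6 days determines
*when* a site reports; within-week chemical variation is not emulated,
so weekly averaging round-trips exactly), and whole-week outages supply
missingness — a 3–6-day cadence alone never skips an ISO week.  What
passing tests on these data do **not** show: robustness to within-week
variation, detection limits, non-Gaussian measurement error, real
geography or population density, gestational-dating error, or
exposure–confounder correlation; none of these are modelled.

## Numerical choices and limitations

* Covariances are factorised after adding `1e-8`-relative diagonal
  jitter; the FFBS symmetrises and re-jitters as needed and reports the
  observation log-likelihood for divergence detection.
* Truncated-normal draws use log-space CDF inversion, stable to
  standardised bounds beyond ±30.
* The bivariate-normal rectangle probabilities use 64-node
  Gauss–Legendre quadrature on the single-integral reduction (~1e-12
  absolute accuracy to |ρ| ≈ 0.999), validated against adaptive
  quadrature.
* Range parameters move on a discrete grid — a deliberate trade of
  resolution for exactness and speed; the grid posterior is sampled, not
  maximised.
* DIC uses the health-outcome likelihood by default (the quantity the
  factor-count comparison targets); `include_pollutant = TRUE` adds the
  panel likelihood.  The plug-in deviance uses posterior means on the
  identified scale with the correlation averaged on the correlation
  scale.
* Known limitations: no case–control sampling correction (by design,
  matching the analysis being emulated); single shared innovation
  variance/range across factors; the cut (default) mode does not let
  outcomes inform the pollution field; `n·M` beyond a few hundred makes
  the stacked FFBS the dominant cost.
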