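---
title: "Estimating seroincidence from cross-sectional antibody surveys: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating seroincidence from cross-sectional antibody surveys: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serorate)
```

## The estimation problem

Seroincidence — the rate $\lambda$ at which new infections occur per
person-time — is the quantity of epidemiological interest in many settings
where longitudinal cohorts are infeasible. A single cross-sectional survey of
quantitative antibody levels contains information about $\lambda$ because
antibody concentrations rise sharply after infection and then wane over
months to years: a population with frequent infection shows many high titres,
a population with rare infection shows mostly noise-level titres. `serorate`
turns that intuition into a likelihood.

Three inputs are required, on a common concentration scale:

1. **Seroresponse parameters** (`sr_params`): posterior draws of the
   two-phase within-host kinetics parameters per antigen-isotype, previously
   estimated from longitudinal data on confirmed cases (that hierarchical
   Bayesian fit is upstream of this package and out of its scope).
2. **Noise parameters** (`noise_params`): biologic noise level $\nu$,
   measurement CV $\epsilon$, and quantification limits
   $y_{low} < y_{high}$ per antigen-isotype.
3. **Cross-sectional survey data** (`pop_data`): subject id, age in years,
   antigen-isotype, measured value, and any stratification covariates.

## The generative model

**Antibody kinetics.** After seroconversion at time 0 the trajectory rises
log-linearly from baseline $y_0$ to peak $y_1$ at $t_1$ days, then decays as
the solution of $dy/dt = -\alpha y^r$:

$$
y(t) = \begin{cases}
 y_0 e^{\mu t}, & 0 \le t \le t_1,\quad \mu = \log(y_1/y_0)/t_1\\[2pt]
 y_1\!\left[1 + (r-1)\,\alpha\,y_1^{\,r-1}(t-t_1)\right]^{-1/(r-1)}, & t > t_1,
\end{cases}
$$

with the exponential limit $y_1 e^{-\alpha(t-t_1)}$ at $r = 1$. The shape
$r$ interpolates between exponential ($r=1$) and increasingly heavy-tailed
power-law waning; note that the unit of $\alpha$,
concentration$^{1-r}$/day, depends on $r$, so rescaling concentrations by
$s$ requires rescaling $\alpha$ by $s^{1-r}$ (the package never rescales
silently, but the estimate is invariant under a consistent rescaling of all
concentration-valued inputs — this is a tested property). Uncertainty and
between-individual heterogeneity in the kinetics enter as an equal-weight
mixture over the $K$ ensemble draws; draws are fixed for the whole
estimation run, not resampled per subject.

**Exposure.** Infections arrive as a Poisson process with constant rate
$\lambda$, so for a subject of age $a$ the time since the most recent
seroconversion $\tau$ has density $\lambda e^{-\lambda\tau}$ on $(0,a)$,
with an atom $e^{-\lambda a}$ on "never infected". We truncate at age —
subjects cannot have seroconverted before birth — rather than using the
stationary untruncated exponential; age is a required input precisely
because of this. Re-infection (boosting) is not modelled; in high-burden
settings where the inter-infection time is comparable to the decay time the
constant-trajectory assumption degrades, which is the main known limitation.

**Observation noise.** The measured value is

$$
Y = (y_{\mathrm{model}} + B)\,E, \qquad
B \sim \mathrm{Uniform}(0,\nu), \qquad
E \sim \mathrm{LogNormal}(-\tfrac{\sigma^2}{2}, \sigma),\;
\sigma^2 = \log(1+\epsilon^2),
$$

where $y_{\mathrm{model}} = y(\tau)$ for infected subjects and $0$
otherwise. $\nu$ is a noise *level* (the scale of antibody signal in
never-exposed individuals from cross-reactivity and non-specific binding;
in practice calibrated as an upper quantile of the unexposed response
distribution), and the uniform form keeps the $\lambda \to 0$ limit flat
and tractable. $E$ has mean 1 and CV $\epsilon$, the natural multiplicative
form for a positive-valued assay. Values at or outside
$[y_{low}, y_{high}]$ are interval-censored: they contribute
$P(Y \le y_{low})$ or $P(Y \ge y_{high})$ instead of a density. The
simulator samples from exactly this model and the likelihood evaluates
exactly this model — one observation model, two directions — which is what
makes the whole pipeline testable without external data.

A deliberate modelling choice: the composition of $\nu$ and $\epsilon$ into
the likelihood (additive-uniform then multiplicative-lognormal) is one of
several defensible readings of "biologic plus measurement noise". The
`mode` argument of `obs_model()` (`"no-measurement-noise"`,
`"noise-free"`) exists to probe sensitivity to this choice.

## The likelihood and its evaluation

Marginalizing over $\tau$ and the ensemble, the density of one observation is

$$
p(y \mid \lambda, a) \;=\; e^{-\lambda a}\, p(y \mid m{=}0)
 \;+\; \int_0^a \lambda e^{-\lambda\tau}\,
   \frac{1}{K}\sum_{k=1}^K p\!\left(y \mid f_{\theta_k}(\tau)\right) d\tau ,
$$

and the multi-biomarker log-likelihood is the sum of $\log p$ over all
records, treating a subject's biomarkers as independent (summing evidence
across antigen-isotypes increases precision; correlated responses are a
non-goal).

Two implementation facts do most of the numerical work:

* **The noise kernel is closed-form.** For fixed model level $m$, the
  uniform–lognormal convolution integrates analytically to a difference of
  normal CDFs, and so does its distribution function. No inner quadrature
  is needed, the $\epsilon = 0$ limit is exact, and a midpoint form guards
  the $\nu \ll m\sigma$ cancellation regime.
* **The $\tau$-integral uses a feature-adapted composite Gauss–Legendre
  rule, built in the antibody-level domain.** On the decay branch we
  substitute $m = f(\tau)$ (Jacobian $1/(\alpha m^r)$) and place panel
  boundaries at the kernel's own support edges and transition points
  ($y-\nu$, the lognormal bump, its $\pm2.5\sigma$ shoulders), merged with
  titres at fixed fractions of the time since peak and a geometric ladder
  that bound the variation of the exposure weight $e^{-\lambda\tau}$ and of
  the Jacobian within each panel. A log-spaced $\tau$-tail covers the
  fully-decayed regime (kernel flat in $m$) and a short grid covers the
  rise branch, which is included in the integral (no peak shortcut). This
  resolves arbitrarily narrow kernels — down to $\nu = 10^{-9}$, where the
  density collapses to the change-of-variables form
  $\lambda e^{-\lambda\tau(y)}/(\alpha y^r)$ used as an analytic oracle —
  while remaining a fixed, deterministic rule: node positions are
  independent of $\lambda$, so one precomputation serves every likelihood
  evaluation in an optimization run. Panels default to 4 Gauss–Legendre
  nodes (`n_nodes`); against adaptive reference integration the density is
  accurate to a few $10^{-3}$ pointwise in the worst corners and well below
  $10^{-3}$ in probability-weighted terms, which the normalization and
  Kolmogorov–Smirnov acceptance checks verify end to end.

**Optimization.** The likelihood is maximized over $x = \log\lambda$
(positivity, near-quadratic surface). Because the precomputed nodes make
the nll and its first two derivatives in $x$ exact and cheap, we use a
safeguarded Newton search: the bracket grows from the start value by step
doubling in the descent direction and Newton steps with bisection fallback
finish inside it. The nll can be non-monotone at extreme $\lambda$ far
outside the data-supported region, which is why the search trusts local
gradients rather than the bound endpoints. Convergence tolerance is
$10^{-6}$ on $x$; bounds default to $[10^{-6}, 5]$ per person-year. The
standard error of $\hat x$ is $1/\sqrt{d^2\mathrm{nll}/dx^2}$ from the same
analytic curvature (no finite differencing), the default 95% CI is Wald on
the log scale, $\exp(\hat x \pm 1.96\,\mathrm{se})$, and a
profile-likelihood interval is available via
`est_options(ci_method = "profile")`. A fit is flagged `converged = FALSE`
— reported, not suppressed — when the optimum sits at a bound (e.g. a
survey with every value below $\nu$ carries no signal and pins
$\hat\lambda$ at the lower bound) or the curvature is non-positive.

**Stratification.** `est_seroincidence_by()` partitions records by the
cross-product of observed covariate values and fits each cell
independently; a single-cell partition reproduces the overall fit
bit-for-bit, cells can run on several workers with identical results, and
cells with fewer than 30 observations (configurable) trigger a warning.
When the ensemble itself carries a stratum column of the same name, each
cell uses its matching draws.

## The simulator and what passing tests mean

`simulate_pop_data()` draws ages uniformly on a configurable range
(default 2–15 years, the span typical of pediatric enteric-fever
serosurveys), infection histories by exact inverse-CDF sampling of the
age-truncated exponential, one ensemble draw per subject and biomarker, and
noise exactly as above. The default synthetic biomarkers
(`synthetic_sr_centers()`) mimic HlyE IgG/IgA responses — peak around day
10, IgG decaying over years ($r = 1.30$, $\alpha = 0.0012$), IgA faster
($r = 1.35$, $\alpha = 0.0020$) — with 30% lognormal dispersion across
draws (10% on $t_1$, 20% on $r-1$), biologic noise 1.5–2 units, 20% assay
CV, and limits $[0.2, 5000]$. These values are this package's own choices
of a realistic regime, fixed once; they are synthetic stand-ins, not
estimates from any cohort.

By default a subject's biomarkers receive *independent* infection
histories, which makes the simulator exactly self-consistent with the
likelihood's independence assumption — the right configuration for oracle
tests (normalization, KS distance, recovery, coverage). Setting
`share_tau = TRUE` couples a subject's biomarkers through one infection
clock, which is closer to reality and quantifies the cost of the
independence approximation. What passing tests demonstrate is therefore
internal validity: the estimator correctly inverts its own generative
model at realistic parameter values. They do not certify the kinetics
model, the noise composition, or the constant-rate assumption against any
real cohort — that validation needs real longitudinal data and is outside
the package.

The recovery and coverage experiment (`recovery_experiment()`) uses
$\lambda \in \{0.05, 0.2, 0.8\}$ per person-year, $n = 1000$ subjects, one
biomarker, $K = 20$ draws and 200 replicates per rate — deliberately
scaled-down study sizes chosen so the whole experiment is a routine desk
run; at these sizes the relative bias of the mean estimate stays within a
few percent and empirical 95% CI coverage near nominal.

## Numerical and design details worth knowing

* Internal units are days for kinetics and per-day for $\lambda$ during
  optimization; everything user-facing is per person-year (and per 1000
  person-years in summaries). Ages are years. `read_sr_params()` converts
  year-scale inputs (`t1` multiplied, `alpha` divided by 365.25).
* $t = t_1$ is assigned to the rise branch; the two branches agree there by
  continuity, the assignment just fixes determinism. Values exactly at a
  quantification limit are censored (inclusive).
* Degenerate panels (clamped to zero width when a feature point falls
  outside the valid range) carry zero weight and are inert by
  construction, which is what lets one fixed panel layout serve every
  (observation, draw) pair vectorized.
* Duplicate `(id, antigen_iso)` rows are an error, never an average;
  column dialects `y.low`/`y_low` and case-insensitive headers are
  accepted; CSV is the only interchange format (RDS users: one-line export
  via `write.csv(readRDS(f), ...)`).
* `est_options(subsample_draws = k)` gives a seeded fast path using
  $k \le K$ draws per biomarker for very large ensembles.
* `sr_curve_table()` summarizes an ensemble as pointwise trajectory
  quantiles over a time grid — the plot-ready view of the modelled decay
  curve and its predictive uncertainty.
* Known limitations: no boosting/re-infection, no correlated biomarkers,
  no time-varying $\lambda$, no age-dependent kinetics beyond what a
  stratified ensemble expresses.
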