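---
title: "Stochastic first-order kinetics and the emergence of log-normal concentrations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic first-order kinetics and the emergence of log-normal concentrations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lognormkin)
```

## The model

Many loss and production processes in environmental systems are first order:
the rate of change of a concentration $[X]$ is proportional to $[X]$ itself.
With a constant rate $k$ this gives plain exponential decay. In real systems
the rate is rarely constant — it depends on reaction partners, temperature,
radiation, turbulence — and a large part of that dependence is effectively
random. `lognormkin` models the rate as a mean plus Gaussian white noise,

$$\frac{d[X]}{dt} = -\left(\mu_k + \sigma_k\,\eta(t)\right)[X],$$

which is a stochastic differential equation with multiplicative noise:
geometric Brownian motion. Its solutions are strictly positive, and the
marginal distribution of $[X]$ at any time is **log-normal**. In log space
the parameters evolve linearly,

$$\mu(t) = \mu_0 - \left(\mu_k + \tfrac{1}{2}\sigma_k^2\right)t,
\qquad \sigma^2(t) = \sigma_0^2 + \sigma_k^2\,t,$$

while the arithmetic mean follows the deterministic decay
$m(t) = X(0)e^{-\mu_k t}$ exactly, because the noise has zero mean. The
widening of $\sigma^2(t)$ and the extra $\tfrac12\sigma_k^2$ in the location
drift express the same fact: fluctuations in the rate broaden the ensemble
multiplicatively, so the median falls faster than the mean.

### Assumptions, and the Itô convention

Three assumptions carry the result: (i) the deterministic part of the rate
is constant over the window considered; (ii) the fluctuations are fast and
uncorrelated (white) relative to that window, i.i.d. Gaussian with unit
amplitude per $\sqrt{dt}$; (iii) the initial condition is either a point
mass or itself log-normal. Under these, the white-noise limit must be
interpreted in a specific stochastic calculus, and the package adopts
**Itô** throughout: it is the convention under which the location drift
acquires the $\tfrac12\sigma_k^2$ correction shown above (under Stratonovich
that term would be absent). All simulators, the density solver and the
recovery diagnostics are mutually consistent in this convention, and the
Monte-Carlo tests in `tests/testthat/` verify the drift correction
empirically.

`sigma_k` therefore has units of $1/\sqrt{\mathrm{time}}$: it is the
diffusion intensity multiplying a Wiener increment, the only reading under
which the log-variance grows linearly in time.

### Formation processes

For a production term the drift sign flips,
$d[X]/dt = +(\mu_k + \sigma_k \eta(t))[X]$. The package derives the log-drift
from the generic Itô transform rather than hard-coding the sink formula:
$d\ln X = (s\,\mu_k - \tfrac12\sigma_k^2)\,dt + \sigma_k\,dW$ with $s = -1$
for a sink and $+1$ for a formation process. For sinks this reproduces the
evolution law above; for formation the location drift is
$+\mu_k - \tfrac12\sigma_k^2$ — note the correction keeps its sign, because
it originates in the convexity of the exponential, not in the direction of
the process. The variance law is direction-independent. Both directions are
checked against Monte Carlo in the test suite.

## Parameters at a glance

| Parameter | Meaning | Units | Typical default |
|---|---|---|---|
| `mu_k` | mean first-order rate | 1/time | 1 |
| `sigma_k` | rate-fluctuation intensity | 1/$\sqrt{\mathrm{time}}$ | 0.5 |
| `mu`, `sigma2` | log-space location/variance | — (log-concentration) | 0, 0.04 |
| `amplitude` (A) | oscillatory log-amplitude | — | 2 |
| `period` (T) | oscillation period | time | 1 |
| `persistence` | Markov stay-probability | — | none (i.i.d.) |

Parameters are stored as log-space *variance*, matching the linear evolution
law; `log_sd()` exposes the standard deviation. The reference configuration
used across the documentation and tests — $\mu_k = 1$, $\sigma_k = 0.5$,
$X(0) = 1$, $t \in [0, 2]$ — puts the terminal coefficient of variation near
$\sqrt{e^{0.5}-1} \approx 0.8$, i.e. visibly broad but far from degenerate,
which is the regime where the log-normal shape is diagnostic.

## Simulators

`simulate_exact()` samples the closed-form solution: one Wiener path per
trajectory, built from cumulative $\sqrt{dt}\,Z$ increments, so marginals
are *exactly* log-normal at every grid time and paths are temporally
consistent. It is the default scheme: no discretization error and guaranteed
positivity.

`simulate_euler_maruyama()` discretizes the concentration-space equation
with the multiplicative update
$X_{i+1} = X_i\,(1 + s\mu_k\,\Delta t + s\sigma_k\sqrt{\Delta t}\,Z_i)$ and
is kept as an independent validation path, since the model is *stated* in
concentration space. Two guards apply: a stability refusal when
$1 - \mu_k \Delta t \le 0$ (with a suggested `n_steps`), and a positivity
guard that **resamples** any increment whose factor would be non-positive.
Resampling is counted and reported, with a warning above 0.1% of increments;
naive clamping was rejected because it biases the moments. Weak convergence
of this scheme to the exact sampler as $\Delta t \to 0$ is one of the
package's standing checks.

Reproducibility: every stochastic function takes a `noise_spec(seed)` and
draws from a single seeded R stream in a fixed (path × step) order, giving
byte-identical output for identical (configuration, seed). The package does
not evaluate ensembles in parallel, so a single ordered stream provides the
same guarantee a counter-based generator would, without adding a custom RNG.
At the experiment level, one global seed is expanded into per-module
sub-seeds by the published rule in `derive_seed()`, so adding one analysis
step never perturbs another's draws.

## The Fokker–Planck solver

The density evolution corresponding to the SDE is solved in log coordinates
$y = \ln x$, where the generator has constant coefficients:

$$\frac{\partial q}{\partial t} =
  -a\,\frac{\partial q}{\partial y}
  + \frac{\sigma_k^2}{2}\,\frac{\partial^2 q}{\partial y^2},
 \qquad a = s\,\mu_k - \tfrac12\sigma_k^2 .$$

Working in $y$ removes the $x \to 0$ coordinate singularity and makes the
scheme uniformly stable on a regular grid; the concentration-space density
is recovered through the Jacobian $1/x$ when needed. Numerical choices:

* **Crank–Nicolson** time stepping with centered differences and a sparse
  tridiagonal LU solve (factorized once per run, reused each step). The
  first step is split into two backward-Euler half-steps to damp the
  initialization oscillations CN is prone to.
* **Homogeneous Dirichlet** boundaries, chosen over no-flux for simplicity;
  their validity is *enforced*, not assumed: boundary density above $10^{-9}$
  raises a grid-too-narrow error naming the offending boundary.
* Default resolution `n_grid = 2048`, `n_steps = 1000`, on a domain
  spanning ±8 terminal standard deviations around the initial and terminal
  locations. At these defaults the terminal $L^1$ error against the analytic
  log-normal is of order $10^{-4}$ and the worst per-step mass defect of
  order $10^{-13}$; the observed convergence is second order in both the
  time step and the grid spacing (the tests require only $\ge 1$ and
  $\ge 2$ respectively).
* A **degenerate initial condition** ($\sigma_0^2 = 0$) is mollified to a
  Gaussian of standard deviation three grid spacings — a point mass cannot
  be represented on a fixed grid, and three spacings keep the mollifier
  resolved while adding $O(\Delta y^2)$ to the terminal variance.

The process has no nontrivial stationary density (mass drifts towards
$-\infty$ in $y$ for a sink), so only transient evolution is supported.

## The three mechanism generators

Concentration distributions in the field reflect more than one mechanism.
The package generates the three principal classes so their signatures can be
compared:

* **Kinetics** (`sample_kinetic()`): i.i.d. log-normal draws, the fixed-time
  outcome of the model above.
* **Mixing, separated limit** (`sample_mixture()`): each observation comes
  from one source state — e.g. a site that is dominated alternately by two
  cities depending on wind direction — giving a multi-modal distribution.
  Switching is i.i.d. by default (clean for distributional work); a Markov
  mode with a stay-probability reproduces the persistent blocks seen in real
  time series. Both modes share the same marginal distribution and test
  surface, and the hidden state labels are returned for verification.
* **Mixing, well-mixed limit** (`sample_convolution()`): each observation is
  the *sum* of one draw from every listed source, tending to normality on
  the raw scale by the Central Limit Theorem. Repeated i.i.d. sources are
  expressed by replicating one component (`replicate_components()`).
* **External oscillation** (`sample_oscillatory()`): the log-concentration
  is modulated by $A\sin(2\pi t/T + \phi)$ at uniformly sampled times. The
  modulation is **additive in log space** (multiplicative in concentration):
  this preserves positivity, composes with the kinetic log-parameters, and
  contributes exactly $A^2/2$ to the log-variance under uniform phase. The
  shape of the modulation is a package design choice — the mechanism class
  is defined by "a deterministic cycle on top of stochastic kinetics", and
  other positive modulations would serve equally; results that depend on the
  precise waveform should not be over-interpreted. With $A \gg \sigma$ the
  log-marginal is bimodal and log-normality is firmly rejected, illustrating
  that an external cycle can mimic a two-state mixture.

`count_density_modes()` counts kernel-density maxima, by default on the log
scale where log-normal components have equal widths; a maximum counts only
if it rises at least 5% of the global peak above its neighbouring minima,
which suppresses bandwidth ripple without hiding genuine modes.

## Diagnostics

**Fitting.** `fit_lognormal()` uses log-scale maximum likelihood
($\hat\mu$ = mean of logs, $\hat\sigma^2_{ML}$ = ML variance), with the
unbiased variant reported alongside. Log-moment ML was preferred over
raw-scale moment matching because it is exact under the model and has simple
standard errors ($\sqrt{\hat\sigma^2/n}$ and $\hat\sigma^2\sqrt{2/n}$).
Non-positive samples are a hard error listing the offending indices:
non-detects and censored values are explicitly *not* imputed, silently
dropping or substituting them would misrepresent the data, and censoring
support is out of scope.

**Testing.** `test_lognormality()` log-transforms and applies Shapiro–Wilk
(default) or Anderson–Darling. Samples beyond 5000 (the Shapiro–Wilk cap)
are subsampled with a fixed, reported seed. Decisions are per-test; no
multiple-testing correction is applied by default because none is prescribed
for the single-series use case — when screening many series, apply
`p.adjust` on the collected p-values. The type-I error at $\alpha = 0.05$ is
calibrated in the acceptance tests (1000 replicates at $n = 200$).

**Recovery.** `recover_kinetics()` inverts the two linear laws by ordinary
least squares on the per-time log-moments: the log-variance slope estimates
$\sigma_k^2$ (clipped at zero with a flag when the fitted slope is
negative), and the log-mean slope gives
$\hat\mu_k = s(b_m + \tfrac12\hat\sigma_k^2)$. Confidence intervals are
percentile bootstrap over paths (default 500 resamples, seeded). On
noiseless analytic input the recovery is exact to machine precision; on
simulated ensembles with $10^4$ paths and 11 times both parameters come back
within a few tenths of a percent, and the error shrinks as
$O(1/\sqrt{n_{\mathrm{paths}}})$.

**Propagation.** `ratio_params()` and `derived_rate_flux()` implement the
closure of the log-normal family under ratios and products of *independent*
variables — the basis for expecting log-normal isotope signatures, rates and
fluxes when concentrations are log-normal. Independence is an assumption,
documented rather than checked; correlated factors would need the bivariate
extension, which is out of scope.

## Study sizes and what the tests do (and do not) show

The test-suite study conditions are: ensembles of $10^5$ paths for
distributional (KS) checks, $10^4$ for moment and recovery checks on an
11-point grid over $[0, 2]$; the three-state mixture ($\mu = -2, 0, 2$,
$\sigma^2 = 0.04$) at $n = 3 \times 10^4$ for mode counting; 100-seed
replications for pass-rate statements; and $n = 110$ observations per
replicate for the convolution-versus-single-component normality contrast.
That last size was fixed by an a-priori power analysis: it is large enough
that Shapiro–Wilk rejects a single log-normal component
($\sigma^2 = 0.25$) at $\alpha = 0.01$ with near-certainty, yet small enough
that the residual skewness of a 30-fold sum
($\gamma_1 \approx 1.75/\sqrt{30} \approx 0.32$) usually stays below the
test's detection threshold — the two requirements bound the usable $n$ from
both sides, and the contrast is intrinsically a marginal one: with enough
data a finite sum of skewed sources is *always* distinguishable from normal.

The generators emulate stochastic rate variation, source switching, source
summing and a clean external cycle. They do not emulate several features of
real monitoring data: serial correlation of measurement times (except the
optional Markov mixture mode), measurement error, detection limits,
deterministic trends in $\mu_k$, or several mechanisms acting at once.
Passing tests therefore demonstrate internal consistency of model, solver
and diagnostics — not that any particular field data set follows the model.

## Known limitations

* Single-component kinetics only: no coupled reactions, nonlinearities or
  feedbacks; the deterministic rate is constant except for the oscillatory
  generator.
* White-noise rates only; correlated (red) rate noise changes the variance
  growth law and is not implemented.
* Ratio/product propagation assumes independence.
* The Fokker–Planck solver is one-dimensional and transient-only.
* Censored data are rejected, not modelled.
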