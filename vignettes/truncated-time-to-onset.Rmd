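---
title: "Estimating time-to-onset distributions from right-truncated spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-to-onset distributions from right-truncated spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttonset)
```

## The problem

Spontaneous reporting databases collect suspected adverse drug reactions
after marketing. For a case reported by the analysis date, two durations
are known: the time-to-onset $x_i$ (treatment initiation to reaction) and
the truncation time $t_i$ (treatment initiation to the analysis date).
Patients who were exposed and will eventually develop the reaction *after*
the analysis date are entirely absent — not censored, absent. The sample
is therefore **right truncated**: every record satisfies $x_i \le t_i$ by
construction, and naive distribution fitting over-represents short onsets.

`ttonset` estimates the time-to-onset distribution $F(\cdot;\theta)$ from
such data, quantifies what ignoring truncation costs, and provides the
non-parametric reference estimate used for graphical goodness-of-fit.

## Two likelihoods

The *naive* approach treats the onsets as an ordinary i.i.d. sample:
$$L_1(\theta) = \prod_{i=1}^n f(x_i;\theta).$$
The *truncation-based estimator* (TBE) conditions each observation on its
own observability $X_i \le t_i$, giving the conditional density
$f(x;\theta)/F(t_i;\theta)$ and
$$L_2(\theta) = \prod_{i=1}^n \frac{f(x_i;\theta)}{F(t_i;\theta)}.$$
Since each factor's denominator is at most 1, $\log L_2 \ge \log L_1$
pointwise, with equality in the untruncated limit — both facts are used as
package self-checks.

Three families cover the hazard shapes seen in pharmacovigilance, all
parameterized with a rate-like $\lambda > 0$ (units 1/time) multiplying
time and a dimensionless shape $\beta > 0$:

| family | density $f(x)$ | mean |
|---|---|---|
| exponential | $\lambda e^{-\lambda x}$ | $1/\lambda$ |
| Weibull | $\lambda\beta(\lambda x)^{\beta-1}e^{-(\lambda x)^\beta}$ | $\Gamma(1+1/\beta)/\lambda$ |
| log-logistic | $\lambda\beta(\lambda x)^{\beta-1}/(1+(\lambda x)^\beta)^2$ | $\dfrac{\pi/\beta}{\lambda\sin(\pi/\beta)}$, only for $\beta>1$ |

Note $\lambda$ is *not* the `stats::dweibull` scale (which is
$1/\lambda$). The log-density is evaluated directly rather than as
$\log(f)$, so likelihoods stay finite where the density underflows. The
support is $x > 0$; zero onset times are a domain error the caller must
pre-screen. The log-logistic mean does not exist for $\beta \le 1$; the
package signals this with a typed warning (`"tto_undefined_mean"`) and an
`NA`, never a silent `NaN`.

## Maximization and the definition of a failed fit

`fit_tto()` maximizes either likelihood over $(\log\lambda, \log\beta)$,
making positivity structural. The naive exponential fit is the closed form
$\hat\lambda = n/\sum x_i$. All other fits run BFGS followed by up to 8
damped Newton steps on the analytic gradient ("polishing"), which pins
interior maxima to gradient norms near $10^{-10}$ and makes the numerical
path agree with closed forms to $10^{-8}$ relative or better.

Under heavy truncation the conditional model approaches a uniform
distribution as $\lambda \to 0$, so $\log L_2$ has a *flat asymptote* in
$\log\lambda$: for some samples the supremum sits at the boundary and is
not attained. Two numerical choices follow from this geometry:

* the objective is scaled by $1/n$ so the first BFGS step (identity
  inverse-Hessian) stays local instead of jumping over the interior
  maximum into the asymptote's basin;
* a fit is declared **converged** when the polished solution is a
  verified stationary point (scaled gradient norm below `grad_tol`) *and*
  its log-parameters stayed within `max_log_drift` (15 log-units) of the
  start. A boundary escape, a non-finite objective or an unpolishable
  gradient counts as a "problem of maximization" (NPM); one retry from
  parameters scaled by 0.5 and by 2 is attempted first.

We deliberately do *not* condition convergence on the BFGS iteration
count: on near-flat likelihoods BFGS routinely exhausts its iteration
budget one step short of an interior maximum that a single Newton step
then locates exactly; discarding those fits would censor precisely the
below-truth estimates and bias the retained set upward. Because every
optimizer draws this line differently, NPM counts are reported as
diagnostics and never treated as reproducible constants.

Warm starts: $\lambda$ from the naive exponential closed form with
$\beta = 1$; TBE fits start from the converged naive fit of the same
family. This reduces failures on flat likelihoods without changing what
counts as one.

## The conditional non-parametric reference

With distinct onset times $v_1 < \dots < v_m$, multiplicities
$n_j = \#\{x_i = v_j\}$ and risk counts
$N_j = \#\{i: x_i \le v_j \le t_i\}$, the product-limit estimate
$$\widehat{\frac{F(x)}{F(t^*)}} = \prod_{v_j > x}\Bigl(1 - \frac{n_j}{N_j}\Bigr)$$
is the non-parametric MLE of the distribution *conditional* on the onset
falling below the largest truncation time $t^*$. The unconditional $F$ is
not identifiable non-parametrically because $F(t^*)$ is unknown — which is
exactly why the parametric TBE, whose $F(x;\hat\theta_{TBE})$ is fully
specified, is the estimator of applied interest. `npmle()` keeps the
right-continuity implied by the strict inequality $v_j > x$, equals the
empirical CDF when truncation is ineffective, and is tested against a
brute-force indicator-sum oracle.

`gof_curves()` implements the graphical check of Lawless for
right-truncated data: conditional parametric survivals
$1 - F(x;\hat\theta)/F(t^*;\hat\theta)$ overlaid on the non-parametric
curve, plus unconditional survivals, on a 200-point grid by default
(configurable; the exact steps remain available from the `tto_npmle`
object). The sup-distance between each conditional curve and the NPMLE is
attached as a descriptive closeness measure, not a test statistic: formal
goodness-of-fit testing under right truncation is out of scope.

## The simulation engine

`tto_scenario()` fixes the study conditions; these defaults *are* the
design of the replication study, not tuning knobs:

* true family and parameters — the study grid crosses
  $\lambda \in \{0.05, 1\}$, $\beta \in \{0.5, 2\}$ (two-parameter
  families), $p \in \{0.25, 0.5, 0.8\}$, $n \in \{100, 500\}$, giving 12
  exponential and 24 + 24 two-parameter scenarios;
* the truncation bound is always derived, $\tau$ solving
  $P(X < \tau) = p$, and truncation times are uniform on $[0, \tau]$,
  independent of $X$;
* a drawn pair with $x > t$ is discarded and *both* coordinates are
  redrawn, until exactly $n$ pairs are accepted (batched drawing is
  distributionally identical and keeps the loop vectorized; a guard
  aborts past $10^7$ draws);
* 1000 replications per scenario.

`run_scenario()` reports per-parameter bias, MSE and the proportion of
estimates above the truth, computed per method over the replications
where that method's maximization succeeded, with the NPM count alongside.
Exclusion is per method: a replication dropped for the TBE still counts
for the naive summary (the alternative — joint exclusion — is not
documented anywhere we could follow, and per-method exclusion keeps each
column self-contained). Seeding is hierarchical (master seed → scenario
substream → replication substream), so any single replication can be
regenerated in isolation and results are bit-identical for a fixed seed.

What the generator emulates is the sampling design above; what it does
not emulate about real spontaneous reports: under-reporting (assumed
uniform), reporting delays, dependence between onset and truncation
times, covariates, and non-stationary exposure uptake. Passing tests
therefore validate the estimators under the stated design, not the full
reporting process.

## Derived summaries and the bootstrap

For a converged fit, `estimate_p()` returns
$\hat p = F(t^*;\hat\theta)$ — the estimated probability that an eventual
case is already observable — and `expected_tto()` the fitted mean.
`bootstrap_ci()` resamples whole $(x, t)$ pairs with replacement (the
pair is the sampling unit, and pair resampling preserves $x \le t$ by
construction), refits on each resample warm-started at the point
estimate, and forms a bias-corrected accelerated (BCa) interval: $z_0$
from the proportion of bootstrap statistics below the point estimate,
acceleration $a$ from jackknife influence values. The percentile interval
on the same draws is always reported next to it, because the two named
conventions ("simple" and BCa) disagree and showing both costs nothing.

Resamples whose maximization fails, or whose statistic is undefined
(log-logistic mean with resampled $\hat\beta \le 1$ — heavy-tail
resamples would otherwise enter the order statistics as an arbitrary
tie-break), are dropped and counted; an interval built on fewer than half
the requested resamples is flagged unreliable. If any jackknife refit is
unusable, $a = 0$ is used and flagged. With $z_0 = a = 0$ the BCa
interval reduces to the percentile interval — kept as a unit test.

## Problem sizes used by the test suite

The packaged checks run the replication study at reduced scale, with
Monte-Carlo tolerances of three standard errors estimated from the
replication spread: representative scenario cells at 300 replications,
the full 60-scenario grid properties (bias shrinkage in $n$,
near-certain naive over-estimation) at 250 replications, and the nested
bootstrap-coverage study at 60 outer replications of $n = 60$ with 400
resamples. `scripts/acceptance.R` re-runs the headline scenarios at the
full 1000 replications. The bundled demonstration dataset
(`inst/extdata/lymphoma_synthetic.csv`) is *synthetic*: 64 cases drawn
from a Weibull with $\lambda = 0.00468$, $\beta = 1.49$ and $\tau = 529$
weeks, mimicking the shape of a published pharmacovigilance application
whose real data are not publicly available.

## Known limitations

* Only exponential, Weibull and log-logistic families; gamma, log-normal
  and mixtures are out of scope.
* Truncation times are treated as fixed (the likelihood conditions on
  them); joint random modelling of $(X, T)$ is not attempted.
* No regression on risk factors, no standard errors from the observed
  information (the bootstrap is the provided uncertainty measure), and no
  formal goodness-of-fit tests for right-truncated data.
* NPM counts depend on the convergence definition above and should be
  compared across optimizers only qualitatively.
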