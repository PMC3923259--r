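# ttonset

Parametric estimation of adverse-drug-reaction **time-to-onset**
distributions from spontaneous reporting data, which are **right
truncated**: a case enters the database only if its reaction occurred
before the analysis date, so every record satisfies `x ≤ t` (onset lag ≤
truncation lag) and late-onset cases are systematically missing. The
package is written for pharmacoepidemiologists and biostatisticians who
want distributional statements ("how long after treatment initiation does
this reaction occur?") from reporting databases rather than cohorts.

## What it computes

For a sample of pairs (x₁,t₁),…,(xₙ,tₙ) and a family F(·;θ)
(exponential, Weibull or log-logistic, rate-like parameterization
λ multiplying time, shape β):

* the **naive estimator**, maximizing `L1(θ) = ∏ f(xᵢ;θ)` — ignores
  truncation and systematically over-estimates λ (and usually β);
* the **truncation-based estimator (TBE)**, maximizing the conditional
  likelihood `L2(θ) = ∏ f(xᵢ;θ)/F(tᵢ;θ)` — the proper estimator under
  right truncation;
* the **conditional non-parametric MLE**
  `F(x)/F(t*) = ∏_{vⱼ>x} (1 − nⱼ/Nⱼ)` (product-limit over the distinct
  onset times, risk sets Nⱼ = #{i: xᵢ ≤ vⱼ ≤ tᵢ}), used as the
  goodness-of-fit reference;
* derived summaries: observable probability `p̂ = F(t*;θ̂)`, expected
  time-to-onset, BCa bootstrap confidence intervals (pair resampling,
  refit per resample);
* a Monte-Carlo engine reproducing the bias / MSE / over-estimation
  study that quantifies the cost of ignoring truncation across 60
  scenarios.

## Installation and checks

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "ttonset", load_package = "installed")'
```

Imports only base-R infrastructure plus `jsonlite`, `yaml`, `optparse`.

## Worked example

The package ships a synthetic 64-case dataset mimicking a lymphoma
time-to-onset application (Weibull, λ = 0.00468, β = 1.49, truncation
times uniform up to τ = 529 weeks — the generating values are recorded in
the `.meta.json` sidecar):

```r
library(ttonset)
path <- system.file("extdata", "lymphoma_synthetic.csv", package = "ttonset")
cases <- read_cases(path, unit = "weeks")

fit <- fit_tto(cases, family = "weibull", method = "tbe")
summary(fit)
#> <tto_fit> weibull model, truncation-based (TBE) likelihood
#>   lambda = 0.004102, beta = 1.463
#>   log-likelihood: -355.4994   n = 64
#>   t* = 498.6486 weeks;  observable probability p-hat = F(t*) = 0.942
#>   expected time-to-onset: 220.8 weeks

naive <- fit_tto(cases, family = "weibull", method = "naive")
coef(naive)                      # lambda 0.00642, beta 1.49
expected_tto(naive)              # 140.7 weeks
```

The TBE recovers the generating parameters; the naive fit inflates the
rate λ (0.0064 vs 0.0041) and shortens the estimated expected onset time
by 80 weeks (140.7 vs 220.8) — the truncation bias this package exists to
correct. Uncertainty and model checking:

```r
bootstrap_ci(cases, "weibull", "tbe", "mean", n_boot = 1000, seed = 1)
#> <tto_boot> mean (weibull, tbe): 220.8
#>   95% BCa interval: [162.4, 805.7]  (percentile: [156, 543.9])
#>   1000 resamples, 0 dropped

fits <- list(fit, fit_tto(cases, "loglogistic", "tbe"))
attr(gof_curves(cases, fits), "sup_distance")
#>     weibull_tbe loglogistic_tbe
#>           0.078           0.099    # Weibull hugs the NPMLE closer
plot(fit)                           # Lawless-style survival overlay
```

Simulation study, e.g. the exponential grid:

```r
tab <- run_grid(scenario_grid(list(families = "exponential", n_reps = 1000)))
write_scenario_summary(tab, "exponential_summary.csv")
```

A thin command-line wrapper (`inst/cli/ttonset`) exposes `fit`, `npmle`,
`gof`, `simulate` and `fixture` subcommands over the same functions.

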