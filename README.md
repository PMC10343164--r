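# betalos

Heavy-tailed modeling of hospital length of stay (LOS) with the
Beta-Geometric distribution.

## The problem

At the scale of a specialty department, the distribution of LOS is dominated
by its right tail: a minority of very long stays holds a disproportionate
share of total bed-days, the empirical mean converges slowly (or not at
all), and the longer a patient has already stayed, the longer they should be
expected to remain. Thin-tailed models (Gaussian, Poisson) and
outlier-trimming erase exactly the part of the distribution that drives
resource consumption and revenue. `betalos` is for health-services
statisticians and capacity planners who need a discrete, mechanistically
interpretable model of LOS together with the diagnostics that justify it.

## The model

Each admitted patient has a constant daily discharge probability $p$;
across patients $p \sim \mathrm{Beta}(\alpha, \beta)$. The stay length is
then Beta-Geometric on $\{1, 2, 3, \dots\}$:

$$P(X = x) = \frac{B(\alpha + 1,\, \beta + x - 1)}{B(\alpha, \beta)},
\qquad
P(X > x) = \frac{B(\alpha,\, \beta + x)}{B(\alpha, \beta)},$$

a compound law whose tail decays like $x^{-\alpha}$, so the $k$-th moment
exists iff $\alpha > k$ — one parameter family spans thin, geometric-like,
and very heavy tails. The package provides:

* the distribution core (`bg_pmf`, `bg_sf`, `bg_cdf`, `bg_sample`,
  `bg_mean`, `bg_variance`) plus truncated-Gaussian and truncated-Poisson
  baselines;
* maximum-likelihood fitting (`fit_betageometric`) and a threshold-split
  mixture for policy-censored wards — truncated-Poisson body, point-mass
  spike at the policy threshold, shifted Beta-Geometric tail
  (`fit_mixture`);
* Monte-Carlo goodness of fit with a discrete two-sample Kolmogorov–Smirnov
  test (`gof_monte_carlo`, `ks_two_sample_discrete`);
* extreme-value diagnostics: mean excess / mean residual life
  (`mean_excess`), maximum-to-sum moment plots (`max_to_sum`), exponential
  QQ of log data (`qq_exponential_log`), empirical subexponentiality ratio
  (`subexp_ratio`);
* concentration and revenue analysis: Gini with seeded bootstrap (`gini`,
  `gini_bootstrap`), (reversed) Lorenz curves (`lorenz`),
  `concentration_share`, elbow detection (`find_elbow`), charge-per-day
  curves and piecewise correlations (`charge_per_day_curve`,
  `piecewise_correlation`);
* admission-registry ingestion and aggregation (`read_records`,
  `per_admission_sample`, `per_patient_sample`, `descriptive_stats`,
  `spike_frequency`);
* a seeded synthetic registry generator with ground truth
  (`generate_cohort`, `make_fixture`) and a command-line driver
  (`los_cli`, wrapped by `inst/cli/los.R`).

## Worked example

Simulate a surgery-like cohort (≈9,000 admissions), fit the model, test the
fit, and quantify concentration:

```r
library(betalos)

sim <- make_fixture("surgery", scale = 0.5, seed = 42)
s <- per_admission_sample(sim$cohort, "surgery")
s
#> LOS sample (per-admission, surgery): n = 8968, mean = 7.400, median = 5, max = 138

fit <- fit_betageometric(s)
fit
#> Beta-Geometric maximum-likelihood fit
#>   alpha = 6.28118, beta = 33.8065, shift = 0
#>   log-likelihood = -26156.5069   n = 8968   converged: TRUE

gof_monte_carlo(s, fit$params, m = 1e5, seed = 42)
#> Discrete two-sample KS: D = 0.0063 (n = 8968, m = 100000)
#>   critical value at level 0.05: 0.0150 -> no evidence against equality

gini_bootstrap(s, n_boot = 1000, seed = 42)
#> Gini index: 0.5040 (bootstrap SE 0.00345, 95% CI [0.4973, 0.5106], B = 1000, n = 8968)

concentration_share(s, 0.5)
#> [1] 0.1741748
```

Reading: the fitted $\hat\alpha = 6.3$, $\hat\beta = 33.8$ put the mean
stay at $(\hat\alpha + \hat\beta - 1)/(\hat\alpha - 1) \approx 7.4$ days
with a finite variance but heavy higher-order behavior; the KS distance
0.0063 is well under the 5% critical value, so the single compound law is
compatible with the data; a Gini of 0.50 and the fact that 17.4% of
admissions hold half of all bed-days quantify how concentrated resource
consumption is. The mean excess curve (`mean_excess(s)`) starts near 7.6
days at threshold 1 and *rises* with the threshold — the longer a patient
has stayed, the longer the expected remainder.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/los.R simulate --fixture surgery --scale 0.5 --seed 42 --out out/
Rscript inst/cli/los.R report --input out/cohort.csv --seed 42 --out out/
```

See `vignettes/beta-geometric-los.Rmd` for the full methodology: model
assumptions, fitting strategy, the policy-spike mixture, diagnostic
conventions, and what the synthetic generator does and does not emulate.

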