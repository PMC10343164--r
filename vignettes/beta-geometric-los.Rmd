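---
title: "Modeling hospital length of stay with the Beta-Geometric distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hospital length of stay with the Beta-Geometric distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betalos)
```

## The model

Hospital length of stay (LOS), measured in whole days with a minimum of one,
is notoriously right-skewed at the scale of a specialty department: most
admissions are short, but a minority of very long stays carries a large share
of the total bed-days. `betalos` models this with a compound discharge
process built from two assumptions:

1. once admitted, a patient has a constant probability $p$ of being
   discharged on each subsequent day, so conditionally on $p$ the stay is a
   shifted geometric variable, $P(X = x \mid p) = p(1-p)^{x-1}$ on
   $\{1, 2, 3, \dots\}$;
2. $p$ varies across patients (case mix, care type, policy), following a
   Beta$(\alpha, \beta)$ law.

Integrating $p$ out gives the Beta-Geometric distribution

$$P(X = x) = \frac{B(\alpha + 1,\; \beta + x - 1)}{B(\alpha, \beta)},
\qquad x \in \{1, 2, 3, \dots\},$$

with survival function $P(X > x) = B(\alpha, \beta + x)/B(\alpha, \beta)$.
This is a *compound* law, not a mixture: a single coherent mechanism whose
tail weight is governed by the low-$p$ mass of the Beta law. Its tail decays
like $x^{-\alpha}$, so the $k$-th moment exists iff $\alpha > k$: the closed
forms are $E[X] = (\alpha + \beta - 1)/(\alpha - 1)$ for $\alpha > 1$, and a
finite variance requires $\alpha > 2$. `bg_mean()` and `bg_variance()`
return `Inf` as an explicit signal — not an error — when a moment diverges,
because the tail diagnostics need to branch on moment existence. A `shift`
parameter translates the support to $\{s+1, s+2, \dots\}$; it exists to
model the tail of policy-censored wards (below).

All Beta-function ratios are evaluated as differences of log-gamma sums:
fitted $\beta$ values in the hundreds push $\beta + x - 1$ far past what raw
Gamma ratios survive.

## Maximum likelihood

The log-likelihood of observations $x_1, \dots, x_n$ is

$$\log L(\alpha, \beta) = \sum_{i=1}^{n} \log B(\alpha + 1, \beta + x_i - 1)
  - n \log B(\alpha, \beta).$$

`fit_betageometric()` maximizes it over $(\log\alpha, \log\beta)$ with
L-BFGS-B inside the box $|\log\theta| \le 16$. The surface is ridge-shaped
when $\alpha + \beta$ is large (the geometric limit, where only
$\alpha/(\alpha+\beta)$ is identified), so the fit is multi-start: a
method-of-moments point matching $P(X = 1) = \alpha/(\alpha+\beta)$ and the
closed-form mean, plus four dispersed fallbacks. The `converged` flag is
honest — it requires the optimizer to report success, the numerical gradient
norm to be below `1e-4 * (1 + |logL|)`, and the estimate to sit strictly
inside the box; a sample of all-equal values is reported as a boundary case
rather than an estimate. Tabulating the sample first makes each likelihood
evaluation scale with the number of *distinct* LOS values, so fitting $10^5$
observations takes well under a second.

```{r fit-example}
x <- bg_sample(1e5, bg_params(7.03, 38.6), seed = 1)
fit_betageometric(x)
```

## Policy-censored wards: the threshold-split mixture

Some wards administratively cut stays short at a round threshold $T$ (20
days in the motivating registry), which shows up as a point mass at $T$ far
exceeding both neighbors. A single compound law cannot absorb that;
`fit_mixture()` fits a three-part model with disjoint supports covering
$\{1, 2, \dots\}$:

* a truncated Poisson body on $1 \dots T-1$ (renormalized to the window —
  fitting a plain Poisson restricted to the window would bias the rate);
* an optional point-mass *spike* exactly at $T$;
* a shifted Beta-Geometric tail.

Weights are the empirical stratum proportions, and each component is fit on
its own stratum (the tail by subtracting the shift, fitting, and adding it
back — the fit is invariant under that translation). The observation exactly
at $T$ is ambiguous: with `spike = TRUE` (default) it forms its own
component and the tail models values $> T$ with shift $T$; with
`spike = FALSE` it joins the tail, which then models values $\ge T$ with
shift $T - 1$. Both conventions keep the shifted tail support starting at 1.

## Goodness of fit

`gof_monte_carlo()` draws $10^5$ values from the fitted model under a
recorded seed and compares them with the data through a **discrete**
two-sample Kolmogorov–Smirnov test: the D-statistic is the largest ECDF gap
over the union of observed values (with integer data, ties are the norm and
the continuous-case machinery does not apply). The critical value uses the
asymptotic two-sample form $c(\ell)\sqrt{(n+m)/(nm)}$ with
$c(\ell) = \sqrt{-\log(\ell/2)/2}$ (1.358 at the 5% level); on discrete data
this is conservative, which is the direction we accept — our calibration
check simulates data from the model itself and requires at most a 10%
rejection rate at nominal 5%. A seeded permutation p-value
(`p_value = TRUE`, 2000 label shuffles by default) is available when
exactness under discreteness matters.

## Heavy-tail diagnostics

Four complementary views, all exported as plain data frames:

* **Mean excess** `mean_excess()`: $ME(a) = E(X - a \mid X > a)$ at each
  distinct observed threshold. Decreasing = thin tail with memory; constant
  = memoryless (geometric/exponential); increasing = the "Lindy" regime
  where the longer a patient has stayed, the longer they are expected to
  remain. The rightmost part of any empirical curve bends down for lack of
  higher observations (finite-sample bias); monotonicity checks therefore
  look at the lower 90–95% of thresholds, and `trim_top_fraction` trims the
  returned curve if desired (full curve by default).
* **Maximum-to-sum** `max_to_sum()`: the running ratio
  $M(n,p)/S(n,p)$ vanishes iff $E[X^p] < \infty$. With $\alpha \le 1$ the
  mean itself diverges and the trajectory refuses to die.
* **Exponential QQ of logs** `qq_exponential_log()`: log-transformed
  Pareto-like data is exponential, so linearity of sorted $\log x$ against
  exponential quantiles at positions $i/(n+1)$ flags a generalized-Pareto
  tail.
* **Subexponentiality ratio** `subexp_ratio()`: estimates
  $(1 - F^{(2)}(x))/(1 - F(x))$, which tends to 2 for subexponential laws —
  two patients jointly exceeding a high threshold is just twice as likely as
  one of them doing so, because the sum is dominated by its largest term.
  From parameters it draws two independent seeded samples; from data it
  splits the sample into random halves to manufacture independence (the
  pairing is arbitrary, which is exactly what exchangeability requires).
  Default thresholds span the 99th–99.9th percentiles of the single copy:
  far enough out to be in the tail regime, close enough in that binomial
  standard errors at $10^6$ draws remain a few percent.

## Concentration and revenue

`gini()` uses the plain sample formula
$G = 2\sum_i i\,x_{(i)} / (n \sum x) - (n+1)/n$ (the $n/(n-1)$ correction is
exposed but off by default — immaterial at registry sizes), with a seeded
nonparametric bootstrap (`gini_bootstrap()`, 1000 resamples, percentile CI)
for uncertainty. `lorenz(reversed = TRUE)` orders units by *decreasing*
value so the curve reads "the top $x$% of admissions hold $y$% of
bed-days", and `concentration_share()` inverts it. `find_elbow()` locates
the knee of a curve as the point of maximum perpendicular distance to the
endpoint chord, declaring "no elbow" when that distance is below $10^{-3}$
of the chord length so straight lines cannot yield spurious breakpoints;
ties break toward smaller $x$, and a second breakpoint is found by recursing
on the remainder.

`charge_per_day_curve()` averages total charge divided by LOS within each
exact LOS value, optionally restricted by discharge outcome, and
`piecewise_correlation()` computes Pearson correlations of that averaged
curve within LOS ranges — over distinct LOS values, unweighted, by default
(weighting by admission counts is an option; the two differ materially when
long-LOS cells are sparse). Bootstrap uncertainty resamples *admissions* and
recomputes the whole curve, so the interval reflects curve-construction
noise, not just within-range scatter.

## Registry conventions

LOS is defined from the dates: `max(1, discharge - admission)`, so same-day
discharges count one day. A stored LOS column is validation only;
disagreements are reported and the dates win. ISO 8601 dates are the
default; day/month/year strings are accepted only under an explicit
`dmy = TRUE` because "03/04" cannot be guessed safely. Rows with
unparseable dates or reversed date order are rejected into a reported
attribute, never silently dropped. Discharge outcomes classify by exact
case-normalized match into the positive set (Complete recovery, Improved,
Delivered, D/C with mother) and the negative set (Dead, Not improved, D/C
separately); everything else is `unknown`. `descriptive_stats()` defaults to
biased (population) moment estimators and Pearson (non-excess) kurtosis —
conventions that materially affect cross-study comparison, so both are
switchable and recorded in the output.

## What the synthetic generator does and does not emulate

`generate_cohort()` exists so that every analysis path can be exercised
end-to-end with known ground truth. Per department it draws an admission
count per patient (geometric with a configurable mean by default — only the
patients-to-admissions *ratio* is observable in practice, so the law itself
is a modeling choice), a LOS per admission from a Beta-Geometric or
threshold-split mixture, a daily charge from piecewise-linear segments plus
symmetric Gaussian noise floored at a positive minimum, and a discharge
outcome. The policy spike is generated as an explicit point-mass mixture
component rather than by relocating tail mass onto the threshold: it is one
plausible mechanism among several, has the advantage of matching the fitted
model object exactly, and makes the configured spike share the true one.

The four presets (`make_fixture()`) encode archetypal departments: three
freely varying wards with heavy tails of decreasing severity (surgery,
OB/GYN, pediatrics; $\alpha$ from 7.1 down to 3.3 at realistic cohort
sizes), and a rehabilitation ward with 304 patients, a patients-to-admissions
ratio of 30.52%, an 11.46% spike at 20 days, a truncated-Poisson body (rate
14), and a thin Beta-Geometric tail ($\alpha = 37.3$, $\beta = 387.4$,
shift 20). The rehab body rate and weights are the package's calibration to
give an overall mean near 24.6 days and a median near 21.

What passing tests on these cohorts shows: the estimators recover known
parameters at realistic sample sizes, the pipeline runs end to end, and the
diagnostics classify tail regimes correctly. What it does not show: real
registries have DRG-level heterogeneity beyond a single Beta law, seasonal
admission dynamics, and coding noise in identifiers and statuses — none of
which the generator produces. Admission dates in particular are uniform in
the window; the generator makes no attempt at census/occupancy realism.

## Numerical choices and test problem sizes

* Log-gamma evaluation everywhere a Beta-function ratio appears; geometric
  sampling by inverse CDF in double precision, so tiny $p$ draws cannot
  overflow integer storage.
* Optimizer: L-BFGS-B on the log scale, box $\pm 16$, `factr = 1e4`, up to
  5 starts; convergence = optimizer success + gradient norm + interior
  estimate.
* KS critical coefficient 1.358 at 5%; permutation alternative B = 2000.
* Bootstrap defaults: 1000 resamples, percentile intervals, seeded.
* Elbow tolerance: relative chord distance $10^{-3}$.
* Test problem sizes were chosen to make Monte-Carlo bands comfortably
  decisive: $10^5$ draws for parameter-recovery checks (20 seeds), $10^6$
  draws for tail diagnostics (DKW bands, mean-excess regimes,
  maximum-to-sum, subexponentiality), $5 \times 10^4$–$10^5$ for KS
  calibration over 100 replicates, and scaled-down fixtures (10% cohorts)
  for pipeline smoke tests.

## Limitations

The Beta-Geometric is a single-department marginal model: no covariates, no
within-stay dynamics, and no occupancy process. For wards with
administrative censoring the mixture fit is honest but its threshold must be
supplied, not discovered. With $\alpha$ near or below 1 empirical moments
converge slowly or not at all — that is the model's point, but it also means
summaries like the sample mean of a fitted ward should be read through the
closed forms, not the data. Finally, the discrete KS critical value is
asymptotic and conservative under heavy ties; use the permutation p-value
when the decision is close.
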