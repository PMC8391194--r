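---
title: "Methods: a Bayesian net-benefit rule for pandemic reopening decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian net-benefit rule for pandemic reopening decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdecide)
```

## The decision problem

A government that has suppressed economic activity during a pandemic must
decide, on a given day, whether to relax the suppression ("decremental
suppression" — partial or full reopening). `nbdecide` quantifies this
decision through the per-capita change in net benefit

$$\Delta NB = \text{income increase} - \text{fatality cost increase} -
\text{medical cost increase},$$

and the rule: **reopen when the expected $\Delta NB$ is positive and
$P(\Delta NB > 0) \ge T$**, where $T \in (0, 1]$ encodes the
decision-maker's risk aversion ($T = 0.9$ means reopening is recommended
only when a positive net benefit is near-certain). Both ingredients are
posterior predictive quantities, so every step below is about getting a
defensible predictive distribution for income and for cost.

## The two econometric models

Both components ride on the **test positivity** $c_t$ — cumulative
confirmed cases divided by cumulative tests — which links the economic and
epidemiological sides.

**Employment (benefit side).** Weekly percent employed $E_t$ (0–100 scale)
follows an autoregression with exogenous covariates:

$$E_t = \alpha_0 + \alpha_1 c_t + \alpha_2 d_t + \sum_{i=1}^{p} \phi_i
E_{t-i} + \varepsilon_t, \qquad \varepsilon_t \sim N(0, \sigma^2),$$

where $d_t$ is a binary regime dummy equal to 1 during recession and
pandemic windows. A one-step-ahead draw of $E_{t+1}$ under a hypothetical
infection rate, times annual per-capita income / 100, is a draw of the
income benefit (`income_from_employment()`). The regime dummy is held at 1
for pandemic-period predictions (overridable through the scenario
argument), since the prediction step is by construction inside the
pandemic regime.

**Fatality rate (cost side).** The daily death rate
$w_t = \text{cumulative deaths}_t / \text{cumulative cases}_{t-7}$
(a seven-day lag separates infection from death; `compute_death_rate()`)
follows the same ARX form with coefficients $\gamma_0, \gamma_1$ and $m$
lags. The numerator is read as *cumulative* deaths: that is the scale
health agencies report, and it is the reading consistent with a Florida
baseline death rate of 3.48% in mid-2020. Incident deaths remain available
via `compute_death_rate(..., numerator = "incident")`.

A fatality-rate draw $w$ at scenario infection rate $c$ converts to
dollars through the cost model with baseline $(w_0, c_0)$ observed on the
decision day:

$$\Delta\lambda_{S_i} = (w_0 c_0 - w c)\, C_{S_i}, \quad
\Delta\lambda_D = (w c - w_0 c_0)\, C_D, \quad
\text{total} = (w c - w_0 c_0)(C_D - C_{S_1} - C_{S_2} - C_{S_3}).$$

Defaults: $C_{S_1} = \$2{,}000$ (testing/treatment of an uninfected
symptomatic person), $C_{S_2} = C_{S_3} = \$15{,}000$ (treatment of an
infected patient who recovers / dies — set equal because there is no
reliable basis for distinguishing them), $C_D = \$7$ million (a
value-of-statistical-life figure), giving the composite multiplier
$\$6{,}968{,}000$ exactly. Fatality cost dominates: errors in the medical
cost assumptions barely move the decision. Costs can be negative when the
scenario product $wc$ falls below the baseline product; that is a feature
of measuring *changes* against a baseline, not a bug.

## Priors, sampler, and why the sampler is blocked

Priors are deliberately diffuse: $N(0, 100)$ on the intercept and
exogenous coefficients, uniform on $[-1, 1]$ for **each** AR coefficient
(joint stationarity of higher-order lag polynomials is *not* enforced),
and inverse-gamma$(0.01, 0.01)$ on $\sigma^2$. MCMC defaults are 20,000
iterations per chain, 10,000 burn-in, two chains; the likelihood
conditions on the first $p$ observations.

All full conditionals are conjugate given $\sigma^2$. The implementation
draws the entire coefficient vector (intercept, exogenous, AR) as **one
block** from its exact truncated multivariate normal full conditional, by
rejection from the unconstrained conjugate normal; if the $[-1,1]^p$ box
rejects 64 proposals in a row, that iteration falls back to an exact
component-wise scan (conjugate normal for the regression block, univariate
truncated normal per AR coefficient). The blocking matters: on
employment-scale data (level $\approx$ 90–100) the intercept and AR
coefficients are nearly collinear, and a one-coefficient-at-a-time scan
has split-$\hat R$ in the double digits at realistic chain lengths, while
the blocked sampler sits at $\hat R \approx 1.00$ within a few thousand
iterations. Both versions are exact; blocking is purely a mixing
improvement. $\sigma^2$ uses its conjugate inverse-gamma update.

Diagnostics are split-chain $\hat R$ (pass threshold 1.05, warning
attached to the fit otherwise) and a bulk effective sample size built from
the combined-chain autocorrelation sequence with Geyer's initial
positive/monotone truncation, capped at the retained draw count. Credible
intervals are highest-posterior-density intervals: the shortest contiguous
window containing the requested mass of the sorted pooled draws. Note the
endpoints of this estimator converge slowly (cube-root rate), so
reporting-precision agreement should only be expected with $10^5$ or more
effectively independent draws.

## Lag-order selection

The AR order is chosen by posterior model probability over candidates
$1..p_{\max}$ under a uniform model prior. The marginal likelihood uses
the Laplace–Metropolis estimator: posterior mean and covariance of the
retained draws (variance on the log scale, with the Jacobian folded into
the prior term) plug into the Laplace approximation, with the likelihood
and priors evaluated at the posterior mean. It is deterministic given the
draws, accurate to a few hundredths of a nat against conjugate/quadrature
oracles at this dimensionality ($\le 10$ parameters), and cheap. All
candidates are scored on a common window (the first $p_{\max}$
observations are excluded from every candidate's likelihood) so no model
sees data another one conditions away.

One practical note: on smooth, near-unit-root series the *individual* AR
coefficients of over-parameterized candidates are weakly identified even
when the order itself is well resolved; the identifiable quantities are
the AR polynomial sum and the exogenous coefficients. The validation suite
is written against those.

## From predictive draws to the decision table

Benefit and cost predictive distributions are approximately normal, so the
$\Delta NB$ stage summarizes them by mean and SD and draws `n_draws =
5000` independent normal pairs, subtracting cost from benefit
(`delta_nb()`). Reported: mean, SD, central 95% interval, and
$P(\Delta NB > 0)$.

Scenario tables extend the rule to policy choices. Policy $j$ (Minor /
Moderate / Major reopening) induces incremental infection rate $k \in
\{10, 15, 20, 25\}\%$ with probability $\pi_{jk}$ (each row sums to 1).
Then

$$E(B_j) = \sum_k \pi_{jk} E(B_{jk}),$$

and $P_j = P(B_j > 0)$ is computed from the $\pi$-weighted **sum of
independent per-rate draws**: for each draw index, one normal draw per
rate, weighted and summed; its closed form is
$\Phi\!\left(\sum_k \pi_{jk}\mu_k \big/ \sqrt{\sum_k \pi_{jk}^2
\sigma_k^2}\right)$ (`analytic = TRUE`). A mixture reading
($\sum_k \pi_{jk} P_k$) is exposed behind `mechanism = "mixture"` but is
not the default: it is inconsistent with the weighted-expectation
construction of $E(B_j)$ — on the Florida reference numbers it yields
0.874 for the Minor policy under the first scenario where the
weighted-sum mechanism (and the published table) give 0.998–0.999.

Choice rules: risk-neutral takes $\arg\max_j E(B_j)$; risk-averse takes
the best policy among those with $P_j > T$, or abstains. Exact ties in
$E(B_j)$ go to the policy listed earlier (the less disruptive reopening) —
conservative under equal expected benefit. Dollar cells are rounded to the
nearest dollar (round-half-to-even), probabilities to four decimals.

## Synthetic data: what it emulates and what it does not

The generators exist so that every stage is testable without external
data, with known ground truth attached to each panel.

* `gen_employment_panel()` runs the weekly ARX recursion directly over a
  dummy schedule with one recession window and one open-ended pandemic
  window, with the infection path zero before onset. Defaults are the
  posterior means of the fitted Florida employment model
  ($\alpha_0 = 0.60$, $\alpha_1 = -5.67$, $\alpha_2 = -0.05$,
  $\phi = (0.32, 0.99, -0.06, -0.26)$, $\sigma^2 = 0.0239$, 695 weeks), so
  the default panel mimics the study series: level near 100, AR sum near
  one.
* `gen_epidemic_panel()` simulates the fatality-rate ARX process and
  back-constructs counts: `cum_positives = round(c * cum_tests)`,
  `cum_deaths[t] = round(w[t] * cum_positives[t-7])`, both forced
  non-decreasing. Back-construction (rather than a mechanistic epidemic
  simulator) guarantees the panel satisfies the rate model's assumptions
  exactly. The structural coefficients default to the fitted Florida
  fatality model; the noise SD defaults to 0.001 — about 2% of the rate
  level — **not** to the fitted residual scale (0.02). The reason is
  arithmetic: under monotone cumulative deaths the recovered rate can only
  fall as fast as lagged cases grow, so a rate path with ±50% daily
  excursions is untrackable (the monotonicity constraint binds on >80% of
  days and recovery fails), whereas a smooth path — which is also what a
  ratio of two cumulative series actually looks like — keeps the
  constraint binding on <5% of days with recovery error $\sim 10^{-3}$.
  Larger noise remains available through `sigma`.

What the generators do **not** emulate: reporting artifacts (weekend dips,
backfills), mechanistic epidemic dynamics, seasonality in employment, and
any cross-state structure. A pipeline that passes on these panels is
validated as *software implementing the model*, not as a claim that the
model describes any particular real series.

## Validation design and problem sizes

The suite validates against independent oracles, at sizes chosen to keep
a full run in a couple of minutes:

* **Sampler vs conjugate/quadrature oracle** — for lag-free models the
  posterior is computed exactly by conjugate algebra given $\sigma^2$
  plus dense 1-D quadrature over $\sigma^2$; MCMC moments must agree
  within 3 Monte-Carlo standard errors, and Laplace–Metropolis evidence
  within 0.1–0.2 nats.
* **HPD coverage** — 20 ARX(1) panels (n = 300, oscillating infection
  path so the infection coefficient is identified separately from the
  regime dummy), 5 parameters each; observed coverage must not be
  statistically below 0.95 (one-sided binomial test, $\alpha = 0.01$).
* **Order recovery** — lag selection must pick the true order of a
  strong-signal AR(2) ($\phi = (0.5, 0.3)$, $\sigma = 0.05$, n = 600) in
  at least 18 of 20 seeds.
* **Predictive floor** — one-step out-of-sample RMSE on a synthetic AR(1)
  (n = 1000, 50-step expanding-window holdout) must approach the
  innovation SD within 20%.
* **Decision layer** — the nine expected-benefit cells, nine policy
  probabilities, expected incremental rates, and per-rate
  $P(\Delta NB > 0)$ values recomputed from the shipped Florida reference
  summaries must match the published table (one cell of which differs by
  \$1 from exact weighting of its own published inputs — a rounding
  artifact in the source; the implementation keeps exact arithmetic).

## Known limitations

* Employment enters through a single-equation model; aggregate supply
  effects and income composition are not modelled.
* The uniform $[-1,1]$ prior per AR coefficient does not impose joint
  stationarity for $p > 1$; near-unit-root posteriors are legitimate
  outputs and show up as wide, asymmetric HPDs.
* The weighted-independent-sum mechanism for $P_j$ assumes independence
  across the per-rate $\Delta NB$ distributions; if the same posterior
  draws underlie every rate, positive correlation would widen the sum's
  spread.
* Multi-step forecasting with feedback of predicted lags is out of scope;
  predictions are strictly one step ahead.
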