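---
title: "A trend-sensitive Bayesian index of Good Environmental Status: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trend-sensitive Bayesian index of Good Environmental Status: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesbayes)
```

## The assessment problem

Marine policy frameworks such as the EU Marine Strategy Framework Directive
ask for one answer to a holistic question — is the ecosystem in Good
Environmental Status (GES)? — built from many heterogeneous indicator time
series (fish community metrics, contaminant concentrations in bird eggs,
nutrient loads, ...). Each indicator comes with an agreed target, a direction
in which "good" lies, and sampling uncertainty around every annual mean.
`gesbayes` turns that bundle into a single posterior probability of GES per
assessment year, in a way that is sensitive to trends but buffered against
ordinary interannual variability.

## The model

**Per-indicator likelihood (censored pass/fail form).** The annual mean
$X_{i,t}$ of indicator $i$ is an estimate with sampling standard deviation
$\sigma_{i,t}$. Because the assessment question is binary — target passed or
not — the likelihood of the hypothesis "GES" uses the probability
*distribution* function rather than the density: the pass probability is the
mass of the sampling distribution of the mean on the good side of the target
$S_i$,
$$p_{i,t} = P(X_{i,t} \text{ on the good side of } S_i)
         = \Phi\!\left(\frac{\pm(X_{i,t}-S_i)}{\sigma_{i,t}}\right)$$
with the sign set by the direction of "good". A mean exactly at its target
gives $p = 0.5$ for any symmetric sampling distribution: the indicator is as
likely as not to have passed. `ges_likelihood()` implements the normal case,
a moment-matched lognormal for strictly positive, right-skewed concentration
data, and the degenerate ($\sigma = 0$) step case.

**Aggregation and prior chaining.** With conditionally independent
indicators the likelihood of the data under GES is the product
$\prod_i p_{i,t}$, and under the complementary exclusive hypothesis non-GES
it is $\prod_i (1-p_{i,t})$ (the non-GES likelihood is forced by the
two-state censored form, though it is easy to leave implicit). Bayes'
theorem over the two exclusive states gives
$$P(\mathrm{GES}\mid X_t) =
  \frac{\pi_t \prod_i p_{i,t}}
       {\pi_t \prod_i p_{i,t} + (1-\pi_t)\prod_i (1-p_{i,t})},$$
and the chain $\pi_{t+1} = P(\mathrm{GES} \mid X_t)$ carries the assessment
forward: the index "remembers" the former state. Products commute, so the
posterior is invariant to indicator order, and an indicator at $p = 0.5$
contributes nothing — uninformative evidence leaves the posterior exactly at
its prior. These two properties are tested as invariants.

**Worked two-indicator arithmetic.** Two indicators exactly at target under
prior 0.45 give posterior 0.45 in year one, and — since the chained prior is
again 0.45 and the evidence again neutral — 0.45 in year two as well. A
published variant of this construction prints 45.1% for the second year;
that value is not reproducible under the exact-at-target reading (neutral
evidence cannot move the posterior), which suggests the underlying
likelihoods sat marginally above one half. The package reproduces 45.0 and
records the discrepancy here. For evidence 10% above target the same
construction run through `posterior_ges()` climbs from 59.7% to about 72.8%
in the second year; 10% below target with prior 0.55 falls from 40.9% to
about 28.2%. Both follow from inverting the year-1 posterior for the common
pass probability and chaining it forward — `scripts/acceptance.R` recomputes
them.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `prior0` | 0.5 | initial prior probability of GES; 0.5 is uninformative. Worked examples above use 0.45/0.55 as configured values, not defaults. |
| `distribution` | `"normal"` | sampling distribution of the annual mean; `"lognormal"` for concentration-type indicators |
| `precaution` | 0 | precautionary target shift in sampling-SD units: the effective target moves `precaution * sd` toward the bad side, so passing needs stronger evidence (at target, `precaution = 1` scores $\Phi(-1) \approx 0.159$) |
| `clip_eps` | 1e-9 | pass probabilities are clipped to `[clip_eps, 1 - clip_eps]` (and the chained prior likewise) so no single certain indicator makes the chain absorbing |
| `lambda` | 1 | prior-chaining discount, `prior = lambda * posterior + (1 - lambda) * 0.5`; 1 = full memory |
| `warning_threshold`, `warning_k` | 0.25, 3 | early-warning scan: flag maximal runs of at least `k` years with `p < threshold` or `p > 1 - threshold`. No published convention exists; these are package defaults and fully configurable. |
| `q` (targets) | 0.5 | percentile used when a target is pragmatically derived from the series itself (linear interpolation between order statistics). Proxy targets converted from a related substance (e.g. a DDT-based target applied to its breakdown product) are accepted only as user-supplied fixed values — no conversion chemistry is built in. |

## Indicator selection and the error term

The complement of what the selected indicators explain is carried as an
explicit error term: if the selection represents a share $R^2$ of total
ecosystem variability, $1 - R^2$ is unexplained and is reported alongside
the posterior (`explained_variance` in `ges_assess()`).

`ges_pca()` ordinates the years-by-indicators matrix on the correlation
matrix — indicator units are incommensurable, so z-scoring is forced, and a
constant column is an error, not a silent drop. `ges_rda()` regresses every
standardized response column on the chosen constraint columns and reports
the share of response variance captured by the fitted values (the
constrained axes are the PCA of those fitted values). The constraint columns
are excluded from the response side; including them would inflate the share
with self-explanation. `independence_screen()` computes pairwise partial
correlations given all remaining columns from the inverse correlation
matrix, flagging pairs whose conditional dependence survives — a chain
X → Z → Y is *not* flagged, because X and Y are conditionally independent
given Z.

`select_indicators()` uses greedy forward selection under a *whole-matrix*
accounting: a selected column counts fully, every remaining column through
the squared multiple correlation of its regression on the selection. This
differs deliberately from the response-only share of `ges_rda()` (also
reported per step): under response-only accounting the trajectory is not
monotone — moving a perfectly explained column into the constraint set can
lower the ratio — whereas the whole-matrix share is monotone non-decreasing
and reaches exactly 1 when every column is selected, which is what a
stopping rule (`goal_share`) needs. Ties are broken by column order. An
exhaustive best-subset search is available for up to 12 columns as an oracle
for the greedy path.

## The synthetic generator

`synthetic_spec()`/`generate_indicators()` emulate the statistical structure
of a real monitoring compilation: a small number of latent ecosystem factors
drive many indicators jointly, plus per-indicator linear trends, process
noise, and a reported sampling SD per annual mean. Loadings built from
target variance shares give unit-variance columns in which factor shares and
noise shares sum to one by construction, so PCA recovers the configured
shares (within ±0.05 at 200 years — a tested property). Factors are
Gaussian and, by default, independent across years; an AR(1) option with
unit marginal variance exists for trend-sensitivity experiments.

The `southern_north_sea_like` scenario mimics a 36-indicator coastal
compilation: 24 indicators on a dominant common factor carrying 44% of total
variance (joint response to pressures and policy) and 12 river-load
indicators on a second factor carrying 13%. Under greedy selection the first
two picks take one indicator from each factor — the pattern in which a large
fish indicator represents the dominant axis and a contaminant series the
river axis. The real compilation's published ordination (57% for two
principal components, 42% constrained by two indicators) is *not* shipped
and is not asserted; what the tests show is that the machinery recovers a
known generating structure, not that real data behave this way.

Scenario defaults chosen where no published value exists: `gradual_approach`
sets targets at the year-1 level with a trend of a quarter sampling-SD per
year, so improvement registers as a steadily climbing posterior;
`variable_ges` sets interannual process fluctuation to 5% of the sampling SD
— the strongly buffered regime in which observation uncertainty dominates
ecosystem noise, which is precisely the situation the variability-buffering
argument addresses; `early_warning` parks one of three indicators 1.5
sampling-SDs on the bad side of its target, far enough below the 0.25
warning band that the flag is deterministic in practice.

## Numerical choices and degenerate inputs

* `posterior_ges()` works in log space, so hundreds of indicators do not
  underflow; contradictory certain evidence (a hard 0 and a hard 1 together)
  returns `NaN` with a warning rather than an arbitrary answer.
* Clipping (`clip_eps`) is applied to likelihoods before aggregation and to
  the chained prior, keeping the recursion non-absorbing; the posterior may
  still saturate to machine 1 under overwhelming evidence.
* `sd = 0` is legal and degenerates the likelihood to a step with value 0.5
  exactly at the target.
* Percentile targets use linear interpolation between order statistics
  (`quantile` type 7), the most common convention; the derivation is
  monotone in `q` and invariant to the time-ordering of observations.
* Missing cells in ordination matrices are linearly interpolated inside the
  observed span only; rows still incomplete are dropped with a warning.
  Missing years in an assessment contribute no likelihood factor (`years =
  "union"`), which is exactly equivalent to `p = 0.5` evidence.
* Sample SDs use the n−1 denominator throughout, matching the
  sampling-distribution convention.
* The independence screen needs more rows than columns; otherwise the
  correlation matrix is shrunk toward the identity (default intensity 0.1)
  with a warning rather than failing outright.

## Problem sizes in the test suite

Parameter-recovery and Monte-Carlo properties run at sizes chosen to make
the law-of-large-numbers arguments sharp but cheap: 200-year ensembles for
factor-share recovery, 100 seeds for the variability-buffering band, 1,000
random draws for the posterior-vs-enumeration equivalence, 10 × 6 random
matrices for the ordination oracles. These are the package's standard
reference sizes and are restated in the tests themselves.

## Limitations

* Indicator states are summarised by pass probabilities only; no state-space
  filtering or full posterior of the indicator trajectory is attempted.
* Conditional independence is screened, not enforced; strongly redundant
  indicators double-count evidence if left in the set.
* The lognormal option matches moments of the mean's sampling distribution;
  for small samples of strongly skewed data this is an approximation.
* The generator is Gaussian and linear: no regime shifts, no heavy tails,
  no mechanistic pressure dynamics. Passing tests demonstrate correctness of
  the machinery under the stated generative assumptions, not ecological
  realism.
* Multi-region roll-ups and descriptor hierarchies are out of scope: the
  associative likelihood product makes a flat aggregation sufficient.
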