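---
title: "Detecting common change-points in seasonal consumption panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting common change-points in seasonal consumption panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commoncp)
```

## The problem

Drug-consumption surveillance networks collect quarterly series from many
countries over decades. Three features dominate such data: strong annual
seasonality (winter peaks, summer troughs, driven by seasonal infections);
homogeneity within but heterogeneity between countries; and unbalanced
reporting — countries join the network late, miss individual quarters, or
have not yet submitted recent years. On top of the smooth trend, abrupt
changes can occur after awareness campaigns, reimbursement changes,
shortages or product restrictions. The scientific question is whether such
abrupt changes — change-points shared by all countries — are present, how
many there are, and when they happened.

## The model

`commoncp` fits the non-linear mixed model

$$Y_{it} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t
  + \sum_{k=1}^{K} (\beta_{k+1} + b_{(k+1)i})\,(t - CP_k)_+
  + (\beta_0^S + b_{0i}^S + \beta_1^S t)\,\sin(\omega t + \delta)
  + \varepsilon_{it}$$

with $(x)_+ = \max(x, 0)$. The hinge basis keeps the piecewise-linear trend
continuous at each change-point; $\beta_{k+1}$ is the change in slope after
versus before $CP_k$, so $K = 0$ reduces to a plain linear trend. The
seasonal term is a sine of fixed frequency $\omega = 2\pi/4$ per quarter
with an amplitude $\beta_0^S + \beta_1^S t$ that drifts linearly; $\omega$
is a known constant carried in the model spec, never sampled. Country
random effects $b_{0i}, b_{1i}, b_{(k+1)i}, b_{0i}^S$ are independent
zero-mean normals with component-specific variances (a diagonal covariance
structure; correlated random effects are out of scope), and
$\varepsilon_{it} \sim N(0, \sigma^2_\varepsilon)$ independently. The
likelihood is conditional on the random effects and sums only over observed
cells, which is what makes unbalanced panels unproblematic.

Because all observations share the change-point locations, evidence is
pooled across countries; because each country has its own random slopes,
pooling does not force identical trends.

### Interpretation caveats

The amplitude $\beta_0^S + b_{0i}^S + \beta_1^S t$ is not constrained to be
positive: a negative amplitude is mathematically a phase flip, and the flat
prior on $\delta$ (no angular wrapping) means $\delta$ and $\delta + 2\pi$
describe the same curve. Neither ambiguity affects the fitted mean; both
are worth knowing about when reading raw parameter tables.

## Priors

All regression coefficients, including the phase shift $\delta$, get
Normal(0, 1000) priors — mean 0, **variance** 1000 (equivalently precision
0.001). Change-points get the ordered-uniform stack $CP_1 \sim U(1, T)$,
$CP_k \sim U(CP_{k-1}, T)$, which both spreads the first location over the
whole window and prevents label switching among later ones. $T$ defaults to
the largest observed time index (84 for a 1997–2017 quarterly study).
Variance components get IGamma(0.001, 0.001) in the shape–rate
parameterisation (the reciprocal is Gamma with mean shape/rate). These
choices are deliberately uninformative; the package does not provide
alternative prior families.

## Sampling

The sampler is Metropolis-within-Gibbs, exploiting that the model is linear
in everything except $\delta$ and the change-points:

* **Coefficients + random effects.** The fixed-effect block is drawn from
  its exact Gaussian conditional *with the random effects integrated out*
  (a collapsed draw, computed per country via the Woodbury identity), and
  the random effects are then redrawn from their per-country Gaussian
  conditionals. The pair is a valid joint block update. The collapsing
  matters: under a flat intercept prior, the population intercept and the
  mean of the random intercepts are nearly unidentified, and the naive
  alternating sampler moves through that ridge at a crawl (effective sample
  sizes of ~1% of draws in our experiments); the collapsed draw removes the
  ridge entirely.
* **Variances.** Conjugate inverse-gamma conditionals.
* **Phase shift and change-points.** Random-walk Metropolis. A
  change-point proposal outside its ordered support
  $(CP_{k-1}, CP_{k+1})$ is rejected outright; because $CP_{k+1}$'s prior
  is $U(CP_k, T)$, the move of $CP_k$ also carries the
  $\log(T - CP_k)$ normalising term in its acceptance ratio. Proposals
  that would leave fewer than two observed time points on either side are
  rejected as well — the likelihood is nearly flat there and chains
  otherwise stick at the boundary. Proposal scales adapt toward a
  20–50% acceptance rate during burn-in only, then freeze, so the
  post-burn-in kernel satisfies detailed balance.

Initialisation is deterministic (coefficients 0, variances 1, change-points
at equally spaced positions in the supported range, $\delta = 0$) plus a
small seed-controlled jitter that differentiates chains. The conditional
deviance $-2\log p(y \mid \theta, b)$ is recorded at every retained draw.

The recommended protocol is two chains of 110 000 iterations, 10 000
burn-in, thinning to every 5th draw; thinning matters mainly for the
change-point and phase parameters, whose Metropolis updates are
autocorrelated. All experiments in the package's tests use a scaled-down
protocol (2 chains × 8 000 iterations, burn-in 2 000, thin 2, on panels of
up to 15 countries × 84 quarters), chosen because the collapsed sampler
reaches split R-hat ≤ 1.03 on all fixed effects at that size while keeping
each fit around half a minute.

### Convergence

Trace plots (`autoplot(fit, type = "trace")`) are the visual check;
numerically, convergence is declared when split R-hat — each chain halved,
between- vs within-sequence variance compared — is at or below 1.1 for
every monitored parameter. Effective sample sizes come from pooled
autocorrelations with a Geyer-style truncation at the first non-positive
lag pair. A fit with more change-points than the data support typically
announces itself here, as non-convergence of the surplus change-point and
slope-difference parameters.

## Model selection

`compute_dic()` reports both DIC variants: `dic_pd = dbar + pd` with
`pd = dbar − dhat`, and `dic_pv = dbar + pv` with `pv = var(deviance)/2`.
Two conventions are worth stating because the literature varies:

* The deviance is **conditional** on the random effects, and `dhat` plugs
  in the componentwise posterior means of *all* sampled quantities, random
  effects included. This is the convention of the BUGS lineage of
  hierarchical-model software; the marginal (integrated) DIC is a
  different quantity and is not computed.
* The posterior mean of each change-point is the plain mean of retained
  draws — the same plug-in state is used for `dhat`, for
  `summarize_posterior()` and for the prediction curves, so the reported
  table, the DIC and the figures are always mutually consistent.

`pd` is not invariant to reparameterisation and can go negative; `pv`
cannot, which is why both are reported. `cp_compare()` fits
$K = 0, \dots, K_{max}$, selects the smallest `dic_pd` among converged
fits (a config switch selects by `dic_pv` instead), and reports
non-converged fits without letting them win.

## The synthetic-data generator

Real network data of this kind are not freely redistributable, so
`simulate_panel()` generates panels with the exact statistical structure of
the model: random effects from their variance components, means from the
piecewise-linear-plus-seasonal surface, Gaussian noise, then missingness.
The default generating values are in the magnitude regime of European
community antibiotic consumption — intercept 18.046, trend −0.017 per
quarter, slope changes +0.054 / −0.051 at quarters 29 and 49, amplitude
3.808 shrinking by 0.012 per quarter, phase 0.399, variance components
(40.711, 0.007, 0.029, 0.042, 2.572) and residual variance 1.646. The
change-point locations are rounded to whole quarters (29, 49) for clean
bookkeeping in recovery experiments.

Missingness emulates three motifs of surveillance panels, each completely
at random: 40% of countries enter late by a uniform 1–40 quarters; each
remaining cell drops independently with probability 0.05; 20% of countries
lack a terminal block of uniform 1–12 quarters (up to three years of
not-yet-submitted data; the generator needs a maximum tail length and three
years is a realistic backlog). Because the likelihood just skips absent
cells, MCAR missingness leaves the fit unbiased.

Two deliberate choices: negative simulated values are *kept* (the fitted
model is Gaussian too, so truncation would bias recovery experiments;
`clip_negative = TRUE` exists for display, and panel validation accepts
negatives only from the simulator, never from input files), and the
generator draws pattern-class membership per country as independent
Bernoullis rather than fixing exact counts, so small panels vary
realistically across seeds.

What passing recovery tests on these panels shows is that the sampler
recovers the parameters of *its own* generating process under realistic
MCAR unbalancedness. Real surveillance data depart from this in ways the
generator does not emulate: reporting-policy missingness is not MCAR,
residuals can be autocorrelated and heteroscedastic, seasonality is not a
pure sine, and change magnitudes differ by country. Results on real panels
therefore still need the usual convergence and sensitivity scrutiny.

## Numerical notes

* The IGamma(0.001, 0.001) prior is so heavy-tailed that about half its
  mass lies beyond the largest representable double; inverse-gamma draws
  whose reciprocal would overflow are redrawn, which truncates the prior at
  ~1e300 — irrelevant once any data are present.
* Posterior means of ordered change-points are automatically ordered
  (ordering holds draw-wise), so the plug-in state is always valid.
* `log_prior()` returns $-\infty$ (not an error) outside the support, so it
  can sit directly in acceptance ratios.
* Calendar translation of a fractional change-point index uses its floor:
  index 44.529 lies *inside* quarter 44 (2007 Q4 from a 1997 Q1 origin).
  Rounding would misplace indices with fractional part above one half.
* Degenerate inputs fail fast with diagnostics: an empty panel needs an
  explicit change-point support; a panel with too few distinct time points
  for the requested $K$ is refused with advice to reduce $K$.

## Limitations

Beyond the generator caveats above: change-points are common to all
countries (no country-specific locations or on/off indicators); random
effects are uncorrelated; errors are homoscedastic Gaussian without
autocorrelation; and $K$ is fixed per fit — selection over $K$ is by DIC
comparison, not transdimensional sampling.
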