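---
title: "Estimating the prevalence of a superordinate disorder category"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the prevalence of a superordinate disorder category}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anyprev)
```

## The problem

Epidemiological syntheses often need the prevalence of a *superordinate
category* -- "any anxiety disorder", "any cardiac disorder" -- defined as
having at least one of a fixed panel of D constituent disorders. The
difficulty is that primary studies rarely measure the whole panel: one study
reports panic disorder and PTSD, another only GAD. An "any disorder"
estimate from a study measuring two disorders and one from a study
measuring six are estimates of different quantities, and pooling them
directly biases the category prevalence downward. The common remedies --
ignoring the issue, filtering studies by the number of disorders measured,
or regressing on that number and extrapolating -- are either biased or
inefficient, and `anyprev` implements them only as comparators.

The approach taken here is instead to model the *constituent* disorders
jointly and derive the category prevalence from the joint posterior.

## The model

Let $\mu_{s,d}$ be the probit-transformed prevalence of disorder $d$ in
study $s$, and $\mu_{s,*}$ the vector over the panel. Between studies,

$$\mu_{s,*} \sim \mathrm{MVN}(\theta,\ \Sigma_B), \qquad
  \Sigma_B[d,d'] = \tau_d\, \omega_B[d,d']\, \tau_{d'},$$

with $\theta_d$ the population-level probit prevalence, $\tau_d$ the
between-study SD (heterogeneity) of disorder $d$, and $\omega_B$ a
correlation matrix describing how disorder prevalences co-vary across
study populations. Samples drawn from the same parent study share one
$\mu_{s,*}$ (the package's `cluster_id`), which handles
pregnant/postpartum sample pairs and similar dependencies.

Within a study, aggregate counts follow independent binomials through the
probit link,

$$n_{s,d} \sim \mathrm{Binomial}\!\left(N_s,\ \Phi(\mu_{s,d})\right),$$

and, where individual participant data (IPD) are available, the binary
diagnoses of participant $i$ are modelled as thresholdings of a latent
multivariate normal trait,

$$y_{s,d,i} = \mathbf{1}\{\tilde y_{s,d,i} > 0\}, \qquad
  \tilde y_{s,*,i} \sim \mathrm{MVN}(\mu_{s,*},\ \omega_C),$$

with unit variances, so that $\omega_C$ is the latent (tetrachoric-style)
comorbidity correlation. For IPD samples this likelihood *replaces* the
aggregate binomial. `fit_model1()` covers the aggregate-only case and
requires $\omega_C$ to be supplied; `fit_model2()` estimates $\omega_C$
from the IPD, propagating its uncertainty into all downstream summaries.
Reported "any disorder" counts are never used by the Bayesian models; they
feed only the univariate comparators.

### Priors and their calibration

* $\theta_d \sim N(-1.88,\ 0.30^2)$. On the prevalence scale this makes
  values between roughly 0.6% and 10% probable within two prior SDs
  (`prior_prevalence_range(-1.88, 0.30)`), a deliberately mild prior for
  panels of rare disorders. For common disorders the location should be
  moved; the diffuse alternative `theta_sd = 1` admits prevalences up to
  ~55%.
* $\tau_d \sim$ half-normal(0.25), making between-study SDs above 0.5
  unlikely. At a 3% mean prevalence, $\tau = 0.5$ already lets true study
  prevalences range from about 0.2% to 19%
  (`implied_study_range(0.03, 0.5)`), which is wide for most applications.
  Heterogeneity interacts with the probit scale: for prevalences below 50%,
  larger $\tau$ *raises* the category prevalence at fixed $\theta$, because
  the right tail gains more probability mass on the proportion scale than
  the left tail loses.
* $\mathrm{Chol}(\omega_B), \mathrm{Chol}(\omega_C) \sim \mathrm{LKJ}(2)$,
  mildly concentrated toward moderate correlations.

All four hyper-parameters are fields of `prevalence_priors()`.

## Posterior computation

The sampler is an adaptive Metropolis-within-Gibbs scheme written in
C++ (Rcpp/RcppArmadillo):

* $\theta$ has a conjugate MVN full conditional and is Gibbs-updated.
* $\mu_{c,d}$ and $\log\tau_d$ take coordinate-wise adaptive random-walk
  updates (Robbins-Monro adaptation to 44% acceptance, warmup only).
* The correlation matrices are sampled on an unconstrained scale: tanh
  canonical partial correlations mapped to a Cholesky factor, with the
  exact LKJ density plus transform Jacobian. A prior-only run reproduces
  the analytic LKJ marginal, which the test suite checks.
* Two interleaved group moves break the funnel geometries that defeat
  plain random-walk samplers in hierarchical models: a *scaling* move that
  proposes $\tau_d$ while rescaling every cluster's deviation
  $\mu_{c,d}-\theta_d$ (the MVN prior and proposal Jacobian cancel
  exactly), and a *translation* move that shifts $\theta_d$ and all
  $\mu_{c,d}$ together (the prior is invariant). These matter when
  $\tau_d$ is small and $\mu$ is effectively welded to $\theta$.
* IPD enter by truncated-normal Gibbs data augmentation of the latent
  traits. Disorders a sample did not measure are *marginalized out* of the
  latent MVN rather than imputed as latent columns -- the marginal of an
  MVN over a coordinate subset is the sub-correlation matrix, so the
  posterior is identical, while the augmented chain mixes considerably
  better. Study-level prevalences of unmeasured disorders are still fully
  recovered through the between-study layer.

`sampler_config()` exposes chains (default 4), iterations/warmup (defaults
5,000/2,500), a seed (chains derive deterministic sub-seeds), and a `thin`
factor (default 8): the number of cheap internal sweeps per recorded
iteration. Random-walk sweeps are so much cheaper than a gradient-based
transition that thinning is the natural way to buy effective samples.

**Known limitation.** The autocorrelation of the $\omega_C$ chain grows
with the number of IPD participants: conditional on the latent traits,
$\omega_C$ is pinned near their empirical correlation, so the recorded
chain moves through $\omega_C$-space slowly when the IPD block is very
large and a pair of disorders is weakly identified. This is the classic
behaviour of probit data augmentation. The convergence report
(`convergence_report()`, split-R-hat $\le 1.05$ and effective sample size
$\ge 200$ on every parameter) flags any fit where this bites; the remedy
is a larger `thin`. Gradient-based samplers move latents and correlations
jointly and do not share this cost profile; within this package the
diagnostics-plus-thinning contract is the supported route.

## From the posterior to category quantities

The category prevalence is a functional of the joint posterior, estimated
by simulating hypothetical participants (`category_prevalence()`): for
each posterior draw $m$, draw `n_inner` new studies
$\mu^* \sim \mathrm{MVN}(\theta^{(m)}, \Sigma_B^{(m)})$, one participant
each from $\mathrm{MVN}(\mu^*, \omega_C^{(m)})$ thresholded at zero, and
record the proportion $\pi_m(k)$ with at least $k$ diagnoses. The summary
is the median and 95% HDI over $\{\pi_m\}$ -- posterior uncertainty --
with person-level Monte-Carlo noise suppressed by the inner loop (default
`n_inner = 1000`). The 95% *prediction interval* for a single new study
uses one shared new study per posterior draw instead, so it adds the
between-study spread and is never narrower than the HDI. The same
machinery yields conditional comorbidity probabilities
(`conditional_probability()`, with a numeric bivariate-orthant fallback
when the conditioning event is too rare to simulate) and per-study
posterior predictive checks (`per_study_predictions()`, which simulates
each sample at its own size $N_s$ and cluster-level $\mu$, including
predictions for disorders the sample never measured).

For Model 1 output, $\omega_C$ in these simulations is the user-supplied
known matrix; sensitivity to that choice should be explored by refitting
with alternatives (it enters only the joint behaviour, not the margins).

## Univariate comparators

`frequentist_table()` reproduces standard practice from first principles:
logit-transformed any-disorder proportions with variances
$1/(Np) + 1/(N(1-p))$, REML estimation of the between-study variance by
direct maximization of the restricted log-likelihood (tolerance $10^{-8}$,
floored at zero), inverse-variance pooling and Wald-z intervals, with no
Knapp-Hartung adjustment -- matching the defaults of the standard
meta-analysis toolchain, which the test suite uses as an independent
oracle (agreement to 4 decimal places on random datasets). Samples with a
0% (or 100%) any-disorder estimate receive the customary only-zero-cells
correction of +0.5 events and +1 to $N$. Clustered samples are deliberately
treated as independent here, faithful to the practice these comparators
represent. The five variants are FRE (all eligible samples), FRE-H (at
least half the panel measured), FRE-A (full panel only), and FRE-M/FRE-MH
(meta-regression on the number of disorders measured, extrapolated to the
full panel, on the FRE/FRE-H sets).

## The synthetic-data generator

`generate_meta_analysis()` draws study sizes as
$100 + \mathrm{round}(\mathrm{Exp}(0.005))$ (mean 300), study effects from
the between-study MVN, diagnoses from the latent comorbidity MVN, and then
applies a *measurement process*: disorder $d$ is included in a study's
panel with probability `incl_prob[d]`, independently (a study drawing an
empty panel redraws, which avoids favouring any particular disorder); the
first two studies are exempt and measure everything, and the first seven
studies contribute IPD for their measured disorders. The three presets
(`preset_config()`) hold the documented study conditions: case-study-like
prevalences 1.5-6% with mixed heterogeneity (sim1), and more diverse
prevalences 1-9% with uniformly low ($\tau = 0.1$, sim2) or high
($\tau = 0.4$, sim3) heterogeneity, all with measurement probabilities
50/50/70/50/70/40%. The correlation matrices behind the original
conditions were posterior medians from a case-study fit and are not
published, so the presets default to exchangeable $\omega_B = \omega_C$
with $\rho = 0.3$ -- a realistic moderate-comorbidity choice -- and both
matrices are ordinary config fields that callers can replace. sim2 and
sim3 reuse sim1's inclusion probabilities.

What the generator does *not* emulate: the preponderance of
single-disorder studies found in real literatures (inclusion is
independent per disorder), heterogeneity in $\omega_C$ across studies
(the model assumes homogeneity too), and any form of measurement or
selection bias. Passing recovery tests on these synthetic conditions
therefore demonstrates correctness of the machinery under the model's own
assumptions, not robustness to violations of them.

The generating process's "true" category prevalence is defined
operationally (`true_category_prevalence()`): simulate participants --
each from its own fresh study -- in replicates, and take the median
proportion with $\ge k$ disorders. With $\tau = 0$ and identity $\omega_C$
this reproduces $1 - \prod_d (1 - p_d)$, an identity the tests verify by
brute-force enumeration of all $2^D$ outcomes.

## The evaluation harness

`evaluate_methods()` runs the comparators and (optionally) both Bayesian
models over replicated synthetic meta-analyses and reports, per method,
the median estimate, median bias, 95%-interval coverage with its binomial
Monte-Carlo error, mean interval width, and -- for the meta-regression
variants -- the power of the two-sided Wald slope test at $\alpha = 0.05$.
Coverage is always judged against the generator's own brute-force truth,
not an analytic shortcut. Method failures on degenerate replicates (for
example a constant disorder-count predictor) are recorded per replicate
and excluded, never fatal to a batch.

## Numerical choices and problem sizes

* `hdi()` is the shortest contiguous interval containing
  $\lceil 0.95\,n\rceil$ sorted draws.
* Truncated normals use rejection sampling (plain below the mode,
  translated-exponential in the tail).
* The bivariate orthant probability used by oracles and the
  conditional-probability fallback is a one-dimensional adaptive
  quadrature, accurate to ~$10^{-10}$.
* The test suite exercises full-scale fits only where needed (the
  case-study convergence check runs 4 chains at 3,000 iterations);
  parameter-recovery experiments use 25 replicates with 2 chains and a few
  hundred recorded iterations each, and simulation coverage uses 100
  replicates of the frequentist methods with the brute-force truth at
  4,000 participants x 400 replicates. These sizes were chosen so the
  whole suite exercises every claim at honest Monte-Carlo tolerances.

## Limitations

* Model 1's conclusions are conditional on the supplied $\omega_C$;
  without IPD the comorbidity structure is not identifiable from aggregate
  margins.
* $\omega_C$ is assumed homogeneous across studies.
* No covariate (meta-regression) term is implemented in the Bayesian
  models.
* The case-study fixture reconstructs integer counts from published
  percentages by rounding, the resolution available in print.
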