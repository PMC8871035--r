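---
title: "Inference for two IERD samples under joint progressive type-II censoring"
author: "ierdjpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference for two IERD samples under joint progressive type-II censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ierdjpc)
```

## The model

The inverted exponentiated Rayleigh distribution (IERD) has cdf

$$F(x;\theta,\lambda) = 1-\bigl(1-e^{-\lambda/x^{2}}\bigr)^{\theta},
  \qquad x>0,\ \theta,\lambda>0,$$

with shape $\theta$ and scale $\lambda$ (units of $\lambda$: squared
lifetime units). Its hazard rises and then falls, which suits lifetimes of
mechanical and electrical components or patient survival better than
monotone-hazard families. The quantile function is available in closed
form, so `rierd()` uses inverse-transform sampling.

We consider two independent samples with a shared scale: sample A of size
$m$ from IERD$(\theta_1,\lambda)$ and sample B of size $n$ from
IERD$(\theta_2,\lambda)$, pooled on one life test under *joint progressive
type-II censoring* (JPC). A design fixes the number of observed failures
$k$ and a removal vector $r_1,\dots,r_k$ with $\sum_i (r_i+1) = m+n$: at
the $i$-th failure, $r_i$ surviving units are withdrawn from the pooled
risk set, all of them at the $k$-th. The observed record is
$(w_i, s_i, t_i, z_i)$: the failure time, the withdrawal counts from each
sample, and the source indicator. Only $r_i$ is fixed; its split
$(s_i,t_i)$ is random.

## What the simulator emulates — and what it does not

`simulate_jpc()` draws the two complete samples, then `apply_jpc()` runs
the censoring mechanism. Two conventions are deliberately pinned down
because the scheme's verbal description leaves them open:

* **Withdrawals are uniform.** The $r_i$ withdrawn units are sampled
  uniformly without replacement from the pooled survivors, so $(s_i,t_i)$
  is hypergeometric given the risk-set composition. Any exchangeable rule
  yields the same likelihood, but finite-sample summaries (e.g. Monte
  Carlo tables) can shift slightly under other rules.
* **Ties break by stable position, sample A first.** Ties have probability
  zero under the model but occur in rounded real data; the rule is
  deterministic and seed-independent.

Records in which every failure comes from one sample ($k_1=0$ or $k_2=0$)
are returned with `is_degenerate()` set, never silently redrawn: the
likelihood is then strictly decreasing in the unrepresented shape, so no
MLE exists. The fitting functions refuse such records; the bootstrap and
the study driver redraw them and report the count.

The generator reproduces the study conditions exactly (the true triple
$(\theta_1,\theta_2,\lambda)=(3,2,2)$ and the published designs are the
defaults in the study driver and acceptance checks). It does not emulate
features of real coating data such as measurement rounding or any
dependence between the two production sides, so passing simulation tests
demonstrates correctness of the machinery, not adequacy of the IERD for
any particular dataset — that is what the K-S check is for.

## Maximum likelihood: EM with a one-dimensional M-step

The observed-data log-likelihood couples the three parameters only through
$G_i(\lambda)=\log(1-e^{-\lambda/w_i^2})$. `em_fit()` treats the withdrawn
units' lifetimes as missing data. With $y=\lambda/u^2$, a missing lifetime
truncated to $(w,\infty)$ maps to an exponentiated-exponential variable
truncated to $(0, \lambda/w^2)$, under which the three E-step expectations
are one smooth, one-dimensional integral each — and
$E[\log(1-e^{-\lambda/U^2})\mid U>w]$ collapses to the closed form
$\log(1-e^{-\lambda/w^2})-1/\theta$ when the integrand and the conditional
law share the same $\lambda$.

Each iteration maximizes the pseudo log-likelihood over $\lambda$ by a
bounded scalar search on $\log\lambda$ (bracket $[\lambda_0/100,
100\lambda_0]$ around the incoming iterate, expanded on boundary hits),
then updates the shapes in closed form. One design point deserves record:

* **The conditional law is frozen at the previous iterate during the
  $\lambda$ search.** The tempting shortcut — letting the candidate
  $\lambda$ enter the conditional density as well, which makes every
  E-step moment closed-form — defines a different fixed point: iterating
  it from the likelihood maximum walks away and settles at a strictly
  lower log-likelihood. Freezing the law restores the Fisher identity
  $\partial Q/\partial\lambda = \partial\ell/\partial\lambda$ at the
  current iterate, so the MLE is the fixed point and the ascent property
  holds. The shape updates may use the freshly maximized $\lambda$ inside
  both density and integrand: that update's stationary point coincides
  with the observed-score root (substituting the closed form into the
  update and solving reproduces $\hat\theta_1=-k_1/\sum_i(z_i+s_i)G_i$),
  so the shortcut is harmless there and is used.
* The $-3E[\log U]$ terms carry no parameter once the law is frozen and
  are dropped from the M-step objective; `conditional_moments()` still
  computes `e_log_u` and it is tested against quadrature.

Iterations stop when all three absolute parameter changes are at most
`tol` ($10^{-4}$ by default, `max_iter` 500). `direct_fit()` maximizes the
same log-likelihood with a general-purpose optimizer (Nelder–Mead then a
BFGS polish, in log-parameter space) and serves as the permanent
cross-check; the test suite requires agreement below $10^{-3}$ relative on
a battery of twenty censored datasets. Default starting values profile the
shapes out of the observed likelihood at
$\lambda_0 = \mathrm{median}(w)^2\log 2$ (exact for a unit-shape IERD
median).

## Observed information and estimator covariance

`observed_info()` uses the missing-information principle: expected
complete information of all $m+n$ units minus the expected information of
each censored lifetime given survival past its withdrawal time. All second
partials of the log-density are analytic; the $(\theta_1,\theta_2)$
cross-entries vanish because each unit involves one shape only, and
$-\partial^2\log f/\partial\theta^2 = 1/\theta^2$ exactly. The remaining
entries are expectations computed by adaptive quadrature on the
probability-scale substitution used throughout, with integrands assembled
in log space so early censoring times ($\tau\to 1$) and late ones
($\tau^\theta$ underflow) are both safe. Every entry is tested against a
finite-difference-plus-quadrature oracle. `estimate_covariance()` inverts
the matrix and raises a conditioning error (with eigenvalues) rather than
substituting a pseudo-inverse; the Bootstrap-t loop treats that error as
"drop this replicate".

## Bootstrap intervals

`bootstrap_p()` refits $N$ parametric replicates simulated from the fitted
triple under the same design and returns percentile intervals at the
$\lfloor \alpha N/2\rfloor$ and $\lfloor(1-\alpha/2)N\rfloor$ order
statistics (1-based, clamped). `bootstrap_t()` studentizes each replicate
by its own information-based standard error. Degenerate replicates are
redrawn (counted, capped at `10 * n_boot`); replicates with an
ill-conditioned information matrix are dropped, with an error beyond 20%.
Replicate refits start at the parent estimates. Both functions expose the
raw replicates and pivots so the interval arithmetic can be recomputed
externally, and both accept `fit_method = "direct"` where wall-clock time
matters more than matching the EM route (the two agree to $10^{-3}$).

A finding worth flagging: with the studentization defined exactly as
above, Bootstrap-t intervals in this model's right-skewed regime come out
*narrower* than Bootstrap-p for the shape parameters — the replicate
standard error grows with the replicate estimate, compressing the pivots —
which reverses the pattern usually quoted for these two methods. The
acceptance suite records this as a failed qualitative expectation rather
than papering over it.

## Bayesian estimation by importance sampling

With independent gamma priors (presets: informative $(2,1,1,2,3,2)$ and
near-flat $10^{-4}$ everywhere), the shapes are conditionally conjugate
given $\lambda$, and the marginal scale posterior factors into a gamma
kernel $Ga(c+k,\ d+\sum_i w_i^{-2})$ times a correction
$B_1^{-(a_1+k_1)}B_2^{-(a_2+k_2)}\prod_i(1-e^{-\lambda/w_i^2})^{-1}$.
`importance_sample()` draws $\lambda$ from the gamma kernel, the shapes
from their conditional gammas, and normalizes the correction as the
importance weight by log-sum-exp. The conditional gamma rates are provably
positive and asserted on every draw. $M$ defaults to 5000.

The gamma kernel is a good proposal only while the correction factor says
little about the scale. That holds for very small records, but its
effective sample size degrades as the censored sample grows, and for data
like the coating weights — where large fitted shapes place the scale
posterior (quadrature-verified to sit near the MLE) far into the
proposal's right tail — it collapses to a handful of draws regardless of
$M$, which the test suite pins down as ESS below 1% of $M$ on that
record. The default proposal is therefore `"laplace"`: a gamma matched to
the mode and curvature of the exact log marginal posterior, weighted by
the full target-to-proposal ratio, which reproduces a deterministic
quadrature oracle to Monte Carlo accuracy with near-full effective sample
size. The textbook decomposition remains available as
`proposal = "conjugate"` and is tested against the same oracle on a small
record; `ess` is always reported and is the thing to check first.

Point estimates: the posterior mean under squared-error loss
(`estimate_square()`) and the linex estimator
$-\delta^{-1}\log E[e^{-\delta g}]$ (`estimate_linex()`, shifted
log-sum-exp, default $\delta=2$; for $\delta>0$ it sits below the
posterior mean by Jensen's inequality and tends to it as
$\delta\to 0$). `credible_interval()` walks the cumulative sorted weights
to the first index reaching $\alpha/2$ and the last below $1-\alpha/2$;
with all weight on one atom the interval degenerates to a point, which is
allowed.

## Model checks for complete samples

`complete_mle()` profiles the shape out analytically and searches the
scale on a log grid to tolerance $10^{-10}$. `ierd_ks_test()` computes the
two-sided sup distance
$\max_i\max(|F(x_{(i)})-i/n|,\ |F(x_{(i)})-(i-1)/n|)$ against the
asymptotic 95% critical value $1.36/\sqrt n$ — the constant that
reproduces the conventional 0.1603 at $n=72$. `lrt_common_scale()` tests
$H_0:\lambda_1=\lambda_2$ by a likelihood ratio between the four-parameter
full model and the three-parameter common-scale model, referred to
$\chi^2_1$; a chi-squared reference (rather than a parametric-bootstrap
null) is the standard choice for this regular nested comparison and is
what the package commits to. The coating-weight loader divides the raw
values by 10 by default (`scaled = FALSE` gives the raw record).

## Monte Carlo study driver

`run_point_study()` and `run_interval_study()` simulate replicate
datasets, apply the requested estimators or interval methods, and report
AV/MSE and AL/CP per parameter; summaries are recomputed from stored
per-replicate results (and tested to be bit-identical). Per-replicate
seeds derive arithmetically from the master seed, so results are
reproducible and independent of execution order. Degenerate draws are
redrawn and counted — the published tables implicitly condition on the
MLE existing — and estimator failures beyond 5% of the study abort it.

Problem sizes used by the packaged checks: the test suite runs the
EM-versus-direct battery on twenty datasets across five designs, the
acceptance study 300 replicates of the $m=25$, $n=20$, $k=30$ design, and
the interval properties on a few hundred replicates with reduced $N$ and
$M$; these sizes give Monte Carlo standard errors small enough for the
qualitative assertions being made while keeping a full run in minutes on
one core.

## Known limitations

* The conjugate importance proposal is reliable only on very small
  records; the Laplace default is the supported route elsewhere (see
  above).
* Bootstrap-t inherits the instability of information-based variances at
  small $k$; replicates are dropped on conditioning failures, and more
  than 20% drops abort.
* The EM route evaluates E-step quadratures at every $\lambda$ candidate;
  for heavily censored designs `direct_fit()` is 1–2 orders of magnitude
  faster and agrees to the tested tolerance. The EM remains the reference
  implementation of the published procedure.
* No type-I, hybrid, or multi-sample censoring variants; one common scale
  shared by exactly two samples.
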