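---
title: "Entropy-balanced weighted PWP models for recurrent events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-balanced weighted PWP models for recurrent events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repwp)
```

## The model and its assumptions

Recurrent clinical events rarely arrive at a constant rate: a prior fall
raises the hazard of the next one, heart-failure hospitalizations cluster
ever closer together. The Prentice–Williams–Peterson (PWP) model captures
this by stratifying the Cox partial likelihood on the event number, so
each recurrence `k` has its own baseline hazard. In the gap-time variant
the clock restarts at each event:

$$h_{ik}(t) = h_{0k}(t - t_{k-1})\, e^{A_i \beta},$$

and `repwp` follows the common convention of treating the gap-time
variant as *the* PWP model (the counting-process variant is available as
`fit_pwp_cp()`). The treatment effect is summarized as the hazard ratio
$e^\beta$, which under proportional hazards, non-informative censoring,
SUTVA, and — critically — randomization *within every risk set*, is also
interpretable as an average cumulative hazard ratio.

The fourth assumption is the problem. Risk set `k > 1` contains only
subjects whose event `k - 1` was observed. Membership is a
post-randomization outcome, so conditioning on it opens a collider path:
in arm comparisons within later risk sets, prognostic covariates are no
longer balanced, and the treatment coefficient picks up their effect.
The direction is predictable — the surviving treated subgroup is
selectively frailer, so the PWP estimate drifts toward the null — while
single-baseline models (Andersen–Gill, Poisson) drift the other way when
the baseline hazard actually rises with the event number, because they
misread the event-number dependence as a rate effect.

### The weighting correction

For each risk set `k > 1`, `fit_weighted_pwp()` constructs weights that
minimize the Kullback–Leibler divergence
$D_1(\omega \| d) = \sum_i \omega_i \log(\omega_i / d_i)$ from uniform
reference weights `d`, subject to first-moment balance: within each arm,
the weighted mean of every balance covariate must equal the *pooled*
risk-set mean, and the weights of each arm must sum to the arm's size.
Both arms are reweighted toward the same pooled target — two independent
convex problems, one per arm — which is what the three-way equality of
the balance constraint demands. The first risk set keeps unit weights:
it is the intact randomized sample. Only the KL member of the Rényi
divergence family is implemented, and only first-moment constraints; both
are the standard choice and the constraint order is deliberately not a
tuning knob.

The solution has the exponential-tilting form
$\omega_i \propto d_i e^{\lambda' u_i}$ within each arm. The dual is
smooth and strictly convex; `entropy_balance()` solves it by damped
Newton iterations (per-arm dual variables, one per covariate), declaring
convergence when the largest constraint violation falls below `1e-8` —
orders of magnitude below any balance diagnostic — with a cap of 200
iterations. Infeasibility has a clean geometric meaning: the pooled
target lies outside the convex hull of one arm's covariate values. The
coordinate-wise (box) case is detected up front and reported as a classed
error naming the stratum and covariate; higher-dimensional infeasibility
surfaces as dual divergence and is reported as non-convergence.

The weighted stratified partial likelihood is maximized by
Newton–Raphson with step halving (convergence when the step falls below
`1e-9` and the score below `1e-8` relative to the total weighted event
count, the achievable floating-point floor at realistic data sizes; 50
iterations maximum; coefficients beyond ±20 are declared monotone
likelihoods). Ties are handled with the Breslow approximation, which
extends cleanly to weighted likelihoods; the simulator's continuous times
make ties measure-zero, and on the bladder data Breslow reproduces the
standard published estimates. The variance is a robust sandwich with the
subject as cluster: each subject's weighted score residuals are summed
across all rows and strata before the outer product. Weights are treated
as fixed constants — no correction for their estimation — a documented
limitation shared with standard practice.

## Truncation rules

Late risk sets are small, and balancing them is either impossible or
meaningless. Two rules are provided and composed:

* **Eligibility**: a stratum qualifies only if both arms have at least
  two members (`eligible_strata()` returns the largest qualifying
  prefix). This is the minimum for the balancing problem to be posed.
* **SMD truncation** (default): after solving the weights,
  `kmax_by_smd()` finds `k_max`, the first stratum whose weights failed
  or whose post-weighting standardized mean difference reaches 0.1 for
  some balance covariate; strata from `k_max` on are dropped.

On the bladder data the two rules genuinely differ: stratum 6 passes
eligibility (6 control, 3 treated) but its treated tumour counts are all
5–6 against a pooled target of 3.4 — outside the hull, unbalanceable —
so the SMD rule truncates at 5 strata. The SMD rule is the default
because retaining a stratum that cannot be balanced defeats the purpose
of the weighted model. The SMD denominator is the *unweighted* pooled
standard deviation of the whole risk set, so pre- and post-weighting
values share a scale.

Stabilized inverse-probability weights
(`sw = P(A)/P(A|X)`, main-effects logistic model per risk set) are
available as `weighting = "ipw"`. They need no feasibility condition but
inherit the instability of propensity weights in small strata; with no
truncation they are the package's reproduction of the known failure mode
of unrestricted IPW in late strata.

## The simulator

`simulate_trial()` emulates a two-arm trial whose gap times are Weibull
with event-number-dependent parameters: survival
$S(t) = e^{-\lambda t^q}$ with
$\lambda = e^{-q(\beta_0 + A\beta + X'\gamma)}$, so effects map to
hazard ratios via $HR = e^{-q\beta}$ (`coef_from_hr()`). The four study
scenarios share shape $q = 1.5$ and per-event baselines
$\beta_0 = (6, 5.5, 5, 4, 3)$ — the hazard rises steeply with the event
number, the regime in which model choice matters — and cross a null
(HR 1) or protective (HR 0.75) treatment with five iid N(0,1) covariates
of common hazard ratio 0.9 or 1.2. Arms are Bernoulli(0.5); events
beyond the fifth reuse the last parameters. Follow-up is administrative
at 730 time units, read as days: two years of daily-scale follow-up
gives a baseline subject a 91% first-event probability, whereas a scale
of years would make events essentially impossible under these parameter
values, so days is the only reading that yields a meaningful trial. The
gap that crosses follow-up is recorded as a censored interval truncated
at the boundary — the standard counting-process convention. Generation
is by inverse-transform sampling, one `set.seed()` per trial.

What the generator does *not* emulate: informative censoring, risk-free
intervals, event-specific treatment effects, unmeasured frailty, and
calendar-time dependence of the baseline hazard (the gap-time clock
restarts at every event). Passing tests therefore demonstrate correct
behaviour under exactly this mechanism — covariate-driven collider bias
with everything measured — not robustness to misspecification on real
data.

## The Monte Carlo harness

`run_study()` simulates, fits, and aggregates: bias on the HR scale
(log-HR also reported, since reasonable readers disagree on the natural
scale), and the rejection rate of the two-sided 5% Wald test (type I
error under null scenarios, power otherwise) with Monte Carlo standard
error $\sqrt{\hat p(1-\hat p)/n_{sim}}$. A CI endpoint exactly at 1
counts as non-rejection — a measure-zero convention. Replicates where a
model fails (monotone likelihood, singular information) are excluded
from that model's summaries and counted in `n_failed`; at the study's
sample sizes failures are rare. Replicate seeds are pre-drawn from the
root seed, so studies are exactly reproducible and models see identical
data streams — which is also what makes the AG and LWYY per-replicate
estimates exactly equal, as they must be.

The package's own calibration runs (tests and `scripts/acceptance.R`)
use 1000 replicates per cell rather than a reference-scale 10000: at
1000 replicates the Monte Carlo standard error of a 5% rate is 0.7
percentage points, sharp enough to separate a calibrated test from the
several-fold inflations at issue, and a full cell runs in minutes on one
core. The headline property-level checks are at `n = 500`: weighted-PWP
mean HR within Monte Carlo error of the generating 0.75, and first-gap
distributions matching the closed-form Weibull survival by
Kolmogorov–Smirnov at `n = 5000`.

## Numerical and design choices

* **Degenerate inputs.** Zero-length at-risk intervals are rejected, not
  jittered — the simulator cannot produce them and in real data they
  signal a recording error. Histories with no events at all are an
  error for any partial-likelihood fit.
* **Constant covariates** in a balancing problem are dropped from the
  Newton step when they already match the target (trivially satisfied)
  and reported as infeasible otherwise.
* **Scaling.** Balance constraints are solved on a centred, max-scaled
  parameterization for conditioning; violations are reported on the
  original covariate scale.
* **Partly weighted models.** Which covariate subset defines the
  "partly weighted" variant is a user choice (`balance_covariates`);
  the study harness's `wpwp3` uses the first three of the five simulated
  covariates. Since the five are exchangeable by construction, the
  choice is immaterial in simulation.
* **Rate models.** The exposure offset is total follow-up time —
  identical to the sum of gap times here, as there are no risk-free
  intervals. The negative binomial is NB2 (gamma frailty) with ML
  dispersion, reducing to Poisson as dispersion vanishes.
* **Counting-process PWP** is provided for completeness; the gap-time
  variant is the default throughout, matching the headline model.

## Known limitations

Hazard ratios are non-collapsible: with covariates in the
data-generating mechanism, the estimand of an unadjusted marginal
analysis sits slightly nearer the null than the covariate-conditional
hazard ratio, even in a perfectly randomized comparison. With five
covariates of hazard ratio 0.9 this gap is under one percentage point on
the HR scale — visible to a Monte Carlo mean over hundreds of
replicates, irrelevant to any single trial, and shared by every
unadjusted model in the package including the weighted PWP.

The weighted model corrects only for *measured* covariates; unmeasured
heterogeneity (frailty) is out of scope, as are time-varying covariates,
competing risks, event-specific treatment effects, and weight-estimation
corrections to the sandwich variance. The balance diagnostic and
truncation default (SMD < 0.1) are conventions, not optimality results.
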