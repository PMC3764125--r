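---
title: "Modelling monthly contrast-enhancing lesion counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling monthly contrast-enhancing lesion counts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celdyn)
```

## The problem

Relapsing–remitting multiple sclerosis produces focal inflammatory events
that appear on monthly T1-weighted post-contrast MRI as contrast-enhancing
lesions (CELs). The monthly CEL count is a non-negative integer with two
awkward properties: it is overdispersed (per-patient variance typically
exceeds the mean over a multi-year window) and serially dependent (a month
with many lesions tends to be followed by another, partly because a lesion
can keep enhancing for more than one scan). `celdyn` implements a population
(nonlinear mixed-effects) analysis of such series: a ladder of discrete
count distributions with Markov lagged-count terms and a steroid-month
covariate, estimated by Laplace-approximate marginal maximum likelihood, and
evaluated by simulation-based predictive checks and a dose-randomization
test. A synthetic cohort generator with the same structure makes every stage
testable without patient-level data.

## The model ladder

Sixteen structural models built from seven count families are available by
name through `model_ladder()`:

* **PS** — Poisson with rate $\lambda_0$; equi-dispersed.
* **PMAK1** — Poisson whose rate switches between $\lambda_1$ (previous
  month lesion-free) and $\lambda_2$ (at least one CEL in the previous
  month).
* **PMAK2 / nested / nested nested** — Poisson with additive lagged-count
  terms (order 1–3).
* **PMIX** — per-observation mixture of two Poisson components with mixing
  probability $MP$.
* **ZIP** — zero-inflated Poisson with extra zero mass $P_0$.
* **GP (± MAK2)** — Consul–Jain generalized Poisson,
  $P(Y{=}n) = \lambda(\lambda + n\delta)^{n-1} e^{-(\lambda + n\delta)}/n!$,
  with dispersion $\delta \in [\max(-1, -\lambda/4),\, 1)$ allowing over-
  and under-dispersion.
* **NB (± MAK2 orders, ± steroid) and ZINB** — negative binomial
  (Poisson–Gamma mixture) with mean $\lambda$ and variance
  $\lambda(1 + OVDP\,\lambda)$, optionally zero-inflated.

The Markov ("MAK2") conditional mean is **additive** in the realized lagged
counts:

$$\lambda_{it} = \lambda_0 e^{\eta_{1i}} \;+\;
  \theta_{PDV}\, e^{\eta_{2i}}\, y_{i,t-1} \;+\;
  \theta_{PPDV}\, y_{i,t-2} \;+\; \theta_{PPPDV}\, y_{i,t-3},$$

with $\eta_{ji} \sim N(0, \omega_j)$ log-normal inter-subject random
effects. We chose the additive form over a multiplicative-exponential one
(`exp(θ·PDV)`) because observed counts reach 10–20, where an exponential
term explodes; the additive form is also the only one consistent with
first-order coefficients near 0.4 alongside stationary 48-month
trajectories. Random effects enter multiplicatively
(parameter $\times\, e^{\eta}$) with $\omega$ the **variance** of $\eta$;
inter-subject variability is reported as $CV\% = 100\sqrt{\omega}$. This
convention is used consistently everywhere (the alternative
$100\sqrt{e^{\omega}-1}$ convention exists in the field; mixing the two
changes reported CV% by several points at these magnitudes).

Lags that would refer to pre-study months are set to zero, i.e. the
likelihood conditions on an assumed lesion-free run-in. This keeps all $T$
monthly contributions and matches the usual longitudinal-count dataset
convention; `drop_initial = TRUE` in `fit_model()` instead drops the first
`order` months from the likelihood for sensitivity analysis.

### The steroid covariate

Steroid courses (methylprednisolone or a prednisone taper, given for
clinical relapses) are coded as a 0/1 month flag. The steroid model
**replaces** the first-order coefficient in dosed months:
$\theta_{PDV} \to \theta_{PDV\_S}$, sharing $\eta_2$. A replacement
coefficient (rather than a fractional multiplier) maps directly onto the
reported estimate tables; the attenuation is recovered as
$100(1 - \theta_{PDV\_S}/\theta_{PDV})$ via `steroid_attenuation()`. The
biological reading: steroids help resolve lesions persisting from the
previous month but do not prevent the month's new lesions. A carryover
variant (effect in the month after administration) is available through
`steroid_carryover`.

The published estimate table for the steroid model lists
$\theta_{PDV\_S} = 0.145$ and $\theta_{PPDV} = 0.150$, while the model
summary table and the reported 66.44% attenuation
($100(1-0.150/0.447) = 66.44$) imply the transposed reading
($\theta_{PDV\_S} = 0.150$, $\theta_{PPDV} = 0.145$). The package's
reference parameter set (`cohort_reference_params()`) adopts the transposed
reading; both are representable, and nothing downstream hard-codes either.
Similarly, the percentage changes reported between the base and steroid
models mix denominators (the $-1.80\%$ and $-14.86\%$ changes are relative
to the base-model estimate, the $+3.80\%$ change relative to the
steroid-model estimate); `percent_change()` exposes both conventions
explicitly.

One further table ambiguity: the second-order Poisson Markov model prints
its second random effect as if it were on $\theta_{PPDV}$, while every other
Markov row places it on $\theta_{PDV}$ and no model carries more than two
random effects. We read it as a label slip and place the effect on
$\theta_{PDV}$.

## Estimation

`fit_model()` minimizes the Laplace-approximate marginal $-2\log L$ (the
OFV) over transformed parameters: log scale for positive parameters and
variances, logit for probabilities, atanh for the GP dispersion. Per
subject, the joint log density is maximized over the (at most two) random
effects by a safeguarded Newton iteration — analytic gradients and Hessians
for the single-rate families, central differences otherwise — and the
Laplace correction $\tfrac{q}{2}\log 2\pi - \tfrac12 \log\det(-H)$ is added
at the mode.

Numerical choices that matter:

* **Inner multi-start.** The per-subject joint density can be multi-modal
  (e.g. a subject whose activity is explained either by a high baseline
  $\eta_1$ or a strong Markov multiplier $\eta_2$). The inner search
  screens a fixed candidate set (prior mode, a moment-matched start, ±1
  prior SD per dimension) and polishes the best two. The candidate set is
  fixed so the OFV is a *deterministic, smooth* function of the parameters;
  a warm start carried across evaluations would make finite-difference
  gradients unreliable.
* **Inner tolerance.** The Newton iteration stops at an absolute gradient
  below 1e-8; looser (relative) tolerances leave mode errors that alias
  into visible noise on the outer finite-difference gradient.
* **Outer optimizer.** A quasi-Newton (PORT) run with an explicit
  central-difference gradient (step 1e-3 on the transformed scale), step
  length capped at 1 transformed unit per iteration, followed by one
  restart from the solution. Fits are deterministic given data, starting
  values and settings.
* **With all $\omega = 0$** the OFV reduces *exactly* to the fixed-effects
  $-2\log L$ at $\eta = 0$; zero variances are profiled out rather than
  approximated.

Standard errors come from a finite-difference Hessian of OFV/2 on the
transformed scale (step 1e-3), inverted and mapped back by the delta
method; RSE% is $100\,SE/|\hat\theta|$ on the natural scale, mirroring the
conventional reporting.

`agq_ofv()` implements adaptive Gauss–Hermite quadrature centered and
scaled at the same per-subject modes. One node reproduces the Laplace value
exactly by construction, so the quadrature serves as an internal truth
standard: on simulated 9-subject cohorts the Laplace OFV agrees with
15-node quadrature to well under 1% across the ladder.

Model selection follows the study convention: a drop in OFV of
$\chi^2_{1,0.99} = 6.63$ per extra parameter for nested models
(`lrt_threshold()`, `compare_fits()`), AIC for non-nested ones. Note that
the Markov coefficients are constrained non-negative, so the null of the
"add one Markov term" comparison sits on the boundary of the parameter
space; the realized type-I rate of the 6.63 rule is therefore at or below
the nominal 1% (asymptotically about half of it). The calibration test in
the suite checks the rate against the 1% ± 1 percentage-point band on
Markov-free simulated cohorts, using the clean one-parameter nesting (the
full ladder's NB and NB_MAK2 rows also differ in random-effect placement
and are not strictly nested).

## The synthetic cohort generator

`simulate_cohort()` draws $\eta_i \sim N(0, \omega)$ per subject, then
iterates months forward, computing $\lambda_{it}$ from the *realized*
earlier counts and sampling from the family's conditional distribution. The
generator's defaults emulate the study conditions: `study_cohort_preset()`
gives 9 subjects × 48 months at the reference estimates of the selected
second-order Markov NB model, and `validation_cohort_preset()` the external
design of 14 subjects × 6 months without dosing.

Dose events in the `triggered` policy are drawn at month $t$ with
probability 0.5 when the *previous* month's count reached 3. Treatment
following a relapse month is the clinically sensible direction, and a
trigger on the same month's count would be circular (the flag modifies the
distribution the count is drawn from). The threshold of 3 with probability
0.5 yields sparse dose events clustered at high-activity episodes, the
qualitative architecture of the real cohort; both knobs are configurable
and none of the inference depends on them.

What the generator deliberately does **not** emulate: missed scans
(complete monthly follow-up is assumed), lesion sizes or locations,
disability scores, and any mechanistic immunology. Passing predictive
checks on synthetic cohorts therefore demonstrates the correctness and
calibration of the machinery under the model's own assumptions — not that
the model is true of any real cohort.

## Model evaluation

`cel_descriptors()` computes the dynamic descriptors: pooled probability of
0, 1, …, 7 or ≥8 CELs per month (the text's "7 and >8" leaves the value 8
unassigned; the bucket is closed at ≥8), per-subject maximum and mean
lesion-free elapsed time, cumulative CELs per non-overlapping 12-month
year, and per-subject (mean, variance) pairs. Lesion-free runs are maximal
runs of zero-count months *within* a subject, counting runs that touch the
series boundaries; a subject with no lesion-free month contributes 0. The
"mean" descriptor averages run lengths within subject first, and the
subject-level values form the distribution that the percentile curves
summarize.

* `vnpc()` — observed versus simulated percentile curves (5th–95th, step
  5) for every descriptor, simulating 1000 individuals of the observed
  series length by default.
* `prediction_intervals()` — 1000 replicate studies of the observed size
  (9 subjects by default), percentile curves 10th–90th per study, pointwise
  2.5–97.5% envelope and median.
* `variance_mean_pi()` — 1000 simulated subjects sorted by per-subject
  mean into 20 bins of 50; per bin the median mean and the 5th/50th/95th
  percentiles of the variances, with the observed pairs overlaid.
* `external_validation()` — per-subject maximum, median and mean over a
  short window (the 6-month external design), rank-ordered and compared
  against the envelope of simulated replicate studies, plus the
  variance–mean envelope for the same window length.

All percentiles use linear interpolation between closest ranks (R's
`quantile` type 7); on 1000 simulated subjects the choice of percentile
definition moves the curves by less than the bin resolution. Descriptor
computation itself is a pure, seedless function of the dataset.

A window-length effect is worth knowing about: the apparent overdispersion
of a subject's series grows with the window over which mean and variance
are computed, so 6-month windows look less overdispersed than 48-month
windows *at identical parameters*. The external-validation comparison
therefore always simulates at the observed window length.

## The dose-randomization test

`randomization_test()` calibrates the steroid effect's significance without
distributional assumptions: the steroid model is refitted under `n_perm`
randomized dose-event architectures that preserve every count series and
the total number of dose events, and the true-architecture OFV is located
in the null OFV distribution. The default `pooled` scope reassigns dose
events uniformly over all subject-months (the stated conservation is of
the total only); `within_subject` additionally preserves each subject's
dose count for sensitivity. Permuted fits are warm-started at the true-data
estimates with unchanged convergence tolerances. Both the raw fraction
$\#\{OFV_{null} \le OFV_{true}\}/n_{perm}$ and the add-one
(permutation-test) estimator are reported; with a genuine effect in the
generator the test is comfortably significant at 200 permutations.

## Problem sizes used in the checks

The packaged checks run at the sizes a desk replication calls for:
parameter recovery at 500 subjects × 48 months (each fixed effect within
two asymptotic SEs of the generating value), quadrature agreement on
9 × 48 cohorts, likelihood-ratio calibration on 500 Markov-free replicates
of 9 × 48, and the randomization test at 200 permutations. These are the
package's own choices of scale; the full-size procedures (1000 simulated
individuals, 1000 studies, 1000 permutations) remain the documented
defaults of the corresponding functions.

## Known limitations

* The Laplace approximation carries a small finite-sample bias relative to
  exact marginal likelihood (visible against the quadrature oracle at the
  0.01–0.1% OFV level); at 500 subjects this bias is still well inside two
  standard errors of the fixed effects, but it is not zero.
* Random-effect variances estimated from 9 subjects have very large
  standard errors; that is a property of the design, not of the
  implementation.
* `PMIX` uses numeric inner derivatives and is noticeably slower than the
  single-rate families.
* No support for missing monthly scans, more than two random effects, or
  covariates other than the steroid flag.
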