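---
title: "Correcting partial verification bias in binary diagnostic tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting partial verification bias in binary diagnostic tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvboot)
```

## The problem

A diagnostic accuracy study compares a binary index test T against a
gold-standard determination of disease status D, reporting sensitivity
Sn = P(T = 1 | D = 1) and specificity Sp = P(T = 0 | D = 0). Gold-standard
verification is often invasive or expensive, so in practice only a subset of
tested patients is verified — and test-positive patients are referred far
more often than test-negatives. Estimating Sn and Sp from the verified
subset alone then suffers *partial verification bias* (PVB): sensitivity is
inflated and specificity deflated, because verified test-positives are
over-represented.

When the decision to verify depends only on the observed test result, the
missing disease statuses are *missing at random* (MAR) given T, and the bias
is correctable. `pvboot` implements the classical corrections together with
an inverse probability bootstrap (IPB) that resamples the verified cases
into *debiased synthetic datasets*, plus a Monte-Carlo harness for studying
all of them under known truth.

Throughout, the data are subject-level records (`test`, `verified`,
`disease`, with `disease = NA` where unverified). Every estimator is a
function of six sufficient counts: the verified 2×2 table
$s_{11}, s_{10}, s_{01}, s_{00}$ (test × disease) and the unverified totals
$u_1, u_0$ per test stratum (`cell_counts()`). We write $n$ for the number
of verified (complete) cases, $N = n + u_1 + u_0$, $m_t$ for the total
subjects with T = t, and $n_t$ for the verified subjects with T = t.

## The estimators

**Full data analysis (FDA)** is the ideal benchmark on fully verified data:
$\widehat{Sn} = s_{11}/(s_{11}+s_{01})$,
$\widehat{Sp} = s_{00}/(s_{10}+s_{00})$.

**Complete case analysis (CCA)** applies the same formulas to the verified
subjects only. Under MAR verification with probabilities
$\lambda_1 = P(V=1|T=1)$, $\lambda_0 = P(V=1|T=0)$ its large-sample limits
are
$$Sn_{CCA} = \frac{Sn\,\lambda_1}{Sn\,\lambda_1 + (1-Sn)\,\lambda_0},
\qquad
Sp_{CCA} = \frac{Sp\,\lambda_0}{Sp\,\lambda_0 + (1-Sp)\,\lambda_1},$$
so with $\lambda_1 > \lambda_0$ sensitivity is biased up and specificity
down. These closed forms are used as independent oracles in the test suite.

**Begg–Greenes (BG)** reassembles the accuracy measures by Bayes' theorem
from quantities that remain unbiased under MAR: the marginal
$\hat P(T=1) = m_1/N$ estimated from all subjects, and the predictive values
$p_t = \hat P(D=1|T=t, V=1)$ estimated from verified subjects:
$$\widehat{Sn}_{BG} =
  \frac{\hat P(T{=}1)\,p_1}{\hat P(T{=}1)\,p_1 + \hat P(T{=}0)\,p_0},
\qquad
\widehat{Sp}_{BG} =
  \frac{\hat P(T{=}0)(1-p_0)}{\hat P(T{=}1)(1-p_1) + \hat P(T{=}0)(1-p_0)}.$$

**Inverse probability weighting (IPWE)** weights each verified subject by
the inverse of its verification propensity $PS_i = P(V_i = 1 | T_i)$:
$$\widehat{Sn}_{IPWE} =
  \frac{\sum_i T_i V_i D_i / \widehat{PS}_i}{\sum_i V_i D_i / \widehat{PS}_i},$$
and the analogous ratio for specificity. With a single binary covariate the
logistic regression of V on T is saturated, so the fitted propensities are
the per-stratum verified fractions (`fit_propensity()` computes them
directly; a test cross-checks the shortcut against an iterative `glm` fit).
A consequence asserted by the test suite to 1e-12 is that **IPWE and BG are
algebraically identical** under the fitted propensity — which is why the
simulation study reports digit-identical rows for the two methods.

**Multiple imputation (MI)** replaces each missing D with draws from the
logistic imputation model $\mathrm{logit}\,P(D=1|T) = \beta_0 + \beta_1 T$
fitted to the verified subjects. Imputation is *proper*: each of the m
imputations first draws $(\beta_0, \beta_1)$ from the asymptotic normal
posterior of the fit, then draws the missing D Bernoulli. Per-imputation
full-data estimates are pooled: the point estimate is their mean, and
intervals use Rubin's rules (`rubin_pool()`) with total variance
$T = \bar W + (1 + 1/m) B$ and the classical degrees of freedom
$(m-1)(1 + \bar W/((1+1/m)B))^2$.

At small samples and low prevalence the verified table frequently contains
an empty cell (most often no verified false negatives), which makes the
bare logistic fit separable. Following standard multiple-imputation
practice, the default fit augments the data with $2pk$ weighted
pseudo-observations — one of each outcome class at
$\bar T \pm \mathrm{sd}(T)$, total weight $p + 1 = 2$ — which bounds the
fitted probabilities away from 0 and 1 while perturbing well-populated
tables negligibly. `impute_disease(..., augment = FALSE)` gives the
unaugmented fit, which refuses separated tables with an error.

## Inverse probability bootstrap

IPB turns the weighting idea into resampling. Each complete case receives
weight
$$w_i = \frac{1/\widehat{PS}_i}{\sum_{j=1}^n 1/\widehat{PS}_j},$$
(`ipb_weights()`; the weights sum to one and are invariant to rescaling all
propensities). Resampling the n complete cases with replacement with
probabilities $w_i$ produces a sample whose expected (test, disease)
composition is the *complete-data* distribution: the weighted mass on
stratum T = t equals the full-sample proportion of that stratum, undoing
the verification selection. The synthetic sample can then be analysed with
any full-data method — here the standard Sn/Sp formulas.

Since complete cases come in only four (test, disease) types, weighted
resampling is implemented as a four-cell multinomial draw; the test suite
verifies distributional agreement with a literal per-subject resampler by
comparing empirical CDFs of replicate estimates at n ≈ 90, b = 10&#8239;000.

### The point estimator and its dispersion

`estimate_ipb()` exposes three variants:

* `point = "sample"` (default). Draw **one** weighted bootstrap sample of
  size n — the debiased synthetic dataset — and report its standard Sn/Sp.
  The `b` *ordinary* bootstrap resamples of the synthetic sample supply the
  standard error and the bootstrap normal interval
  $\widehat{Sn} \pm z_{1-\alpha/2}\,SE_{boot}$.
* `point = "mean"`. The mean of the standard estimates over `b` weighted
  bootstrap samples.
* `point = "plugin"`. The weighted (Hájek) estimate itself — identical to
  IPWE.

All three have the same expectation, so the same (small) bias; they differ
in dispersion. The `"sample"` estimator's variance is the *sum* of the
sampling variance of the weighted estimator and one full resampling
variance: a single multinomial draw does not average the resampling noise
away. Writing $\sigma^2_{outer}$ for the IPWE variance and
$\sigma^2_{inner}$ for the within-sample resampling variance (for Sn,
approximately $Sn(1-Sn)$ over the expected number of diseased subjects in
the synthetic sample), the `"sample"` estimator has variance
$\sigma^2_{outer} + \sigma^2_{inner}$ — typically an SE inflation of about
$\sqrt 2$ relative to IPWE at these designs — while `"mean"` shrinks the
inner term by $1/b$. This is the price of producing an analysable debiased
dataset rather than only a number, and it is why the package's simulation
study shows IPB with the largest standard errors at small samples, shrinking
as N (hence n and the diseased subgroup $p \times n$) grows. The default is
`"sample"` because the method's purpose is the synthetic dataset, and its
dispersion is what the Monte-Carlo study tabulates.

Bootstrap replicates in which a resample contains no diseased (or no
non-diseased) subjects leave Sn (or Sp) undefined; such replicates are
excluded from that quantity's mean/SD and counted, with a warning above 1%
incidence. Exclusion avoids biasing the estimate toward any arbitrary
imputed value for an undefined ratio. A degenerate *synthetic* sample (no
diseased subjects drawn at all) is redrawn.

## Confidence intervals

Each method uses the interval construction conventional for it: Wald for
FDA/CCA (`wald_ci()`); for BG a logit-scale delta-method interval
(`bg_analytic_ci()`), using
$\mathrm{Var}[\mathrm{logit}\,\widehat{Sn}] = N/(m_1 m_0) +
(1-p_1)/(n_1 p_1) + (1-p_0)/(n_0 p_0)$
(the three components — the T margin and the two stratum predictive values —
are asymptotically independent under the two-phase design), with a
subject-resampling bootstrap alternative that the test suite checks agrees
at large N; BCa bootstrap for IPWE (`boot_bca_ci()`, following the
conventions of the classical bootstrap literature so that it matches the
`boot` package to 1e-6 on shared replicates); Rubin's rules for MI; and
bootstrap normal for IPB. All intervals on proportions are clipped to
[0, 1] after construction.

## The simulator

`simulate_complete()` draws one N-trial multinomial over the four cells
$$\pi_1 = Sn\cdot p,\quad \pi_2 = (1-Sn)p,\quad \pi_3 = (1-Sp)(1-p),\quad
\pi_4 = Sp(1-p),$$
expands to subject level and shuffles — equivalent in distribution to
per-subject categorical draws but much faster. `apply_mar_verification()`
then draws each subject's verification Bernoulli with probability
$\lambda_1$ (test-positives) or $\lambda_0$ (test-negatives) and masks the
unverified disease statuses. The defaults $\lambda_1 = 0.8$,
$\lambda_0 = 0.4$ encode the classical referral asymmetry. The analytic
verified fraction is $\lambda_1 P(T{=}1) + \lambda_0 P(T{=}0)$, which the
generator matches within binomial error.

The generator emulates exactly the MAR-given-T mechanism: no covariates
beyond the test result, a fixed test with no measurement drift, and
independent subjects. Real verification decisions often also depend on
symptoms, site, or clinician — i.e. on covariates not in this model — and
may be MNAR; passing tests under this generator therefore demonstrate
correctness under MAR-given-T, not robustness to richer missingness.

## The Monte-Carlo study

`run_cell()` evaluates the estimators over B independent replicates of one
scenario; `run_study()` crosses prevalence p ∈ {0.4, 0.1}, (Sn, Sp) ∈
{(0.6, 0.6), (0.6, 0.9), (0.9, 0.6)} and N ∈ {200, 1000}. Design choices:

* **Common random numbers.** Within a replicate, one simulated dataset
  feeds every method (FDA sees the complete version, the rest the masked
  version), so between-method comparisons are not blurred by independent
  generation noise.
* **Per-replicate seed streams.** Replicate i runs on a seed derived from
  the master seed, so any single replicate can be reproduced in isolation
  and the replicate stream does not depend on which methods are requested.
* **Conditioning on estimable samples.** A replicate is redrawn until all
  four verified cells are non-empty; the number of redraws is reported.
  At low prevalence and small N this conditioning is substantial (at
  p = 0.1, Sn = 0.9, N = 200 nearly half of raw draws lack a verified
  false negative) and it shifts *every* method's conditional expectation —
  including FDA's, whose small negative bias in that cell is a conditioning
  effect, not an estimator defect. The alternative — dropping degenerate
  replicates per method — would compare methods on different sample sets.
* **Count-level fast path.** Generation and estimation run on the six
  sufficient counts (binomial thinning per cell instead of per-subject
  Bernoulli draws); this is exactly equivalent in distribution and makes a
  full 12-cell × 6-method study with B = 500, b = 1000 run in well under a
  minute on one core.
* **Metrics.** Bias $= \bar{\hat\theta} - \theta$ and Monte-Carlo SE (SD
  with the B−1 denominator), per `compute_metrics()`. Coverage of the
  intervals is deliberately out of scope for the study runner.
* **Reporting.** `format_study_table()` rounds to three decimals for
  display; the long-format result keeps full precision.

Default sizes B = 500 and b = 1000 match standard practice for this kind of
bias/SE study and keep a full grid cheap; m = 100 imputations for simulated
data, and for applied analyses `m = "auto"` sets m to the percentage of
incomplete cases (a common applied rule).

## Worked clinical-style example

Two classic verification-bias teaching datasets ship as count tables
reconstructed in code from their published margins (`pvb_example()`; no
data files are bundled):

```{r clinical}
hep <- pvb_example("hepatic")
estimate_accuracy(hep, b = 1000, m = "auto", seed = 1)
```

CCA overstates sensitivity (0.895 vs ≈ 0.836 for every corrected method)
and understates specificity, exactly the PVB signature; the corrections
agree closely with one another. On the diaphanography data (90.2%
unverified, low prevalence) the corrections also agree on the point
estimates but IPB's intervals are visibly the widest — the small-n,
low-prevalence regime where the synthetic-sample dispersion dominates.

## Numerical notes and limitations

* Estimates and interval endpoints are proportions; clipping to [0, 1]
  happens after construction (unclipped values are recoverable from the
  standard errors).
* `m = "auto"` never goes below 2; Rubin pooling requires m ≥ 2.
* BCa falls back to a point interval (with a warning) when all replicates
  are identical, and refuses an infinite bias correction (point estimate
  outside the replicate range).
* The propensity model conditions on T only, matching the MAR mechanism
  studied; verification driven by additional covariates needs a richer
  propensity model and is out of scope, as are MNAR mechanisms and
  non-binary tests.
* The Begg–Greenes analytic interval is a delta-method approximation; at
  small verified counts the bootstrap alternative (`ci = "boot"`) is
  preferable.
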