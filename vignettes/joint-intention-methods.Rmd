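---
title: "Methods: joint modelling of vaccine and contact-tracing-app intentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint modelling of vaccine and contact-tracing-app intentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

During an epidemic, pharmacological (vaccination) and non-pharmacological
(digital contact tracing) measures coexist, and the factors driving uptake of
one need not drive the other. `bivintent` analyses the two stated intentions
jointly: each respondent reports, on 0–100 sliders, how likely they are to get
a COVID-19 vaccine and to download the national contact-tracing app (CTA).
Because the two answers come from the same person they are correlated, and the
*strength* of that correlation is itself of scientific interest — it tells us
whether the same people accept or refuse both measures, and which covariates
make acceptance concordant or discordant.

# The bivariate Gaussian distributional regression

The core model treats the pair \(Y = (Y_1, Y_2)\) (vaccine intention, CTA
intention) as bivariate normal,

\[ Y \sim N_2(\mu, \Sigma), \qquad \Sigma = D\,\Omega\,D, \]

with \(D = \mathrm{diag}(\sigma_1, \sigma_2)\) and \(\Omega\) the 2×2
correlation matrix with off-diagonal \(\rho\). All five distributional
parameters are regressed on covariates:

\[ \mu_j = \beta_j^\top x, \qquad \log \sigma_j = \gamma_j^\top x, \qquad
   \mathrm{rhogit}(\rho) = \beta_3^\top x, \]

where \(\mathrm{rhogit}(\rho) = \rho / \sqrt{1 - \rho^2}\) maps \((-1, 1)\)
bijectively to the real line. The links guarantee \(\sigma_j > 0\) and
\(|\rho| < 1\) for *every* finite coefficient vector, so any parameter value
the sampler visits yields a valid covariance — a property the test suite
checks by Cholesky-factorising random draws.

By convention one covariate set is shared by all five blocks. Age enters
through a low-rank thin-plate regression spline with 5 basis functions
(sum-to-zero constraint absorbed, leaving 4 coefficients), built with
`mgcv::smoothCon`; the roughness penalty \((\lambda/2)\, b^\top P b\) acts as
a Gaussian prior on the spline coefficients.

## Estimation: ML initialisation, then MCMC

Estimation is two-stage. First, a joint BFGS maximisation of the (penalized)
log-likelihood over all blocks, with analytic gradients, initialised from
per-outcome least squares; the inverse observed information gives asymptotic
standard errors and, more importantly, proposal covariances. Second, a
blockwise adaptive random-walk Metropolis sampler started at the ML solution,
with improper flat priors on all regression coefficients. Defaults follow the
analysis design: 10,000 iterations with a 1,000-iteration burn-in; proposal
scales adapt by Robbins–Monro toward 23.4% acceptance during burn-in only,
so the retained chain is a proper Markov chain. Coefficients are reported as
posterior means with 2.5–97.5% percentile credible intervals, flagged when
the interval excludes zero.

Design choices the model family leaves open, decided here:

* **Sampler.** Blockwise adaptive random-walk Metropolis with ML-based
  proposal covariance, scaled \(2.38^2/d\). Seed-deterministic by
  construction.
* **Smoothing parameters.** Fixed during MCMC at REML estimates from
  marginal Gaussian additive fits of each outcome (`mgcv::gam`), rescaled to
  penalty-per-unit-log-likelihood (\(\mathrm{sp}/\hat\sigma^2\)); each
  location block uses its own outcome's estimate and the scale/correlation
  blocks take the geometric mean. Sampling \(\lambda\) was considered and
  rejected: with only 4 penalized coefficients the posterior for \(\lambda\)
  is weakly identified and fixing it keeps the chain simple and reproducible.
* **DIC.** Spiegelhalter's \(\bar D + p_D\), with the deviance computed from
  the *unpenalized* likelihood and \(p_D = \bar D - D(\bar\theta)\) at the
  posterior-mean coefficients.
* **Forward selection.** Greedy: each remaining candidate enters all five
  blocks simultaneously (the shared-covariate convention); the candidate with
  the largest DIC reduction is kept; the search stops when no candidate
  reduces DIC; ties within 0.01 go to the earlier-listed candidate.
* **Bounded outcomes.** The 0–100 scores are modelled as unbounded
  Gaussians, with no censoring correction. The residual Q–Q diagnostic
  (`residual_qq`) is the honesty check: on clamped data it shows the expected
  lower-tail departure while remaining near slope 1 on data from the model's
  own law.

# Factor scores and categorical codings

The three perceived-risk items (likelihood of infection, severity, scare) and
the three trust items (international, national institutions, scientific
committees) are each reduced to a single index by a one-factor
maximum-likelihood solution on the empirical variance–covariance matrix
(`fit_single_factor`; the normal-theory discrepancy is minimised directly,
loading sign fixed so the sum is positive, uniquenesses floored at
\(10^{-3}\) of the item variance with a Heywood warning). Variance explained
is \(\sum_i \lambda_i^2 / \mathrm{tr}(S)\). A correlation-matrix mode exists
(`standardize = TRUE`) and is cross-checked against `factanal` in the tests;
the covariance mode is the default. Scores are Thomson regression scores.

Scores are coded into terciles with bounds at the 1/3 and 2/3 inverse-ECDF
quantiles, intervals lower-open/upper-closed so boundary values fall in the
lower category. The vaccine-doubts score is zero-inflated: exact zeros form a
"No doubts" class and the strictly positive values are split by *their own*
terciles (Low/Medium/High doubts). Interval bounds are printed per category
as `(lower, upper)` using observed minima/maxima as the outer bounds.

# The motivation model

Each respondent rated how much their intention was meant to protect
themselves and to protect others, for each measure — four ordinal responses
per subject on a 1–4 scale (items are *collected* 0–4; validation collapses
raw levels 0 and 1 into modelling level 1, a documented and overridable
recode, since the two numbering conventions cannot otherwise be reconciled).
The wide items are reshaped to long format (4 rows per subject, reference
levels "CTA Immuni" and "for others") and fitted with the mixed-effects
proportional-odds model

\[ \mathrm{logit}\, P(Y_{ij} \le k) = \theta_k - (x_{ij}^\top\beta +
   \gamma_j), \qquad \gamma_j \sim N(0, \sigma_\gamma^2). \]

This model family is sometimes written with an extra Gaussian residual
\(\varepsilon\) inside the logit; that term is nonstandard and is treated
here as notational —
the logistic latent error of the cumulative logit is implicit — which matches
the model actually fit by the standard ordinal-regression software family.
Positive \(\beta\) means higher motivation categories are more likely, so
\(e^\beta\) is the odds ratio of a *higher* response.

The random intercept is integrated out by **adaptive Gauss–Hermite
quadrature** (default 15 nodes): per-subject modes and curvatures are found
by vectorised Newton steps, nodes are recentred and rescaled, and the
log-sum-exp keeps the integral stable. At \(\sigma_\gamma = 0\) the code
short-circuits to the exact fixed-effects likelihood. The quadrature is
validated against brute-force trapezoid integration on a small panel
(agreement to \(10^{-6}\)) and doubling the node count moves the toy
log-likelihood by less than \(10^{-8}\). Model choice is by AIC
(\(-2\ell + 2\,\mathrm{npar}\)); Wald confidence intervals are computed on
the log-odds scale from the inverse observed information on the natural
parameterisation and exponentiated. The conspiracy-belief outcome (1–7) uses
the same machinery without the random intercept.

# The descriptive layer

`table_one` stratifies the sample (by the doubts classes, typically):
continuous rows show median (q25, q75) and are tested by Wilcoxon rank-sum
(2 strata) or Kruskal–Wallis (>2); categorical rows show count (%) and use
Pearson's chi-squared, switching to Fisher's exact test whenever *any*
expected cell count falls below 10 — the switch is a pure function of the
expected-count table and is tested as such. The vaccine-vs-CTA comparison is
implemented as the *paired* signed-rank test, since the same respondents
rated both measures; an unpaired variant is available through `wilcox.test`
directly. Continuity corrections are off by default and switchable.
`spearman_matrix` gives the pairwise rank-correlation matrix with
midrank ties and asymptotic rho-test p-values, checked against a permutation
oracle in the tests.

# The synthetic-data generator

`generate_survey` emulates the structures the analysis assumes — not the full
empirical joint distribution of any real survey:

* n = 448, 70.8% female, age 33.8 ± 13.9 (truncated 18–85);
* one latent standard-normal factor behind each 3-item block, items =
  loading × factor + unique noise, affinely mapped to 0–100 (risk loadings
  weight scare/severity above likelihood; trust loadings are uniformly high);
* vaccine doubts zero-inflated: Bernoulli point mass at 0 (default 0.219,
  loosely calibrated to a "No doubts" class of 98/448) plus a scaled
  Beta(0.9, 1.6) on (0, 100] — the Beta shape is our choice, made once;
* intentions drawn from the bivariate distributional law given each
  respondent's doubts, latent factors and flu-vaccination status, then
  clamped to [0, 100]. Clamping produces the boundary spikes ("non-bell
  shape") of real slider data while the *estimation* model stays exactly the
  Gaussian law — so parameter-recovery tests use the unclamped generator
  (`generate_bbg_data` or `clamp = FALSE`), and tests on clamped data check
  robustness, not unbiasedness;
* motivation items from the mixed cumulative-logistic law (vaccine effect
  log 3, self effect log 0.71, a positive latent-risk effect, subject
  intercept SD 1.5), conspiracy from a 7-level cumulative logit driven by
  doubts.

One master seed drives independent per-stage substreams, so a fixed seed
fixes every generated byte and single stages can be regenerated in
isolation. Generator outputs always pass `validate_survey`.

# Numerical choices and degenerate inputs

* ML convergence: BFGS with relative tolerance \(10^{-12}\); the relative
  gradient norm is stored on the fit. Line-search excursions that overflow
  `exp` are absorbed by a large finite objective value.
* MCMC failure: post-adaptation acceptance below 1% in any block raises an
  error rather than returning a silent garbage chain.
* Thresholds of the ordinal model are optimised as (first threshold, log
  gaps), guaranteeing monotonicity; the reported covariance is computed on
  the natural scale.
* Degenerate inputs: constant outcomes (no identifiable thresholds), empty
  synthetic datasets (n = 0), singular item covariances, rank-deficient
  designs, non-monotone thresholds and out-of-range scores all raise typed
  errors; all-equal score vectors and missing zero classes degrade to
  single-category codings with warnings.

# Problem sizes used in the checks

The statistical guarantees are exercised at sizes chosen to make Monte-Carlo
noise negligible relative to each tolerance: likelihood oracles on ~100-row
instances; ML recovery at n = 5000; credible-interval calibration over 100
replicates of n = 300 with 2,000-iteration chains (chain length is not part
of the model definition; at this n the posterior quantiles are stable well
before 2,000 iterations, and the 10,000/1,000 default remains in force for
data analysis); DIC selection over 100 replicates of n = 200; ordinal
recovery at 500 subjects × 4 responses; descriptive test sizes over 1,000
permuted replicates.

# Known limitations

* The Gaussian likelihood ignores the censoring created by the bounded
  0–100 scale; effects near the boundaries are attenuated. The Q–Q
  diagnostic makes the misfit visible rather than correcting it.
* The one-factor extractor is limited to 3-item blocks by design; no
  rotations or multi-factor solutions.
* Forward selection explores a single greedy path; it reports its full trace
  precisely because the path, not just the endpoint, is the evidence.
* DIC and AIC are the only model-comparison criteria, matching the analysis
  design; no cross-validation.
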