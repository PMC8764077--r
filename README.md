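# bivintent

Joint analysis of two COVID-19 preventive-behaviour intentions — getting
vaccinated and downloading the national contact-tracing app (CTA) — from
respondent-level survey data. The package is aimed at biostatisticians and
behavioural epidemiologists who want to model two bounded 0–100 intention
scores *jointly*, asking not only which covariates shift each intention but
which covariates change their spread and their concordance.

## The models

**Bivariate Gaussian distributional regression.** The pair
*Y* = (*Y*₁, *Y*₂) (vaccine, CTA) is modelled as *Y* ~ N₂(μ, Σ) with
Σ = *D*Ω*D* (scales σ₁, σ₂ and correlation ρ), and *all five* parameters
regressed on covariates:

    μ_j = β_jᵀx,   log σ_j = γ_jᵀx,   rhogit(ρ) = β₃ᵀx,
    rhogit(ρ) = ρ / √(1 − ρ²)

Estimation is maximum likelihood (joint BFGS, analytic gradients) followed by
blockwise adaptive Metropolis MCMC started at the ML solution with flat
priors (default 10,000 iterations, 1,000 burn-in). Coefficients are reported
as posterior means with 2.5–97.5% credible intervals; model comparison and
forward covariate selection use DIC; age can enter through a 5-basis
thin-plate regression spline.

**Mixed-effects cumulative logistic model.** Each respondent's four
motivation items (2 measures × protect self/others) are reshaped to long
format and fitted with the proportional-odds model
logit P(*Y*ᵢⱼ ≤ *k*) = θ_k − (*x*ᵀβ + γⱼ), γⱼ ~ N(0, σ_γ²), the random
intercept integrated by adaptive Gauss–Hermite quadrature; effects are
reported as odds ratios of a higher motivation score with Wald 95% CIs. A
fixed-effects variant serves the 7-point conspiracy-belief outcome.

**Upstream/downstream layers.** Single-factor maximum-likelihood extraction
on the covariance matrix of the 3-item perceived-risk and trust blocks
(variance explained, Thomson scores), tercile and zero-inflated categorical
codings, stratified descriptive tables with the chi-squared→Fisher switching
rule (expected count < 10), Spearman correlation matrices, and a synthetic
survey generator that reproduces the statistical structure the models assume
(n = 448, 70.8% female, age 33.8 ± 13.9, zero-inflated doubts, clamped
bivariate intentions, risk-linked motivation items).

## Worked example

```r
library(bivintent)

d <- generate_survey(synthetic_config(n = 448, seed = 1))
d$doubts_cat <- categorize_doubts(d$vaccine_doubts)$categories

fit <- fit_bbg(d, bbg_design_spec(covariates = c("doubts_cat",
                                                 "flu_vaccine_2019")),
               config = bbg_mcmc_config(iterations = 10000, burnin = 1000,
                                        seed = 1))
subset(summarize_bbg(fit), term == "mu1:doubts_catHigh doubts")
#>                         term block      mean      q2.5     q97.5 excludes_zero
#> 4 mu1:doubts_catHigh doubts   mu1 -34.15712 -40.74475 -27.60638          TRUE
```

Respondents in the highest doubts tercile intend to vaccinate about 34
points less (on the 0–100 slider) than the "no doubts" reference, with a
95% credible interval of roughly (−41, −28) — the generator's true latent
effect is about −41, attenuated by boundary clamping. The same
summary carries the CTA-intention block (`mu2:`) and the correlation block
(`rho:`), whose coefficients are on the rhogit scale.

```r
long <- reshape_motivation_long(d)
mot <- fit_cumlogit(long)   # measure type + protection target, random intercept
render_table3(odds_ratios(mot))
#>                                      term   OR        CI95       p
#> 1                           Intercept 1|2 0.08 (0.06-0.10) < 0.001
#> 2                           Intercept 2|3 0.33 (0.26-0.42) < 0.001
#> 3                           Intercept 3|4 1.54 (1.21-1.96) < 0.001
#> 4      measure_typeCTA Immuni (reference) 1.00           -       -
#> 5            measure_typeCOVID-19 vaccine 2.86 (2.34-3.50) < 0.001
#> 6 motivation_targetfor others (reference) 1.00           -       -
#> 7             motivation_targetfor myself 0.79 (0.65-0.96)   0.016
```

Motivation to get the vaccine is about 2.9 times the odds of a higher score
than for the CTA, and motivation framed as self-protection runs *below*
protection of others (OR 0.79) — the generating values are exp(1.10) = 3 and
exp(−0.34) = 0.71.

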