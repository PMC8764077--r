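# shared fixtures: built once per test run, cached in this environment
.fixtures <- new.env(parent = emptyenv())

# small survey used by io/descriptives/reporting tests
fixture_survey <- function(n = 250, seed = 42) {
  key <- paste0("survey_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_survey(synthetic_config(n = n, seed = seed))
  }
  .fixtures[[key]]
}

# a fitted bivariate model on data drawn from its own law (no clamping),
# one binary covariate in every block; reused by summary/diagnostic tests
fixture_bbg_fit <- function() {
  if (is.null(.fixtures$bbg_fit)) {
    set.seed(11)
    n <- 600
    X <- cbind(1, rbinom(n, 1, 0.5))
    sim <- generate_bbg_data(beta1 = c(50, 15), beta2 = c(30, -8),
                             gamma1 = c(log(10), 0.3),
                             gamma2 = c(log(8), 0),
                             beta3 = c(rhogit(0.4), 0.4),
                             X = X, seed = 11)
    dat <- data.frame(vaccine_intent = sim$y[, 1],
                      cta_intent = sim$y[, 2],
                      x = X[, 2])
    fit <- fit_bbg(dat, bbg_design_spec(covariates = "x"),
                   config = bbg_mcmc_config(iterations = 2000L,
                                            burnin = 500L, seed = 7L))
    .fixtures$bbg_fit <- fit
  }
  .fixtures$bbg_fit
}

# brute-force bivariate normal log-density via marginal x conditional
oracle_binorm_loglik <- function(y1, y2, mu1, mu2, s1, s2, rho) {
  lm1 <- dnorm(y1, mu1, s1, log = TRUE)
  cond_mean <- mu2 + s2 * rho * (y1 - mu1) / s1
  cond_sd <- s2 * sqrt(1 - rho^2)
  sum(lm1 + dnorm(y2, cond_mean, cond_sd, log = TRUE))
}

# brute-force trapezoid marginal likelihood of the mixed cumulative logit
oracle_mixed_loglik <- function(theta, beta, sigma, X, y, subject,
                                lim = 8, npts = 4001) {
  gam <- seq(-lim, lim, length.out = npts)
  h <- gam[2] - gam[1]
  eta <- if (length(beta)) drop(X %*% beta) else numeric(length(y))
  up <- c(theta, Inf)[y]
  lo <- c(-Inf, theta)[y]
  ll <- 0
  for (s in unique(subject)) {
    rows <- which(subject == s)
    dens <- vapply(gam, function(g) {
      p <- plogis(up[rows] - eta[rows] - g) - plogis(lo[rows] - eta[rows] - g)
      prod(p) * dnorm(g, 0, sigma)
    }, numeric(1))
    int <- h * (sum(dens) - 0.5 * (dens[1] + dens[npts]))
    ll <- ll + log(int)
  }
  ll
}
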