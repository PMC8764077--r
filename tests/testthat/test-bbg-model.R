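test_that("bivariate log-density matches closed forms and factorizations", {
  d <- data.frame(vaccine_intent = rep(0, 10), cta_intent = rep(0, 10))
  des <- build_design(bbg_design_spec(), d)
  theta <- numeric(5)  # mu = (0,0), sigma = (1,1), rho = 0
  expect_equal(bbg_loglik(theta, des, as.matrix(d)), -10 * log(2 * pi),
               tolerance = 1e-12)

  # rho = 0 factorizes into the two univariate Gaussian log-likelihoods
  set.seed(71)
  y <- cbind(rnorm(50, 3, 2), rnorm(50, -1, 0.5))
  d2 <- data.frame(vaccine_intent = y[, 1], cta_intent = y[, 2])
  des2 <- build_design(bbg_design_spec(), d2)
  th <- c(3, -1, log(2), log(0.5), 0)
  expect_equal(bbg_loglik(th, des2, y),
               sum(dnorm(y[, 1], 3, 2, log = TRUE)) +
                 sum(dnorm(y[, 2], -1, 0.5, log = TRUE)),
               tolerance = 1e-10)
})

test_that("analytic gradient matches central differences", {
  set.seed(72)
  d <- data.frame(vaccine_intent = rnorm(40, 50, 10),
                  cta_intent = rnorm(40, 30, 8),
                  x = rnorm(40), g = factor(sample(c("a", "b"), 40, TRUE)))
  des <- build_design(bbg_design_spec(covariates = c("x", "g")), d)
  y <- as.matrix(d[1:2])
  theta <- rnorm(length(unlist(des$idx)), sd = 0.2)
  theta[des$idx$mu1[1]] <- 45; theta[des$idx$mu2[1]] <- 28
  theta[des$idx$sigma1[1]] <- log(9); theta[des$idx$sigma2[1]] <- log(7)
  g <- bbg_loglik_grad(theta, des, y)
  num <- vapply(seq_along(theta), function(i) {
    e <- 1e-6
    tp <- theta; tp[i] <- tp[i] + e
    tm <- theta; tm[i] <- tm[i] - e
    (bbg_loglik(tp, des, y) - bbg_loglik(tm, des, y)) / (2 * e)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("design construction: treatment coding, spline constraint, locality", {
  d <- fixture_survey(n = 150)
  d$doubts_cat <- categorize_doubts(d$vaccine_doubts)$categories
  des <- build_design(bbg_design_spec(covariates = "doubts_cat",
                                      spline = list(variable = "age",
                                                    lambda = 1)), d)
  X <- des$X$mu1
  expect_equal(sum(startsWith(colnames(X), "doubts_cat")), 3L)  # 4 levels -> 3
  expect_true("(Intercept)" %in% colnames(X))
  spl <- X[, startsWith(colnames(X), "s(age)"), drop = FALSE]
  expect_equal(ncol(spl), 4L)                 # 5 bases, sum-to-zero absorbed
  expect_lt(max(abs(colSums(spl))), 1e-8)     # orthogonal to the intercept
  # penalty matrix is symmetric positive semi-definite
  S <- des$penalties[[1]]$S
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-8))

  # rows identical except one covariate differ only in that covariate's columns
  d2 <- d[c(1, 1), ]
  d2$respondent_id <- c("A", "B")
  d2$job <- factor(c("employee", "student"), levels = levels(d$job))
  des2 <- build_design(bbg_design_spec(covariates = c("gender", "job")), d2)
  diffcols <- which(des2$X$mu1[1, ] != des2$X$mu1[2, ])
  expect_true(all(startsWith(colnames(des2$X$mu1)[diffcols], "job")))
})

test_that("a zero column with any coefficient leaves the log-likelihood unchanged", {
  set.seed(73)
  d <- data.frame(vaccine_intent = rnorm(30, 50, 5),
                  cta_intent = rnorm(30, 30, 5))
  des <- build_design(bbg_design_spec(), d)
  y <- as.matrix(d)
  theta <- c(50, 30, log(5), log(5), 0.2)
  ll0 <- bbg_loglik(theta, des, y)
  des_aug <- des
  des_aug$X$mu1 <- cbind(des$X$mu1, zero = 0)
  des_aug$idx <- list(mu1 = 1:2, mu2 = 3, sigma1 = 4, sigma2 = 5, rho = 6)
  des_aug$terms <- c("mu1:(Intercept)", "mu1:zero", des$terms[-1])
  theta_aug <- c(50, 123.4, 30, log(5), log(5), 0.2)
  expect_equal(bbg_loglik(theta_aug, des_aug, y), ll0, tolerance = 1e-12)
})

test_that("with constant scale and correlation blocks, ML locations equal OLS", {
  set.seed(74)
  n <- 400
  d <- data.frame(x = rnorm(n), z = rbinom(n, 1, 0.4))
  sim <- generate_bbg_data(beta1 = c(50, 6, -4), beta2 = c(30, -2, 5),
                           gamma1 = c(log(7), 0, 0), gamma2 = c(log(5), 0, 0),
                           beta3 = c(rhogit(0.5), 0, 0),
                           X = cbind(1, d$x, d$z), seed = 74)
  d$vaccine_intent <- sim$y[, 1]
  d$cta_intent <- sim$y[, 2]
  spec <- bbg_design_spec(mu1 = c("x", "z"), mu2 = c("x", "z"),
                          sigma1 = character(), sigma2 = character(),
                          rho = character(), covariates = character())
  des <- build_design(spec, d)
  ml <- fit_bbg_ml(des, sim$y)
  ols1 <- coef(lm(vaccine_intent ~ x + z, d))
  ols2 <- coef(lm(cta_intent ~ x + z, d))
  expect_equal(unname(ml$par[des$idx$mu1]), unname(ols1), tolerance = 1e-6)
  expect_equal(unname(ml$par[des$idx$mu2]), unname(ols2), tolerance = 1e-6)

  # refitting from the solution is a fixed point
  ml2 <- fit_bbg_ml(des, sim$y, init = unname(ml$par))
  expect_equal(unname(ml2$par), unname(ml$par), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  d <- data.frame(vaccine_intent = rnorm(20), cta_intent = rnorm(20),
                  x = 1:20, y2 = 2 * (1:20))
  des <- build_design(bbg_design_spec(covariates = c("x", "y2")), d)
  expect_error(fit_bbg_ml(des, as.matrix(d[1:2])), "rank deficient")
})

test_that("MCMC is seed-deterministic and agrees with ML on strong-signal data", {
  fit <- fixture_bbg_fit()
  cfg <- bbg_mcmc_config(iterations = 300L, burnin = 100L, seed = 5L)
  a <- run_bbg_mcmc(fit$ml_fit, cfg)
  b <- run_bbg_mcmc(fit$ml_fit, cfg)
  expect_identical(a$draws, b$draws)

  # posterior means near the ML estimates (flat priors, n = 600)
  post <- colMeans(fit$draws)
  sdp <- apply(fit$draws, 2, sd)
  expect_true(all(abs(post - fit$ml_fit$par) < 0.75 * sdp + 1e-8))
})

test_that("posterior summaries: quantiles, flags, degenerate draws", {
  draws <- matrix(rep(c(2, -1), each = 150), ncol = 2)
  colnames(draws) <- c("mu1:(Intercept)", "rho:(Intercept)")
  s <- summarize_bbg(draws)
  expect_equal(s$mean, c(2, -1))
  expect_equal(s$q2.5, c(2, -1))
  expect_equal(s$q97.5, c(2, -1))
  expect_true(all(s$excludes_zero))

  set.seed(76)
  z <- matrix(rnorm(1e5), ncol = 1)
  colnames(z) <- "mu1:x"
  sz <- summarize_bbg(z)
  expect_equal(sz$q2.5, -1.96, tolerance = 0.02)
  expect_equal(sz$q97.5, 1.96, tolerance = 0.02)
  expect_false(sz$excludes_zero)
  expect_error(summarize_bbg(z[1:50, , drop = FALSE]), "100")
})

test_that("DIC collapses to the plug-in deviance under a point-mass posterior", {
  fit <- fixture_bbg_fit()
  theta_hat <- unname(fit$ml_fit$par)
  dev_hat <- -2 * bbg_loglik(theta_hat, fit$designs, fit$y, penalized = FALSE)
  point <- fit
  point$draws <- matrix(rep(theta_hat, each = 200), nrow = 200)
  colnames(point$draws) <- fit$designs$terms
  point$deviance <- rep(dev_hat, 200)
  d <- bbg_dic(point)
  expect_equal(d$pd, 0, tolerance = 1e-8)
  expect_equal(d$dic, dev_hat, tolerance = 1e-8)
})

test_that("forward selection returns the intercept-only spec for no candidates", {
  d <- data.frame(vaccine_intent = rnorm(50, 50), cta_intent = rnorm(50, 30))
  sel <- forward_select_bbg(d, candidates = character(),
                            config = bbg_mcmc_config(iterations = 300L,
                                                     burnin = 100L, seed = 2L))
  expect_identical(sel$selected, character(0))
  expect_equal(nrow(sel$trace), 1L)
})

test_that("spline effect: flat under zero coefficients, centred, recovers a known curve", {
  set.seed(77)
  n <- 500
  age <- runif(n, 20, 70)
  f_true <- 0.02 * (age - 45)^2 - mean(0.02 * (age - 45)^2)
  y1 <- 50 + f_true + rnorm(n, 0, 5)
  y2 <- 30 + rnorm(n, 0, 5)
  d <- data.frame(vaccine_intent = y1, cta_intent = y2, age = age)
  spec <- bbg_design_spec(spline = list(variable = "age", blocks = "mu1"))
  fit <- fit_bbg(d, spec, config = bbg_mcmc_config(iterations = 2000L,
                                                   burnin = 500L, seed = 3L))
  grid <- seq(25, 65, length.out = 25)
  eff <- spline_effect(fit, "mu1", grid)
  truth <- 0.02 * (grid - 45)^2
  truth <- truth - mean(0.02 * (age - 45)^2)
  covered <- mean(truth >= eff$q2.5 - 1 & truth <= eff$q97.5 + 1)
  expect_gte(covered, 0.9)
  expect_warning(spline_effect(fit, "mu1", c(10, 40)), "range")

  zero <- fit
  zero$draws[, grep("s\\(age\\)", colnames(zero$draws))] <- 0
  flat <- spline_effect(zero, "mu1", grid)
  expect_equal(flat$mean, rep(0, 25), tolerance = 1e-12)

  # sum-to-zero constraint: effect at the observed ages averages to zero
  at_obs <- spline_effect(fit, "mu1", sort(age[1:200]))
  expect_lt(abs(mean(spline_effect(fit, "mu1", age)$mean)), 1.0)
})
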