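test_that("wide-to-long reshape is faithful and invertible", {
  d <- as.data.frame(fixture_survey(n = 12))
  one <- d[1, ]
  one$motivation_vaccine_self <- 3L
  one$motivation_vaccine_others <- 4L
  one$motivation_cta_self <- 2L
  one$motivation_cta_others <- 2L
  long1 <- reshape_motivation_long(one)
  expect_equal(nrow(long1), 4L)
  expect_equal(long1$response[long1$measure_type == "COVID-19 vaccine" &
                                long1$motivation_target == "for myself"], 3L)
  expect_equal(long1$response[long1$measure_type == "CTA Immuni" &
                                long1$motivation_target == "for others"], 2L)
  expect_equal(levels(long1$measure_type)[1], "CTA Immuni")
  expect_equal(levels(long1$motivation_target)[1], "for others")

  long <- reshape_motivation_long(d)
  expect_equal(nrow(long), 4L * nrow(d))
  # reconstruct the wide items: round trip is lossless
  back <- sapply(seq_len(nrow(d)), function(i) {
    rows <- long[long$subject_id == d$respondent_id[i], ]
    c(rows$response[rows$measure_type == "COVID-19 vaccine" &
                      rows$motivation_target == "for myself"],
      rows$response[rows$measure_type == "COVID-19 vaccine" &
                      rows$motivation_target == "for others"],
      rows$response[rows$measure_type == "CTA Immuni" &
                      rows$motivation_target == "for myself"],
      rows$response[rows$measure_type == "CTA Immuni" &
                      rows$motivation_target == "for others"])
  })
  expect_equal(back[1, ], as.integer(d$motivation_vaccine_self))
  expect_equal(back[2, ], as.integer(d$motivation_vaccine_others))
  expect_equal(back[3, ], as.integer(d$motivation_cta_self))
  expect_equal(back[4, ], as.integer(d$motivation_cta_others))

  dup <- d[c(1, 1), ]
  expect_error(reshape_motivation_long(dup), "duplicated")
})

test_that("category probabilities telescope to one and are location-invariant", {
  theta <- c(-1.2, 0.3, 1.7)
  eta <- 0.4
  gam <- -0.8
  p <- diff(c(0, plogis(theta - eta - gam), 1))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # shifting thresholds and linear predictor together changes nothing
  set.seed(81)
  d <- generate_ordinal_data(theta = c(-1, 0, 1), beta = c(1, -0.5),
                             sigma_gamma = 1, n_subjects = 40, seed = 81)
  X <- cbind(measure = as.integer(d$measure_type) - 1,
             target = as.integer(d$motivation_target) - 1)
  ll0 <- cumlogit_loglik(c(-1, 0, 1), c(1, -0.5), 1, X, d$response,
                         d$subject_id)
  Xc <- cbind(X, const = 1)
  llc <- cumlogit_loglik(c(-1, 0, 1) + 5, c(1, -0.5, 5), 1, Xc, d$response,
                         d$subject_id)
  expect_equal(llc, ll0, tolerance = 1e-8)
  expect_error(cumlogit_loglik(c(1, 0, 2), c(1, -0.5), 1, X, d$response,
                               d$subject_id), "increasing")
})

test_that("Gauss-Hermite marginal likelihood matches brute-force integration", {
  set.seed(82)
  d <- generate_ordinal_data(theta = c(-1, 0, 1), beta = c(1, -0.3),
                             sigma_gamma = 1, n_subjects = 5, seed = 82)
  X <- cbind(as.integer(d$measure_type) - 1,
             as.integer(d$motivation_target) - 1)
  theta <- c(-0.8, 0.1, 1.2)
  beta <- c(0.7, -0.2)
  agq <- cumlogit_loglik(theta, beta, 1, X, d$response, d$subject_id,
                         n_quad = 25L)
  brute <- oracle_mixed_loglik(theta, beta, 1, X, d$response, d$subject_id)
  expect_equal(agq, brute, tolerance = 1e-6)

  # doubling the node count changes nothing appreciable
  agq2 <- cumlogit_loglik(theta, beta, 1, X, d$response, d$subject_id,
                          n_quad = 50L)
  expect_lt(abs(agq2 - agq), 1e-8)

  # sigma = 0 reduces exactly to the fixed-effects likelihood
  eta <- drop(X %*% beta)
  up <- c(theta, Inf)[d$response]
  lo <- c(-Inf, theta)[d$response]
  fixed <- sum(log(plogis(up - eta) - plogis(lo - eta)))
  expect_identical(cumlogit_loglik(theta, beta, 0, X, d$response,
                                   d$subject_id), fixed)
})

test_that("null data give near-zero effects and closed-form thresholds", {
  set.seed(83)
  d <- generate_ordinal_data(theta = c(-1, 0, 1), beta = c(0, 0),
                             sigma_gamma = 0, n_subjects = 1500, seed = 83)
  fit <- fit_cumlogit(d, random_intercept = FALSE)
  expect_true(all(abs(fit$beta) < 0.2))
  freq <- cumsum(tabulate(d$response, 4) / nrow(d))[1:3]
  # against the saturated (intercept-only) cutpoints from category frequencies
  fit0 <- fit_cumlogit(d, covariates = character(), random_intercept = FALSE)
  expect_equal(unname(fit0$theta), qlogis(freq), tolerance = 1e-4)
})

test_that("fixed-effects variant matches MASS::polr", {
  set.seed(84)
  d <- generate_ordinal_data(theta = c(-1.2, 0, 1.4), beta = c(0.9, -0.5),
                             sigma_gamma = 0, n_subjects = 600, seed = 84)
  fit <- fit_cumlogit(d, random_intercept = FALSE)
  pol <- MASS::polr(factor(response) ~ measure_type + motivation_target,
                    data = d)
  expect_equal(unname(fit$beta), unname(coef(pol)), tolerance = 1e-3)
  expect_equal(unname(fit$theta), unname(pol$zeta), tolerance = 1e-3)
  expect_equal(fit$aic, AIC(pol), tolerance = 0.01)
})

test_that("proportional-odds structure holds on fitted probabilities", {
  set.seed(85)
  d <- generate_ordinal_data(theta = c(-1, 0.2, 1.3), beta = c(1, -0.4),
                             sigma_gamma = 1, n_subjects = 200, seed = 85)
  fit <- fit_cumlogit(d)
  X <- unique(cbind(as.integer(d$measure_type) - 1,
                    as.integer(d$motivation_target) - 1))
  for (i in seq_len(nrow(X))) {
    cum <- plogis(fit$theta - drop(X[i, ] %*% fit$beta))
    expect_true(!is.unsorted(cum))
    expect_true(all(cum > 0 & cum < 1))
  }
})

test_that("odds-ratio table: references, thresholds, null coverage", {
  set.seed(86)
  d <- generate_ordinal_data(theta = c(-1, 0, 1), beta = c(0, 0),
                             sigma_gamma = 0.5, n_subjects = 300, seed = 86)
  fit <- fit_cumlogit(d)
  tab <- odds_ratios(fit)
  refs <- tab[tab$reference, ]
  expect_equal(refs$or, c(1, 1))
  expect_true(all(is.na(refs$ci_low)))
  expect_match(tab$term[1], "Intercept 1\\|2")
  nonref <- tab[!tab$reference & !startsWith(tab$term, "Intercept"), ]
  expect_true(all(nonref$ci_low < 1 & nonref$ci_high > 1))  # null data
  expect_true(all(tab$ci_low <= tab$ci_high, na.rm = TRUE))
})

test_that("adding a pure-noise covariate usually increases AIC", {
  worse <- 0L
  for (r in 1:20) {
    d <- generate_ordinal_data(theta = c(-1, 0, 1), beta = c(1, -0.4),
                               sigma_gamma = 0, n_subjects = 80,
                               seed = 860 + r)
    set.seed(8600 + r)
    d$noise <- rnorm(nrow(d))
    f0 <- fit_cumlogit(d, random_intercept = FALSE)
    f1 <- fit_cumlogit(d, covariates = c("measure_type", "motivation_target",
                                         "noise"),
                       random_intercept = FALSE)
    worse <- worse + (f1$aic > f0$aic)
  }
  expect_gt(worse, 10L)
})

test_that("conspiracy model is fixed-effects and rejects constant outcomes", {
  d <- fixture_survey(n = 200)
  d$doubts_cat <- categorize_doubts(d$vaccine_doubts)$categories
  res <- fit_conspiracy(d, covariates = c("gender", "doubts_cat"))
  expect_false(res$fit$random_intercept)
  expect_equal(res$fit$sigma_gamma, 0)
  expect_equal(res$fit$K, max(as.integer(d$conspiracy)))
  expect_true(any(res$or_table$reference))

  flat <- as.data.frame(d)
  flat$conspiracy <- 4
  expect_error(fit_conspiracy(flat, covariates = "gender"), "constant")
})
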