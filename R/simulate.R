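#' Configuration of the synthetic survey generator
#'
#' Defaults emulate the study conditions the analysis assumes: 448
#' respondents, 70.8% female, age 33.8 +/- 13.9 years, a zero-inflated
#' vaccine-doubts score (about 22% exact zeros), boundary-clustered 0-100
#' intention scores generated from the bivariate Gaussian law with positive
#' cross-outcome correlation, one latent factor behind each 3-item
#' risk/trust block (loadings calibrated so the one-factor solutions explain
#' about 60% and 71% of the item variance, scare/severity weighted above
#' infection likelihood, trust in science highest), and Likert motivation
#' items tied positively to perceived risk through the ordinal law.
#'
#' The generation-scale design vector for the intentions is
#' `(1, doubts/100, risk factor, trust factor, flu vaccine)`.
#'
#' @param n Respondent count.
#' @param female_prop Proportion of female respondents.
#' @param age_mean,age_sd Age distribution in years (truncated at 18-85).
#' @param doubts_zero_prob Point mass at zero of the doubts score.
#' @param loadings_risk,loadings_trust Length-3 loading vectors of the two
#'   item blocks (unit-variance latent factors; uniquenesses
#'   `1 - loading^2`).
#' @param beta1,beta2 True location coefficients (COVID-19 vaccine,
#'   contact-tracing app) on the generation design.
#' @param gamma1,gamma2 True log-scale coefficients.
#' @param beta3 True rhogit-scale correlation coefficients.
#' @param theta_motivation Increasing thresholds of the motivation model.
#' @param beta_motivation Named effects: `measure` (COVID-19 vaccine vs CTA),
#'   `self` (for myself vs for others), `risk` (per unit latent risk
#'   factor).
#' @param sigma_gamma Motivation random-intercept SD.
#' @param theta_conspiracy Six thresholds of the 7-level conspiracy model.
#' @param beta_conspiracy_doubts Conspiracy effect per doubts point.
#' @param seed Integer seed; independent per-stage substreams are derived
#'   from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 448L,
                             female_prop = 0.708,
                             age_mean = 33.8, age_sd = 13.9,
                             doubts_zero_prob = 0.219,
                             loadings_risk = c(0.62, 0.82, 0.86),
                             loadings_trust = c(0.82, 0.83, 0.88),
                             beta1 = c(88, -55, 5, 3, 6),
                             beta2 = c(55, -15, 8, 10, 3),
                             gamma1 = c(log(20), 0.6, 0, 0, 0),
                             gamma2 = c(log(30), 0, 0, 0, 0),
                             beta3 = c(rhogit(0.45), 0, 0, 0, 0),
                             theta_motivation = c(-2.6, -1.2, 0.4),
                             beta_motivation = c(measure = log(3),
                                                 self = log(0.71),
                                                 risk = 0.9),
                             sigma_gamma = 1.5,
                             theta_conspiracy = stats::qlogis(
                               cumsum(c(.10, .12, .15, .18, .17, .15))) + 1.25,
                             beta_conspiracy_doubts = 0.025,
                             seed = 1L) {
  stopifnot(n >= 0, female_prop >= 0, female_prop <= 1,
            doubts_zero_prob >= 0, doubts_zero_prob <= 1,
            length(loadings_risk) == 3L, length(loadings_trust) == 3L,
            length(beta1) == 5L, length(beta2) == 5L,
            length(gamma1) == 5L, length(gamma2) == 5L, length(beta3) == 5L,
            !is.unsorted(theta_motivation, strictly = TRUE),
            !is.unsorted(theta_conspiracy, strictly = TRUE))
  structure(as.list(environment()), class = "synthetic_config")
}

# independent substream: deterministic function of the master seed and stage
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 10007L) %% 2147483562L
}

#' Generate a synthetic survey dataset
#'
#' Deterministic for a fixed seed (independent per-stage substreams allow
#' stages to be regenerated in isolation). Intention scores are drawn from
#' the bivariate Gaussian distributional law given each respondent's
#' covariates and then clamped to \[0, 100\], producing the boundary spikes
#' typical of 0-100 intention sliders; motivation items come from the
#' mixed cumulative-logistic law; risk and trust item blocks load on one
#' latent factor each; the doubts score mixes a point mass at zero with a
#' scaled Beta distribution.
#'
#' @param config A [synthetic_config()].
#' @param clamp Clamp intentions to \[0, 100\]? When `FALSE` the raw
#'   latent-scale draws are returned unvalidated (useful for checking the
#'   uncensored generating law); the default `TRUE` returns a validated
#'   `survey_dataset`.
#' @return A `survey_dataset` (or raw data frame when `clamp = FALSE`).
#' @export
generate_survey <- function(config = synthetic_config(), clamp = TRUE) {
  n <- config$n
  if (n == 0L) stop("cannot generate an empty dataset (n = 0)", call. = FALSE)
  seed <- config$seed

  set.seed(stage_seed(seed, 1L))  # demographics
  gender <- ifelse(stats::runif(n) < config$female_prop, "female", "male")
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                         18), 85))
  education <- sample(c("middle school", "high school",
                        "university degree or higher"),
                      n, TRUE, prob = c(0.074, 0.440, 0.486))
  family_status <- sample(c("single", "married-living together", "other"),
                          n, TRUE, prob = c(0.49, 0.42, 0.09))
  job <- sample(c("employee", "business-owner", "retired-unemployed",
                  "student"), n, TRUE, prob = c(0.415, 0.118, 0.078, 0.389))
  salary <- sample(c("<15k", "15-55k", ">55k", "unknown"),
                   n, TRUE, prob = c(0.27, 0.44, 0.10, 0.19))
  flu <- stats::rbinom(n, 1L, 0.112)
  covid_contact <- stats::rbinom(n, 1L, 0.55)

  set.seed(stage_seed(seed, 2L))  # latent factors and item blocks
  risk_f <- stats::rnorm(n)
  trust_f <- stats::rnorm(n)
  item_block <- function(f, loadings) {
    sapply(loadings, function(l) {
      raw <- l * f + sqrt(1 - l^2) * stats::rnorm(n)
      round(pmin(pmax(50 + 18 * raw, 0), 100))
    })
  }
  risk_items <- item_block(risk_f, config$loadings_risk)
  trust_items <- item_block(trust_f, config$loadings_trust)
  trust_local <- round(100 * stats::rbeta(n, 2.2, 1.3))
  self_efficacy <- round(100 * stats::rbeta(n, 2.6, 1.1))

  set.seed(stage_seed(seed, 3L))  # zero-inflated doubts
  zero <- stats::runif(n) < config$doubts_zero_prob
  doubts <- ifelse(zero, 0, pmax(1, round(100 * stats::rbeta(n, 0.9, 1.6))))

  set.seed(stage_seed(seed, 4L))  # intentions from the bivariate law
  X <- cbind(1, doubts / 100, risk_f, trust_f, flu)
  Y <- simulate_bbg_rows(X, config$beta1, config$beta2,
                         config$gamma1, config$gamma2, config$beta3)
  if (clamp) Y <- round(pmin(pmax(Y, 0), 100))

  set.seed(stage_seed(seed, 5L))  # motivation items from the ordinal law
  bm <- config$beta_motivation
  gam <- stats::rnorm(n, 0, config$sigma_gamma)
  draw_mot <- function(measure, self) {
    eta <- bm[["measure"]] * measure + bm[["self"]] * self +
      bm[["risk"]] * risk_f + gam
    draw_ordinal(config$theta_motivation, eta)
  }
  mot_cta_others <- draw_mot(0, 0)
  mot_cta_self <- draw_mot(0, 1)
  mot_vac_others <- draw_mot(1, 0)
  mot_vac_self <- draw_mot(1, 1)

  set.seed(stage_seed(seed, 6L))  # conspiracy beliefs
  conspiracy <- draw_ordinal(config$theta_conspiracy,
                             config$beta_conspiracy_doubts * (doubts - 30))

  out <- data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    vaccine_intent = Y[, 1], cta_intent = Y[, 2],
    motivation_vaccine_self = mot_vac_self,
    motivation_vaccine_others = mot_vac_others,
    motivation_cta_self = mot_cta_self,
    motivation_cta_others = mot_cta_others,
    risk_likelihood = risk_items[, 1],
    risk_severity = risk_items[, 2],
    risk_scare = risk_items[, 3],
    trust_international = trust_items[, 1],
    trust_national = trust_items[, 2],
    trust_scientific = trust_items[, 3],
    trust_local = trust_local,
    self_efficacy = self_efficacy,
    vaccine_doubts = doubts,
    flu_vaccine_2019 = flu,
    conspiracy = conspiracy,
    gender = gender, age = age, education = education,
    family_status = family_status, job = job, salary = salary,
    covid_contact = covid_contact,
    stringsAsFactors = FALSE)
  if (!clamp) return(out)
  validate_survey(out)
}

# one ordinal draw per element of eta under logit P(Y<=k) = theta_k - eta
draw_ordinal <- function(theta, eta) {
  cum <- stats::plogis(outer(eta, theta, function(e, t) t - e))
  1L + rowSums(stats::runif(length(eta)) > cum)
}

# bivariate Gaussian rows with observation-specific mu, sigma, rho
simulate_bbg_rows <- function(X, beta1, beta2, gamma1, gamma2, beta3) {
  mu1 <- drop(X %*% beta1)
  mu2 <- drop(X %*% beta2)
  s1 <- exp(drop(X %*% gamma1))
  s2 <- exp(drop(X %*% gamma2))
  rho <- rhogit_inv(drop(X %*% beta3))
  z1 <- stats::rnorm(nrow(X))
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nrow(X))
  cbind(mu1 + s1 * z1, mu2 + s2 * z2)
}

#' Simulate paired outcomes from the bivariate distributional law
#'
#' Direct simulation from the model's own law (no clamping): each row is an
#' independent bivariate normal draw with location, scale and correlation
#' given by its design row through the identity, log and inverse-rhogit
#' links. Used for parameter-recovery and coverage tests.
#'
#' @param beta1,beta2,gamma1,gamma2,beta3 True coefficient vectors, lengths
#'   matching `ncol(X)` blockwise.
#' @param X Design matrix (including an intercept column), shared by all
#'   five parameter blocks.
#' @param n Number of rows to draw (`X` is recycled by row if it has fewer
#'   rows than `n`).
#' @param seed Integer seed.
#' @return A list with `y` (n x 2 matrix) and `X`.
#' @export
generate_bbg_data <- function(beta1, beta2, gamma1, gamma2, beta3, X,
                              n = nrow(X), seed = 1L) {
  X <- as.matrix(X)
  for (b in list(beta1, beta2, gamma1, gamma2, beta3)) {
    if (length(b) != ncol(X)) {
      stop("coefficient length ", length(b), " does not match ", ncol(X),
           " design columns", call. = FALSE)
    }
  }
  if (nrow(X) < n) X <- X[rep_len(seq_len(nrow(X)), n), , drop = FALSE]
  set.seed(seed)
  list(y = simulate_bbg_rows(X, beta1, beta2, gamma1, gamma2, beta3), X = X)
}

#' Simulate long-format ordinal responses with a subject random intercept
#'
#' Each subject draws one Gaussian intercept shared by all of its
#' responses; responses follow the cumulative logistic law
#' \eqn{\mathrm{logit} P(Y \le k) = \theta_k - (x^\top\beta + \gamma)}.
#' With 4 responses per subject the rows carry the 2x2 measure-type by
#' protection-target crossing and `beta` is `(measure, target)`; otherwise
#' supply `X` directly.
#'
#' @param theta Strictly increasing thresholds.
#' @param beta Fixed effects (length 2 for the default crossing; length 0
#'   for a null model; or `ncol(X)` when `X` is given).
#' @param sigma_gamma Random-intercept SD (>= 0).
#' @param n_subjects Number of subjects.
#' @param responses_per_subject Rows per subject (default 4).
#' @param seed Integer seed.
#' @param X Optional design matrix (`n_subjects * responses_per_subject`
#'   rows, no intercept column).
#' @return Long data frame: `subject_id`, `response`, plus either the
#'   crossing columns or the supplied design columns.
#' @export
generate_ordinal_data <- function(theta, beta = numeric(0), sigma_gamma = 1,
                                  n_subjects = 100L,
                                  responses_per_subject = 4L,
                                  seed = 1L, X = NULL) {
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  stopifnot(sigma_gamma >= 0, n_subjects >= 1L)
  nr <- n_subjects * responses_per_subject
  subject <- rep(seq_len(n_subjects), each = responses_per_subject)
  crossing <- NULL
  if (is.null(X)) {
    if (responses_per_subject == 4L && length(beta) == 2L) {
      crossing <- data.frame(
        measure_type = factor(rep(c("CTA Immuni", "CTA Immuni",
                                    "COVID-19 vaccine", "COVID-19 vaccine"),
                                  n_subjects),
                              levels = c("CTA Immuni", "COVID-19 vaccine")),
        motivation_target = factor(rep(c("for others", "for myself"),
                                       2L * n_subjects),
                                   levels = c("for others", "for myself")))
      X <- cbind(measure = as.integer(crossing$measure_type) - 1L,
                 target = as.integer(crossing$motivation_target) - 1L)
    } else if (length(beta) == 0L) {
      X <- matrix(0, nr, 0)
    } else {
      stop("supply X for this beta/responses combination", call. = FALSE)
    }
  }
  X <- as.matrix(X)
  stopifnot(nrow(X) == nr, ncol(X) == length(beta))
  set.seed(seed)
  gam <- stats::rnorm(n_subjects, 0, sigma_gamma)
  eta <- (if (length(beta)) drop(X %*% beta) else numeric(nr)) + gam[subject]
  out <- data.frame(subject_id = subject,
                    response = draw_ordinal(theta, eta))
  if (!is.null(crossing)) out <- cbind(out, crossing)
  out
}
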