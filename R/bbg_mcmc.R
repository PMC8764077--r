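#' MCMC configuration for the bivariate model
#'
#' @param iterations Total MCMC iterations (default 10000).
#' @param burnin Iterations discarded as burn-in (default 1000); proposal
#'   scales adapt only during burn-in.
#' @param seed Integer seed; every run records it.
#' @param target_accept Target acceptance rate of the blockwise random-walk
#'   proposals during adaptation.
#' @return A list of class `bbg_mcmc_config`.
#' @export
bbg_mcmc_config <- function(iterations = 10000L, burnin = 1000L,
                            seed = 1L, target_accept = 0.234) {
  stopifnot(iterations > burnin, burnin >= 0L)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 seed = as.integer(seed),
                 target_accept = target_accept),
            class = "bbg_mcmc_config")
}

#' Posterior sampling for the bivariate distributional regression
#'
#' Blockwise adaptive random-walk Metropolis over the five coefficient
#' blocks, started at the maximum-likelihood estimate with proposal
#' covariances taken from the corresponding blocks of the ML covariance
#' (scaled by \eqn{2.38^2/d}). Priors are improper flat on all regression
#' coefficients; spline blocks carry the Gaussian roughness penalty as their
#' prior, with smoothing parameters fixed at their design-time (REML)
#' values. Scale factors adapt by Robbins-Monro during burn-in only, so the
#' retained chain is a valid Markov chain.
#'
#' @param ml_fit A [fit_bbg_ml()] result.
#' @param config A [bbg_mcmc_config()].
#' @return A `bbg_fit` list: `draws` (retained iterations x parameters),
#'   `deviance` (-2 log-likelihood trace, unpenalized), `acceptance` per
#'   block, plus the ML fit, designs and config.
#' @export
run_bbg_mcmc <- function(ml_fit, config = bbg_mcmc_config()) {
  designs <- ml_fit$designs
  y <- ml_fit$y
  idx <- designs$idx
  set.seed(config$seed)

  # blockwise proposal Cholesky factors from the ML covariance
  prop <- lapply(idx, function(ii) {
    V <- ml_fit$vcov[ii, ii, drop = FALSE]
    V <- (V + t(V)) / 2
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) L <- diag(sqrt(pmax(diag(V), 1e-8)), nrow = length(ii))
    t(L)
  })
  lscale <- vapply(idx, function(ii) log(2.38 / sqrt(length(ii))), numeric(1))

  theta <- unname(ml_fit$par)
  ll <- bbg_loglik(theta, designs, y, penalized = TRUE)
  n_keep <- config$iterations - config$burnin
  draws <- matrix(NA_real_, n_keep, length(theta))
  deviance <- numeric(n_keep)
  acc <- integer(length(idx))
  tries <- integer(length(idx))
  accept_rate_fail <- FALSE

  for (t in seq_len(config$iterations)) {
    for (b in seq_along(idx)) {
      ii <- idx[[b]]
      cand <- theta
      cand[ii] <- cand[ii] +
        exp(lscale[b]) * drop(prop[[b]] %*% stats::rnorm(length(ii)))
      ll_cand <- tryCatch(bbg_loglik(cand, designs, y, penalized = TRUE),
                          error = function(e) -Inf)
      accepted <- log(stats::runif(1)) < (ll_cand - ll)
      if (accepted) {
        theta <- cand
        ll <- ll_cand
      }
      if (t <= config$burnin) {
        lscale[b] <- lscale[b] +
          t^(-0.6) * ((if (accepted) 1 else 0) - config$target_accept)
      } else {
        acc[b] <- acc[b] + accepted
        tries[b] <- tries[b] + 1L
      }
    }
    if (t > config$burnin) {
      k <- t - config$burnin
      draws[k, ] <- theta
      deviance[k] <- -2 * (ll + penalty_value(theta, designs))
    }
  }
  rates <- acc / pmax(tries, 1L)
  if (any(rates < 0.01)) {
    stop("sampler failure: post-adaptation acceptance rate below 1% in block ",
         block_names[which(rates < 0.01)[1]], call. = FALSE)
  }
  colnames(draws) <- designs$terms
  structure(list(draws = draws, deviance = deviance,
                 acceptance = stats::setNames(rates, block_names),
                 ml_fit = ml_fit, designs = designs, y = y, config = config),
            class = "bbg_fit")
}

#' Posterior summary: means, 95% credible intervals, null-exclusion flags
#'
#' @param fit A `bbg_fit` (or a bare draws matrix).
#' @return Data frame with one row per coefficient: `term`, `block`, `mean`,
#'   `q2.5`, `q97.5`, and `excludes_zero` (TRUE when the 95% CrI does not
#'   contain 0, the bold-marking convention of the coefficient tables).
#' @export
summarize_bbg <- function(fit) {
  draws <- if (is.matrix(fit)) fit else fit$draws
  if (nrow(draws) < 100L) stop("need at least 100 retained draws", call. = FALSE)
  qs <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  term <- colnames(draws) %||% paste0("par", seq_len(ncol(draws)))
  out <- data.frame(term = term,
                    block = sub(":.*$", "", term),
                    mean = colMeans(draws),
                    q2.5 = qs[, 1], q97.5 = qs[, 2],
                    row.names = NULL)
  out$excludes_zero <- out$q2.5 > 0 | out$q97.5 < 0
  out
}

#' Deviance Information Criterion of a fitted bivariate model
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{D(\theta) = -2\,\ell(\theta)} the
#' unpenalized deviance, \eqn{\bar D} its posterior mean, and \eqn{p_D =
#' \bar D - D(\bar\theta)} evaluated at the posterior-mean coefficients.
#'
#' @param fit A `bbg_fit`.
#' @return A list with `dic`, `dbar`, `pd`.
#' @export
bbg_dic <- function(fit) {
  dbar <- mean(fit$deviance)
  theta_bar <- colMeans(fit$draws)
  dhat <- -2 * bbg_loglik(unname(theta_bar), fit$designs, fit$y,
                          penalized = FALSE)
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, pd = pd)
}

#' Fit the bivariate model end to end (ML + MCMC)
#'
#' @param data Data frame with outcomes and covariates.
#' @param spec A [bbg_design_spec()].
#' @param outcomes Length-2 character vector of outcome column names
#'   (first: COVID-19 vaccine intention; second: contact-tracing-app
#'   intention).
#' @param config A [bbg_mcmc_config()].
#' @return A `bbg_fit` augmented with `dic`.
#' @export
fit_bbg <- function(data, spec, outcomes = c("vaccine_intent", "cta_intent"),
                    config = bbg_mcmc_config()) {
  designs <- build_design(spec, data, outcomes = outcomes)
  y <- as.matrix(as.data.frame(data)[outcomes])
  ml <- fit_bbg_ml(designs, y)
  fit <- run_bbg_mcmc(ml, config)
  fit$dic <- bbg_dic(fit)
  fit
}

#' Forward covariate selection by DIC
#'
#' Greedy search: at each step every remaining candidate is entered
#' simultaneously in all five parameter blocks (one covariate set shared by
#' location, scale and correlation predictors), the model is refitted, and
#' the candidate giving the largest DIC reduction is kept; the search stops
#' when no candidate reduces DIC. Ties within `tie_tol` go to the candidate
#' listed earlier.
#'
#' @param data Data frame.
#' @param candidates Ordered character vector of candidate covariates.
#' @param outcomes Outcome column names.
#' @param config A [bbg_mcmc_config()]; each refit derives its own seed
#'   deterministically from `config$seed`.
#' @param spline Optional spline description, always kept in the model.
#' @param max_steps Cap on the number of forward steps.
#' @param tie_tol DIC tie tolerance (default 0.01).
#' @return List with `spec` (selected design), `selected`, and `trace`
#'   (one row per evaluated model: step, candidate, dic, selected flag).
#' @export
forward_select_bbg <- function(data, candidates,
                               outcomes = c("vaccine_intent", "cta_intent"),
                               config = bbg_mcmc_config(),
                               spline = NULL, max_steps = Inf,
                               tie_tol = 0.01) {
  stopifnot(is.character(candidates))
  fit_counter <- 0L
  fit_one <- function(covs) {
    fit_counter <<- fit_counter + 1L
    cfg <- config
    cfg$seed <- (config$seed + 7919L * fit_counter) %% .Machine$integer.max
    spec <- bbg_design_spec(covariates = covs, spline = spline)
    fit_bbg(data, spec, outcomes, cfg)$dic$dic
  }

  selected <- character()
  current_dic <- fit_one(selected)
  trace <- data.frame(step = 0L, candidate = "(intercept-only)",
                      dic = current_dic, selected = TRUE)
  remaining <- candidates
  step <- 0L
  while (length(remaining) && step < max_steps) {
    step <- step + 1L
    dics <- vapply(remaining, function(cand) fit_one(c(selected, cand)),
                   numeric(1))
    best <- min(dics)
    if (best >= current_dic) {
      trace <- rbind(trace, data.frame(step = step, candidate = remaining,
                                       dic = unname(dics), selected = FALSE))
      break
    }
    pick <- which(dics <= best + tie_tol)[1]
    trace <- rbind(trace,
                   data.frame(step = step, candidate = remaining,
                              dic = unname(dics),
                              selected = seq_along(remaining) == pick))
    selected <- c(selected, remaining[pick])
    current_dic <- dics[pick]
    remaining <- remaining[-pick]
  }
  list(spec = bbg_design_spec(covariates = selected, spline = spline),
       selected = selected, trace = trace)
}
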