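#' Log-likelihood of the bivariate Gaussian distributional regression
#'
#' Each observation contributes the bivariate normal log-density with its own
#' location vector \eqn{(\mu_1, \mu_2)}, scales \eqn{\sigma_j =
#' \exp(\eta_{\sigma_j})} and correlation \eqn{\rho = \eta_\rho /
#' \sqrt{1+\eta_\rho^2}} (inverse rhogit), all linear in their design
#' matrices. In penalized mode the spline roughness penalty
#' \eqn{(\lambda/2)\, b^\top P b} is subtracted.
#'
#' @param theta Packed coefficient vector in block order
#'   `mu1, mu2, sigma1, sigma2, rho` (see `designs$idx`).
#' @param designs A `bbg_designs` object from [build_design()].
#' @param y Two-column numeric matrix of outcomes.
#' @param penalized Subtract the roughness penalty? Default `TRUE` (no-op
#'   without spline terms).
#' @return Scalar log-likelihood.
#' @export
bbg_loglik <- function(theta, designs, y, penalized = TRUE) {
  p <- bbg_linpred(theta, designs)
  z1 <- (y[, 1] - p$mu1) / p$s1
  z2 <- (y[, 2] - p$mu2) / p$s2
  w <- 1 / (1 - p$rho^2)
  Q <- z1^2 - 2 * p$rho * z1 * z2 + z2^2
  ll_i <- -log(2 * pi) - log(p$s1) - log(p$s2) -
    0.5 * log1p(-p$rho^2) - 0.5 * w * Q
  if (!all(is.finite(ll_i))) {
    stop("non-finite log-likelihood contribution at observation ",
         which(!is.finite(ll_i))[1], call. = FALSE)
  }
  ll <- sum(ll_i)
  if (penalized) ll <- ll - penalty_value(theta, designs)
  ll
}

# observation-level parameters from the packed coefficient vector
bbg_linpred <- function(theta, designs) {
  X <- designs$X
  idx <- designs$idx
  eta_r <- drop(X$rho %*% theta[idx$rho])
  list(mu1 = drop(X$mu1 %*% theta[idx$mu1]),
       mu2 = drop(X$mu2 %*% theta[idx$mu2]),
       s1 = exp(drop(X$sigma1 %*% theta[idx$sigma1])),
       s2 = exp(drop(X$sigma2 %*% theta[idx$sigma2])),
       eta_r = eta_r,
       rho = rhogit_inv(eta_r))
}

#' Analytic gradient of [bbg_loglik()]
#' @inheritParams bbg_loglik
#' @return Gradient vector of the same length as `theta`.
#' @export
bbg_loglik_grad <- function(theta, designs, y, penalized = TRUE) {
  p <- bbg_linpred(theta, designs)
  z1 <- (y[, 1] - p$mu1) / p$s1
  z2 <- (y[, 2] - p$mu2) / p$s2
  rho <- p$rho
  w <- 1 / (1 - rho^2)
  Q <- z1^2 - 2 * rho * z1 * z2 + z2^2

  d_mu1 <- w * (z1 - rho * z2) / p$s1
  d_mu2 <- w * (z2 - rho * z1) / p$s2
  d_ls1 <- -1 + w * z1 * (z1 - rho * z2)
  d_ls2 <- -1 + w * z2 * (z2 - rho * z1)
  d_rho <- rho * w - rho * w^2 * Q + w * z1 * z2
  d_eta_r <- d_rho * rhogit_inv_deriv(p$eta_r)

  g <- unname(c(drop(crossprod(designs$X$mu1, d_mu1)),
         drop(crossprod(designs$X$mu2, d_mu2)),
         drop(crossprod(designs$X$sigma1, d_ls1)),
         drop(crossprod(designs$X$sigma2, d_ls2)),
         drop(crossprod(designs$X$rho, d_eta_r))))
  if (penalized) g <- g - penalty_grad(theta, designs)
  g
}

#' Maximum-likelihood fit of the bivariate distributional regression
#'
#' Joint BFGS maximisation of the (penalized) log-likelihood over all five
#' coefficient blocks, started from marginal least-squares fits for the
#' locations, the log residual standard deviations for the scales, and the
#' rhogit of the residual correlation for the correlation intercept. Used
#' both as a standalone estimator and as the initialisation of the MCMC
#' sampler.
#'
#' @inheritParams bbg_loglik
#' @param init Optional starting value (packed vector).
#' @param control Passed to [stats::optim()]; sensible defaults otherwise.
#' @return A `bbg_ml_fit` list: `par`, `loglik` (unpenalized), `penalized`
#'   value, `vcov` (inverse observed-information of the penalized fit),
#'   `se`, `designs`, `convergence`, `grad_norm`.
#' @export
fit_bbg_ml <- function(designs, y, init = NULL, penalized = TRUE,
                       control = list()) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2L, nrow(y) == designs$n)
  for (b in block_names) {
    qx <- qr(designs$X[[b]])
    if (qx$rank < ncol(designs$X[[b]])) {
      bad <- colnames(designs$X[[b]])[qx$pivot[-seq_len(qx$rank)]]
      stop("design for block '", b, "' is rank deficient (",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  npar <- length(unlist(designs$idx))
  if (is.null(init)) {
    init <- numeric(npar)
    f1 <- stats::lm.fit(designs$X$mu1, y[, 1])
    f2 <- stats::lm.fit(designs$X$mu2, y[, 2])
    init[designs$idx$mu1] <- f1$coefficients
    init[designs$idx$mu2] <- f2$coefficients
    init[designs$idx$sigma1][1] <- log(stats::sd(f1$residuals))
    init[designs$idx$sigma2][1] <- log(stats::sd(f2$residuals))
    r <- stats::cor(f1$residuals, f2$residuals)
    init[designs$idx$rho][1] <- rhogit(max(min(r, 0.99), -0.99))
  }
  ctrl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12), control)
  # overflow-safe wrappers: exploratory line-search steps can push exp()
  # past floating-point range; a large finite value makes BFGS retreat
  fn <- function(th) {
    v <- tryCatch(-bbg_loglik(th, designs, y, penalized),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(th) {
    g <- tryCatch(-bbg_loglik_grad(th, designs, y, penalized),
                  error = function(e) rep(NA_real_, length(th)))
    if (!all(is.finite(g))) numeric(length(th)) else g
  }
  opt <- stats::optim(init, fn = fn, gr = gr, method = "BFGS", control = ctrl)
  if (opt$convergence != 0L) {
    # one polish pass; BFGS occasionally reports maxit on flat ridges
    opt <- stats::optim(opt$par, fn = fn, gr = gr, method = "BFGS",
                        control = ctrl)
  }
  g <- bbg_loglik_grad(opt$par, designs, y, penalized)
  H <- stats::optimHess(opt$par, fn = fn, gr = gr)
  V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  par <- stats::setNames(opt$par, designs$terms)
  structure(list(par = par,
                 loglik = bbg_loglik(opt$par, designs, y, penalized = FALSE),
                 penalized_loglik = -opt$value,
                 vcov = V,
                 se = stats::setNames(sqrt(pmax(diag(V), 0)), designs$terms),
                 designs = designs, y = y,
                 convergence = opt$convergence,
                 grad_norm = sqrt(sum(g^2)) / max(1, abs(opt$value))),
            class = "bbg_ml_fit")
}
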