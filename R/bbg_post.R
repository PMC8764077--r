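#' Posterior smooth effect over a covariate grid
#'
#' Evaluates the centred spline effect (posterior mean and 95% credible
#' band) of the smoothed covariate in a chosen parameter block, typically
#' the age effect on each intention or on the rhogit-linked correlation.
#'
#' @param fit A `bbg_fit` whose design contains a spline term.
#' @param block One of `"mu1"`, `"mu2"`, `"rho"` (or a scale block if the
#'   smooth was placed there).
#' @param grid Numeric grid of covariate values; defaults to 50 points over
#'   the observed range. Values outside the observed range trigger a
#'   warning.
#' @return Data frame: `x`, `mean`, `q2.5`, `q97.5`.
#' @export
spline_effect <- function(fit, block = "mu1", grid = NULL) {
  designs <- fit$designs
  sm <- designs$smooths[[block]]
  if (is.null(sm)) stop("block '", block, "' has no spline term", call. = FALSE)
  pen <- Filter(function(p) p$block == block, designs$penalties)[[1]]
  rng <- range(designs$spline_x)
  if (is.null(grid)) {
    grid <- seq(rng[1], rng[2], length.out = 50L)
  } else if (any(grid < rng[1] | grid > rng[2])) {
    warning("grid extends beyond the observed covariate range")
  }
  Xp <- mgcv::PredictMat(sm, data.frame(x = grid))
  cols <- designs$idx[[block]][pen$cols]
  curves <- Xp %*% t(fit$draws[, cols, drop = FALSE])
  qs <- t(apply(curves, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  data.frame(x = grid, mean = rowMeans(curves),
             q2.5 = qs[, 1], q97.5 = qs[, 2])
}

#' Posterior-residual normal Q-Q table
#'
#' Standardises each observation pair by its fitted (posterior-mean)
#' location and covariance: \eqn{r = L^{-1}(y - \mu)} with \eqn{LL^\top =
#' \Sigma}, so that under the model the stacked residuals are iid standard
#' normal with zero within-pair correlation. Boundary clumping of the raw
#' 0-100 scores shows up as lower-tail departure here, as expected for a
#' Gaussian model of bounded scores.
#'
#' @param fit A `bbg_fit`.
#' @return List with `table` (data frame `theoretical`, `sample`), `slope`
#'   (robust quartile-based Q-Q slope, 1 under a correct model) and
#'   `pair_cor` (correlation of the two whitened residual coordinates).
#' @export
residual_qq <- function(fit) {
  theta <- colMeans(fit$draws)
  p <- bbg_linpred(unname(theta), fit$designs)
  y <- fit$y
  z1 <- (y[, 1] - p$mu1) / p$s1
  z2 <- (y[, 2] - p$mu2) / p$s2
  # Cholesky whitening of the standardized pair
  r1 <- z1
  r2 <- (z2 - p$rho * z1) / sqrt(1 - p$rho^2)
  r <- sort(c(r1, r2))
  th <- stats::qnorm(stats::ppoints(length(r)))
  slope <- diff(stats::quantile(r, c(0.25, 0.75), names = FALSE)) /
    diff(stats::qnorm(c(0.25, 0.75)))
  list(table = data.frame(theoretical = th, sample = r),
       slope = slope,
       pair_cor = stats::cor(r1, r2))
}
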