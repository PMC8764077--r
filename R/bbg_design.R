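#' Specify the design of a bivariate Gaussian distributional regression
#'
#' Five linear predictors are modelled: the two locations \eqn{\mu_1,
#' \mu_2}, the two log scales \eqn{\log\sigma_1, \log\sigma_2}, and the
#' rhogit-linked correlation. Each takes its own covariate list; the
#' `covariates` shortcut puts the same set in all five blocks, which is the
#' default analysis strategy of this package.
#'
#' @param covariates Character vector of covariate names entered in all five
#'   blocks (ignored when the per-block arguments are given).
#' @param mu1,mu2,sigma1,sigma2,rho Optional per-block covariate name
#'   vectors, overriding `covariates`.
#' @param spline Optional smooth-term description: a list with `variable`
#'   (numeric covariate name, typically age), `k` (basis dimension before
#'   constraint absorption, default 5), `lambda` (smoothing parameter; `NULL`
#'   to estimate by REML at design-build time) and `blocks` (which of the
#'   five predictors receive the smooth; default the two locations and the
#'   correlation).
#' @return An object of class `bbg_design_spec`.
#' @export
bbg_design_spec <- function(covariates = character(),
                            mu1 = NULL, mu2 = NULL,
                            sigma1 = NULL, sigma2 = NULL, rho = NULL,
                            spline = NULL) {
  pick <- function(x) if (is.null(x)) covariates else x
  if (!is.null(spline)) {
    spline$k <- spline$k %||% 5L
    spline$blocks <- spline$blocks %||% c("mu1", "mu2", "rho")
    stopifnot(is.character(spline$variable), spline$k >= 3L)
  }
  structure(list(blocks = list(mu1 = pick(mu1), mu2 = pick(mu2),
                               sigma1 = pick(sigma1), sigma2 = pick(sigma2),
                               rho = pick(rho)),
                 spline = spline),
            class = "bbg_design_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

block_names <- c("mu1", "mu2", "sigma1", "sigma2", "rho")

#' Build design matrices for all five distributional parameters
#'
#' Factors receive treatment (reference-level) coding, the reference being
#' the first factor level of each variable in `data`. Smooth terms use a
#' low-rank thin-plate regression spline with a sum-to-zero constraint
#' absorbed by reparameterisation, so the constrained basis columns are
#' orthogonal to the intercept.
#'
#' @param spec A [bbg_design_spec()].
#' @param data Data frame containing every named covariate (and, when a
#'   spline smoothing parameter must be estimated, the outcome columns named
#'   in `outcomes`).
#' @param outcomes Length-2 character vector naming the two response columns;
#'   only used to estimate spline smoothing parameters by REML when
#'   `spec$spline$lambda` is `NULL`.
#' @return A `bbg_designs` list: per-block model matrices `X`, a parameter
#'   index map, penalty descriptors, and stored smooth constructors for
#'   prediction.
#' @export
build_design <- function(spec, data, outcomes = c("vaccine_intent", "cta_intent")) {
  data <- as.data.frame(data)
  X <- list()
  penalties <- list()
  smooths <- list()

  sm <- NULL
  if (!is.null(spec$spline)) {
    v <- spec$spline$variable
    if (!v %in% names(data)) stop("spline variable '", v, "' not in data",
                                  call. = FALSE)
    sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = spec$spline$k),
                          data = data.frame(x = data[[v]]),
                          absorb.cons = TRUE)[[1]]
    lambda <- spec$spline$lambda
    if (is.null(lambda)) {
      lam2 <- estimate_spline_lambda(spec, data, outcomes)
      # per-block smoothing: each location uses its own outcome's REML
      # estimate; scale/correlation blocks take the geometric mean
      lambda_for <- function(b) switch(b, mu1 = lam2[1], mu2 = lam2[2],
                                       exp(mean(log(lam2))))
    } else {
      lambda_for <- function(b) lambda
    }
  }

  for (b in block_names) {
    covs <- spec$blocks[[b]]
    miss <- setdiff(covs, names(data))
    if (length(miss)) stop("covariate(s) not in data: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    f <- if (length(covs)) {
      stats::reformulate(paste0("`", covs, "`"))
    } else ~1
    Xb <- stats::model.matrix(f, data = data)
    colnames(Xb)[1] <- "(Intercept)"
    if (!is.null(sm) && b %in% spec$spline$blocks) {
      Sb <- sm$X
      colnames(Sb) <- paste0("s(", spec$spline$variable, ").", seq_len(ncol(Sb)))
      start <- ncol(Xb) + 1L
      Xb <- cbind(Xb, Sb)
      penalties[[length(penalties) + 1L]] <-
        list(block = b, cols = start:(start + ncol(Sb) - 1L),
             S = sm$S[[1]], lambda = lambda_for(b))
      smooths[[b]] <- sm
    }
    X[[b]] <- Xb
  }

  sizes <- vapply(X, ncol, integer(1))
  idx <- split(seq_len(sum(sizes)), rep(block_names, sizes))
  idx <- idx[block_names]
  terms <- unlist(lapply(block_names, function(b) {
    paste0(b, ":", colnames(X[[b]]))
  }))

  structure(list(X = X, idx = idx, terms = terms, n = nrow(data),
                 penalties = penalties, smooths = smooths,
                 spline = spec$spline,
                 spline_x = if (!is.null(sm)) data[[spec$spline$variable]],
                 spec = spec),
            class = "bbg_designs")
}

# REML smoothing parameters from marginal Gaussian additive fits to each
# outcome, rescaled to roughness penalty per unit log-likelihood
estimate_spline_lambda <- function(spec, data, outcomes) {
  v <- spec$spline$variable
  have_y <- all(outcomes %in% names(data))
  if (!have_y) return(c(1, 1))
  covs <- unique(unlist(spec$blocks[c("mu1", "mu2")]))
  rhs <- paste(c(if (length(covs)) paste0("`", covs, "`"),
                 sprintf("s(`%s`, bs = 'tp', k = %d)", v, spec$spline$k)),
               collapse = " + ")
  sps <- vapply(outcomes, function(yname) {
    f <- stats::as.formula(paste0("`", yname, "` ~ ", rhs))
    fit <- mgcv::gam(f, data = data, method = "REML")
    # mgcv reports sp on the scale of its own (scaled) penalty; rescale to a
    # roughness penalty per unit error variance for use in the joint model
    as.numeric(fit$sp[1] / fit$sig2)
  }, numeric(1))
  pmax(unname(sps), 1e-8)
}

# total roughness penalty (lambda/2) b' S b and its gradient
penalty_value <- function(theta, designs) {
  p <- 0
  for (pen in designs$penalties) {
    b <- theta[designs$idx[[pen$block]]][pen$cols]
    p <- p + 0.5 * pen$lambda * drop(crossprod(b, pen$S %*% b))
  }
  p
}

penalty_grad <- function(theta, designs) {
  g <- numeric(length(theta))
  for (pen in designs$penalties) {
    pos <- designs$idx[[pen$block]][pen$cols]
    g[pos] <- g[pos] + pen$lambda * drop(pen$S %*% theta[pos])
  }
  g
}
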