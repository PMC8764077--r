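#' Reshape motivation items to long format
#'
#' Each respondent answered four motivation items: 2 preventive measures
#' (contact-tracing app, COVID-19 vaccine) x 2 protection targets (others,
#' self). The wide columns become 4 rows per subject with `measure_type`
#' (reference "CTA Immuni") and `motivation_target` (reference "for
#' others") covariates; all other subject-level columns are carried onto
#' each row.
#'
#' @param data A validated `survey_dataset` (or any data frame with the four
#'   motivation columns and `respondent_id`).
#' @return A long data frame with `4 * nrow(data)` rows, columns
#'   `subject_id`, `measure_type`, `motivation_target`, `response`, plus the
#'   carried covariates.
#' @export
reshape_motivation_long <- function(data) {
  data <- as.data.frame(data)
  if (anyDuplicated(data$respondent_id)) {
    stop("duplicated respondent_id", call. = FALSE)
  }
  items <- c(motivation_cta_others     = "CTA Immuni|for others",
             motivation_cta_self      = "CTA Immuni|for myself",
             motivation_vaccine_others = "COVID-19 vaccine|for others",
             motivation_vaccine_self  = "COVID-19 vaccine|for myself")
  miss <- setdiff(names(items), names(data))
  if (length(miss)) stop("missing motivation column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  carry <- setdiff(names(data), c(names(items), "respondent_id"))
  blocks <- lapply(names(items), function(col) {
    lab <- strsplit(items[[col]], "|", fixed = TRUE)[[1]]
    cbind(data.frame(subject_id = data$respondent_id,
                     measure_type = lab[1],
                     motivation_target = lab[2],
                     response = as.integer(data[[col]])),
          data[carry])
  })
  long <- do.call(rbind, blocks)
  long$measure_type <- factor(long$measure_type,
                              levels = c("CTA Immuni", "COVID-19 vaccine"))
  long$motivation_target <- factor(long$motivation_target,
                                   levels = c("for others", "for myself"))
  long <- long[order(match(long$subject_id, data$respondent_id)), ]
  rownames(long) <- NULL
  long
}

# logistic density derivative f'(x) = f(x) (1 - 2 F(x))
dlogis_deriv <- function(x) stats::dlogis(x) * (1 - 2 * stats::plogis(x))

# category log-probability pieces for a cumulative logit model:
# P(Y = k) = F(theta_k - eta) - F(theta_{k-1} - eta), theta_0 = -Inf.
cumlogit_bounds <- function(theta, y) {
  K <- length(theta) + 1L
  up <- c(theta, Inf)[y]
  lo <- c(-Inf, theta)[y]
  list(up = up, lo = lo, K = K)
}

#' Marginal log-likelihood of the (mixed) cumulative logistic model
#'
#' Proportional-odds model \eqn{\mathrm{logit}\,P(Y_{ij} \le k) = \theta_k -
#' (x_{ij}^\top\beta + \gamma_j)} with subject random intercepts
#' \eqn{\gamma_j \sim N(0, \sigma_\gamma^2)} integrated out by adaptive
#' Gauss-Hermite quadrature (per-subject mode and curvature located by
#' Newton steps). With `sigma_gamma = 0` this reduces exactly to the
#' fixed-effects likelihood.
#'
#' @param theta Strictly increasing threshold vector (K-1 cutpoints).
#' @param beta Fixed-effect coefficients (length = `ncol(X)`).
#' @param sigma_gamma Random-intercept standard deviation (>= 0).
#' @param X Model matrix without intercept column.
#' @param y Integer responses in `1:K`.
#' @param subject Subject index (factor or integer) grouping the rows.
#' @param n_quad Number of quadrature nodes (default 15).
#' @return Scalar log-likelihood.
#' @export
cumlogit_loglik <- function(theta, beta, sigma_gamma, X, y, subject,
                            n_quad = 15L) {
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  eta <- if (length(beta)) drop(X %*% beta) else numeric(length(y))
  b <- cumlogit_bounds(theta, y)
  if (sigma_gamma < 1e-10) {
    p <- stats::plogis(b$up - eta) - stats::plogis(b$lo - eta)
    return(sum(log(pmax(p, 1e-300))))
  }
  subject <- as.integer(factor(subject))
  ns <- max(subject)

  gfun <- function(gam_row) {
    # per-row log prob and its first two derivatives in gamma
    u <- b$up - eta - gam_row
    l <- b$lo - eta - gam_row
    p <- pmax(stats::plogis(u) - stats::plogis(l), 1e-300)
    dp <- -(stats::dlogis(u) - stats::dlogis(l))
    d2p <- dlogis_deriv(u) - dlogis_deriv(l)
    list(logp = log(p), d1 = dp / p, d2 = d2p / p - (dp / p)^2)
  }

  # Newton search for each subject's conditional mode
  gam <- numeric(ns)
  for (it in 1:25) {
    gr <- gfun(gam[subject])
    g1 <- rowsum(gr$d1, subject)[, 1] - gam / sigma_gamma^2
    g2 <- rowsum(gr$d2, subject)[, 1] - 1 / sigma_gamma^2
    step <- g1 / g2
    step <- pmin(pmax(step, -3 * sigma_gamma), 3 * sigma_gamma)
    gam <- gam - step
    if (max(abs(step)) < 1e-10) break
  }
  gr <- gfun(gam[subject])
  curv <- -(rowsum(gr$d2, subject)[, 1] - 1 / sigma_gamma^2)
  omega <- 1 / sqrt(pmax(curv, 1e-12))

  gh <- pracma::gaussHermite(n_quad)
  # integral of exp(h(gamma)) with h = sum log p + log phi(gamma; 0, sigma^2)
  logint <- matrix(NA_real_, ns, n_quad)
  for (j in seq_len(n_quad)) {
    gj <- gam + sqrt(2) * omega * gh$x[j]
    hg <- rowsum(gfun(gj[subject])$logp, subject)[, 1] +
      stats::dnorm(gj, 0, sigma_gamma, log = TRUE)
    logint[, j] <- log(gh$w[j]) + gh$x[j]^2 + hg
  }
  m <- apply(logint, 1L, max)
  sum(m + log(rowSums(exp(logint - m))) + log(sqrt(2) * omega))
}

#' Fit a (mixed-effects) proportional-odds cumulative logistic model
#'
#' Maximum (marginal) likelihood via `nlminb` on an unconstrained
#' parameterisation (first threshold + log threshold gaps; log
#' random-intercept SD). Standard errors come from the inverse observed
#' information on the natural scale (thresholds, coefficients, log sigma).
#' Positive coefficients mean higher motivation categories are more likely,
#' so exponentiated coefficients are odds ratios of a higher response.
#'
#' @param table Long-format data frame (e.g. [reshape_motivation_long()]).
#' @param covariates Character vector of covariate columns.
#' @param response Name of the ordinal response column (integer 1..K).
#' @param subject Name of the subject-id column (grouping the random
#'   intercept).
#' @param random_intercept Include a subject-level Gaussian random
#'   intercept? (`FALSE` gives the ordinary proportional-odds model.)
#' @param n_quad Adaptive Gauss-Hermite nodes.
#' @param start Optional list with `theta`, `beta`, `sigma_gamma`.
#' @return A `cumlogit_fit`: `theta`, `beta`, `sigma_gamma`, `vcov` (natural
#'   scale), `loglik`, `aic`, `n_subjects`, term metadata.
#' @export
fit_cumlogit <- function(table, covariates = c("measure_type", "motivation_target"),
                         response = "response", subject = "subject_id",
                         random_intercept = TRUE, n_quad = 15L, start = NULL) {
  table <- droplevels(as.data.frame(table))
  y <- as.integer(table[[response]])
  K <- max(y)
  if (length(unique(y)) < 2L) {
    stop("outcome is constant; no thresholds are identifiable", call. = FALSE)
  }
  f <- if (length(covariates)) {
    stats::reformulate(paste0("`", covariates, "`"))
  } else ~1
  mf <- stats::model.frame(f, table)
  X <- stats::model.matrix(f, mf)[, -1, drop = FALSE]
  subj <- table[[subject]]
  p <- ncol(X)

  if (is.null(start)) {
    cum <- cumsum(tabulate(y, K) / length(y))[-K]
    start <- list(theta = stats::qlogis(pmin(pmax(cum, 1e-4), 1 - 1e-4)),
                  beta = numeric(p), sigma_gamma = 1)
  }
  pack <- function(theta, beta, lsig) {
    c(theta[1], log(diff(theta)), beta, if (random_intercept) lsig)
  }
  unpack <- function(par) {
    gaps <- if (K > 2L) exp(par[2:(K - 1)]) else numeric(0)
    theta <- cumsum(c(par[1], gaps))
    beta <- par[K - 1 + seq_len(p)]
    sig <- if (random_intercept) exp(par[K + p]) else 0
    list(theta = theta, beta = beta, sigma_gamma = sig)
  }
  negll <- function(par) {
    q <- unpack(par)
    -cumlogit_loglik(q$theta, q$beta, q$sigma_gamma, X, y, subj, n_quad)
  }
  opt <- stats::nlminb(pack(start$theta, start$beta, log(max(start$sigma_gamma, 0.05))),
                       negll, control = list(iter.max = 500L, eval.max = 1000L))
  q <- unpack(opt$par)
  npar <- (K - 1) + p + as.integer(random_intercept)

  # observed information on the natural scale
  nat <- c(q$theta, q$beta, if (random_intercept) log(q$sigma_gamma))
  negll_nat <- function(v) {
    theta <- v[seq_len(K - 1)]
    if (is.unsorted(theta, strictly = TRUE)) return(1e10)
    beta <- v[K - 1 + seq_len(p)]
    sig <- if (random_intercept) exp(v[K + p]) else 0
    -cumlogit_loglik(theta, beta, sig, X, y, subj, n_quad)
  }
  H <- stats::optimHess(nat, negll_nat)
  V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  term_names <- c(paste0("Intercept ", seq_len(K - 1), "|", 2:K),
                  colnames(X), if (random_intercept) "log(sigma_gamma)")
  dimnames(V) <- list(term_names, term_names)

  structure(list(theta = stats::setNames(q$theta,
                                         paste0("Intercept ", seq_len(K - 1), "|", 2:K)),
                 beta = stats::setNames(q$beta, colnames(X)),
                 sigma_gamma = q$sigma_gamma,
                 random_intercept = random_intercept,
                 vcov = V, loglik = -opt$objective,
                 aic = 2 * opt$objective + 2 * npar,
                 K = K, n = length(y),
                 n_subjects = length(unique(subj)),
                 xlevels = stats::.getXlevels(stats::terms(f), mf),
                 covariates = covariates,
                 convergence = opt$convergence),
            class = "cumlogit_fit")
}

#' Odds-ratio table with Wald 95% confidence intervals
#'
#' Exponentiates thresholds and fixed-effect coefficients; factor reference
#' levels appear as OR 1.00 rows with empty intervals, matching the usual
#' reporting layout of proportional-odds fits.
#'
#' @param fit A `cumlogit_fit`.
#' @return Data frame: `term`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `reference` flag.
#' @export
odds_ratios <- function(fit) {
  est <- c(fit$theta, fit$beta)
  keep <- seq_along(est)
  se <- sqrt(pmax(diag(fit$vcov)[keep], 0))
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(term = names(est), or = exp(est),
                    ci_low = exp(est - 1.96 * se),
                    ci_high = exp(est + 1.96 * se),
                    p_value = pv, reference = FALSE,
                    row.names = NULL)
  # insert reference rows ahead of each factor's contrast rows
  for (v in rev(names(fit$xlevels))) {
    ref <- fit$xlevels[[v]][1]
    pos <- which(startsWith(out$term, v))[1]
    refrow <- data.frame(term = paste0(v, ref, " (reference)"), or = 1,
                         ci_low = NA_real_, ci_high = NA_real_,
                         p_value = NA_real_, reference = TRUE)
    out <- if (is.na(pos)) rbind(out, refrow) else
      rbind(out[seq_len(pos - 1L), ], refrow,
            out[pos:nrow(out), ])
  }
  rownames(out) <- NULL
  out
}

#' Proportional-odds model of conspiracy beliefs (no random intercept)
#'
#' The 1-7 conspiracy score is modelled at the respondent level with a
#' fixed-effects cumulative logistic regression; same odds-ratio reporting
#' as the motivation model.
#'
#' @param data A validated `survey_dataset` with a `conspiracy` column and
#'   the requested covariates.
#' @param covariates Character vector of covariate columns.
#' @return List with `fit` (a `cumlogit_fit`) and `or_table`.
#' @export
fit_conspiracy <- function(data, covariates = c("gender", "trust_cat", "doubts_cat")) {
  data <- as.data.frame(data)
  tab <- data
  tab$response <- as.integer(tab$conspiracy)
  tab$subject_id <- data$respondent_id
  fit <- fit_cumlogit(tab, covariates = covariates,
                      random_intercept = FALSE)
  list(fit = fit, or_table = odds_ratios(fit))
}
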