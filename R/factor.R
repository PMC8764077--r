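#' Maximum-likelihood single-factor model on a 3-item block
#'
#' Fits the one-factor model \eqn{\Sigma = \lambda\lambda^\top +
#' \mathrm{diag}(\psi)} to the empirical variance-covariance matrix of three
#' items (perceived-risk or trust blocks) by minimising the normal-theory
#' discrepancy \eqn{F = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| -
#' p}. The loading sign is fixed so the loading sum is positive. Variance
#' explained is \eqn{\sum_i \lambda_i^2 / \mathrm{tr}(S)}. Uniquenesses are
#' floored at \eqn{10^{-3}} of each item variance; hitting the floor (a
#' Heywood case) raises a warning.
#'
#' @param items Data frame or matrix with 3 numeric columns, n >= 10 rows.
#' @param standardize Fit on the correlation matrix instead (items scaled to
#'   unit variance)? Default `FALSE`: the covariance matrix is used.
#' @return A `factor_model` list: `item_names`, `loadings`, `uniquenesses`,
#'   `variance_explained`, `score_coefficients` (Thomson regression
#'   weights), `centering`, `scaling`, `discrepancy`.
#' @export
fit_single_factor <- function(items, standardize = FALSE) {
  items <- as.matrix(items)
  if (ncol(items) != 3L) stop("expected exactly 3 items", call. = FALSE)
  if (nrow(items) < 10L) stop("need at least 10 rows", call. = FALSE)
  centering <- colMeans(items)
  scaling <- if (standardize) apply(items, 2L, stats::sd) else rep(1, 3L)
  Z <- sweep(sweep(items, 2L, centering), 2L, scaling, "/")
  S <- stats::cov(Z)
  if (abs(det(S)) < 1e-12 * prod(diag(S))) {
    stop("singular item covariance matrix", call. = FALSE)
  }
  floor_psi <- 1e-3 * diag(S)

  # principal-axis start
  e <- eigen(S, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(e$values[1])
  psi0 <- pmax(diag(S) - lam0^2, 2 * floor_psi)

  discrepancy <- function(par) {
    lam <- par[1:3]
    psi <- floor_psi + exp(par[4:6])
    Sig <- tcrossprod(lam) + diag(psi)
    d <- determinant(Sig, logarithm = TRUE)$modulus
    as.numeric(d) + sum(diag(solve(Sig, S))) -
      as.numeric(determinant(S, logarithm = TRUE)$modulus) - 3
  }
  opt <- stats::optim(unname(c(lam0, log(pmax(psi0 - floor_psi, 1e-6)))),
                      discrepancy, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  lam <- opt$par[1:3]
  psi_free <- exp(opt$par[4:6])
  if (any(psi_free < 1e-6 * diag(S))) {
    warning("Heywood case: uniqueness floored at 1e-3 of the item variance")
  }
  psi <- floor_psi + psi_free
  if (sum(lam) < 0) lam <- -lam

  Sig <- tcrossprod(lam) + diag(psi)
  structure(list(item_names = colnames(items) %||% paste0("item", 1:3),
                 loadings = lam,
                 uniquenesses = unname(psi),
                 variance_explained = sum(lam^2) / sum(diag(S)),
                 score_coefficients = drop(solve(Sig, lam)),
                 centering = centering, scaling = scaling,
                 discrepancy = opt$value,
                 S = S),
            class = "factor_model")
}

#' Thomson (regression) factor scores
#'
#' \eqn{\hat f = \lambda^\top \Sigma^{-1} (x - \bar x)} per respondent;
#' scores average (approximately) zero over the fitting sample.
#'
#' @param model A [fit_single_factor()] result.
#' @param items Item table with the same 3 columns, in the same order.
#' @return Numeric vector of factor scores.
#' @export
compute_scores <- function(model, items) {
  items <- as.matrix(items)
  if (ncol(items) != 3L) stop("expected exactly 3 items", call. = FALSE)
  nm <- colnames(items)
  if (!is.null(nm) && !identical(nm, model$item_names)) {
    stop("item columns do not match the fitted model (expected ",
         paste(model$item_names, collapse = ", "), ")", call. = FALSE)
  }
  Z <- sweep(sweep(items, 2L, model$centering), 2L, model$scaling, "/")
  drop(Z %*% model$score_coefficients)
}

#' Tercile coding of a continuous score
#'
#' Category bounds sit at the 1/3 and 2/3 empirical quantiles (inverse-ECDF,
#' i.e. observed values), with lower-open/upper-closed intervals: a value
#' equal to a bound goes to the lower-indexed category.
#'
#' @param scores Numeric vector, n >= 3.
#' @param labels Three category labels, low to high.
#' @param variable Name recorded in the coding.
#' @return List of class `categorical_coding`: `variable`, `labels`,
#'   `bounds` (outer min, two cutpoints, outer max), `categories` (factor of
#'   length n), `zero_inflated = FALSE`.
#' @export
categorize_terciles <- function(scores, labels = c("Low", "Medium", "High"),
                                variable = "score") {
  stopifnot(length(labels) == 3L)
  if (length(scores) < 3L) stop("need at least 3 scores", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("all scores identical: degenerate single-category coding")
    cats <- factor(rep(labels[1], length(scores)), levels = labels)
    return(structure(list(variable = variable, labels = labels,
                          bounds = rep(scores[1], 4L), categories = cats,
                          zero_inflated = FALSE),
                     class = "categorical_coding"))
  }
  cuts <- stats::quantile(scores, c(1, 2) / 3, type = 1L, names = FALSE)
  if (min(table(cut(scores, c(-Inf, cuts, Inf)))) == 0 ||
      anyDuplicated(cuts)) {
    warning("heavy ties at a tercile boundary: categories are unbalanced")
    cuts <- unique(cuts)
  }
  breaks <- unique(c(-Inf, cuts, Inf))
  cats <- cut(scores, breaks = breaks, labels = labels[seq_len(length(breaks) - 1L)],
              right = TRUE)
  structure(list(variable = variable, labels = labels,
                 bounds = c(min(scores), cuts, max(scores)),
                 categories = factor(cats, levels = labels),
                 zero_inflated = FALSE),
            class = "categorical_coding")
}

#' Zero-inflated coding of the vaccine-doubts score
#'
#' A 0-100 doubtfulness score with a point mass at zero is coded into four
#' classes: "No doubts" for exact zeros, then terciles of the strictly
#' positive values (Low/Medium/High doubts).
#'
#' @param doubts Numeric vector in \[0, 100\].
#' @param labels Labels for the three positive terciles.
#' @return A `categorical_coding` with `zero_inflated = TRUE`; `bounds`
#'   refer to the positive part.
#' @export
categorize_doubts <- function(doubts,
                              labels = c("Low doubts", "Medium doubts",
                                         "High doubts")) {
  if (any(doubts < 0 | doubts > 100)) {
    stop("doubts scores must lie in [0, 100]", call. = FALSE)
  }
  pos <- doubts[doubts > 0]
  if (!any(doubts == 0)) {
    warning("no exact zeros: 'No doubts' category is empty")
  }
  sub <- categorize_terciles(pos, labels = labels, variable = "vaccine_doubts")
  all_labels <- c("No doubts", labels)
  cats <- factor(rep("No doubts", length(doubts)), levels = all_labels)
  cats[doubts > 0] <- as.character(sub$categories)
  structure(list(variable = "vaccine_doubts",
                 labels = all_labels,
                 bounds = sub$bounds,
                 categories = cats,
                 zero_inflated = TRUE),
            class = "categorical_coding")
}

#' Printed interval labels of a categorical coding
#'
#' Formats per-category intervals in the `(lower, upper)` style used in the
#' report tables, e.g. `Medium (-0.407, 0.623)`.
#'
#' @param coding A `categorical_coding`.
#' @param digits Significant digits.
#' @return Named character vector of interval strings (tercile categories
#'   only; the zero-inflation class has no interval).
#' @export
coding_intervals <- function(coding, digits = 3L) {
  b <- signif(coding$bounds, digits)
  labs <- if (coding$zero_inflated) coding$labels[-1] else coding$labels
  ints <- sprintf("(%g, %g)", b[-length(b)], b[-1])
  stats::setNames(ints[seq_along(labs)], labs)
}
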