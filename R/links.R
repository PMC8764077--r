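#' rhogit link for a correlation parameter
#'
#' Maps a correlation \eqn{\rho \in (-1, 1)} to the real line via
#' \eqn{\rho / \sqrt{1 - \rho^2}}, so that a linear predictor for the
#' correlation of a bivariate Gaussian is unconstrained. The map is a
#' strictly increasing odd bijection; its inverse is
#' \eqn{\eta / \sqrt{1 + \eta^2}}.
#'
#' @param rho Numeric vector of correlations, all strictly inside (-1, 1).
#' @return Numeric vector of link-scale values.
#' @seealso [rhogit_inv()]
#' @export
#' @examples
#' rhogit(0.6)          # 0.75
#' rhogit_inv(rhogit(0.3))
rhogit <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop("rhogit() requires |rho| < 1", call. = FALSE)
  }
  rho / sqrt(1 - rho^2)
}

#' Inverse rhogit link
#'
#' @param eta Numeric vector on the link (real) scale.
#' @return Correlations in (-1, 1).
#' @export
rhogit_inv <- function(eta) {
  eta / sqrt(1 + eta^2)
}

# derivative d rho / d eta, used by the likelihood gradient
rhogit_inv_deriv <- function(eta) {
  (1 + eta^2)^(-1.5)
}
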