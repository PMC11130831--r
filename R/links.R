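#' Link functions for category-ratio regression
#'
#' The four link functions available for each non-baseline category
#' comparison: \code{"logit"}, \code{"probit"}, \code{"loglog"} and
#' \code{"cloglog"}.  Each is a strictly increasing differentiable bijection
#' from (0, 1) onto the real line:
#' \itemize{
#'   \item logit: \eqn{g(\rho) = \log(\rho / (1 - \rho))}
#'   \item probit: \eqn{g(\rho) = \Phi^{-1}(\rho)}
#'   \item loglog: \eqn{g(\rho) = -\log(-\log \rho)}
#'   \item cloglog: \eqn{g(\rho) = \log(-\log(1 - \rho))}
#' }
#'
#' @name links
#' @keywords internal
NULL

.MML_LINKS <- c("logit", "probit", "loglog", "cloglog")

match_link <- function(link) {
  match.arg(link, .MML_LINKS)
}

#' Apply a link function to a category ratio
#'
#' @param link One of \code{"logit"}, \code{"probit"}, \code{"loglog"},
#'   \code{"cloglog"}.
#' @param rho Numeric vector of probabilities strictly inside (0, 1).
#' @return \code{g(rho)}, a numeric vector on the real line.
#' @examples
#' link_apply("logit", 0.5)          # 0
#' link_apply("loglog", exp(-1))     # 0
#' @export
link_apply <- function(link, rho) {
  link <- match_link(link)
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1))
    stop("'rho' must lie strictly inside (0, 1)")
  switch(link,
    logit   = stats::qlogis(rho),
    probit  = stats::qnorm(rho),
    loglog  = -log(-log(rho)),
    cloglog = log(-log(1 - rho))
  )
}

#' Invert a link function
#'
#' Maps a linear predictor back to a probability.  The result is clipped to
#' \code{[eps, 1 - eps]} so that downstream logarithms stay finite; at the
#' default \code{eps = 1e-12} fitted values are unaffected at reported
#' precision.
#'
#' @inheritParams link_apply
#' @param eta Numeric vector of finite linear-predictor values.
#' @param eps Clipping distance from the {0, 1} boundary.
#' @return Probabilities in (0, 1).
#' @examples
#' link_inverse("probit", 0)   # 0.5
#' link_inverse("loglog", 0)   # exp(-1)
#' @export
link_inverse <- function(link, eta, eps = 1e-12) {
  link <- match_link(link)
  rho <- switch(link,
    logit   = stats::plogis(eta),
    probit  = stats::pnorm(eta),
    loglog  = exp(-exp(-eta)),
    cloglog = -expm1(-exp(eta))
  )
  pmin(pmax(rho, eps), 1 - eps)
}

#' Derivative of the inverse link
#'
#' Closed-form \eqn{d\rho/d\eta}, the Jacobian factor used in Fisher scoring.
#' Always positive.
#'
#' @inheritParams link_inverse
#' @return Numeric vector of derivatives.
#' @export
link_inverse_deriv <- function(link, eta) {
  link <- match_link(link)
  switch(link,
    logit   = stats::dlogis(eta),
    probit  = stats::dnorm(eta),
    loglog  = exp(-eta - exp(-eta)),
    cloglog = exp(eta - exp(eta))
  )
}
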