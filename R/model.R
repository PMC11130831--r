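#' Define a multinomial mixed-link model
#'
#' A model specification combines a response structure, one link function per
#' non-baseline category comparison, an odds assumption and the number of
#' covariates.  Under nonproportional odds (\code{"npo"}) every comparison j
#' has its own slope vector; under proportional odds (\code{"po"}) the slope
#' vector is shared, so the parameter count is
#' \eqn{p = (d+1)(J-1)} for npo and \eqn{p = d + J - 1} for po.
#'
#' @param structure One of \code{"baseline"}, \code{"cumulative"},
#'   \code{"adjacent"}, \code{"continuation"}.
#' @param links Character vector of length J-1 of link names
#'   (\code{"logit"}, \code{"probit"}, \code{"loglog"}, \code{"cloglog"}).
#' @param odds \code{"po"} (shared slopes) or \code{"npo"} (per-category
#'   slopes).
#' @param d Number of covariates (>= 0).
#' @param covariate_names Optional character vector of length \code{d} used
#'   for coefficient labels.
#' @return An object of class \code{"mml_spec"}.
#' @examples
#' # the cumulative proportional-odds model with loglog and logit links
#' mixed_link_spec("cumulative", c("loglog", "logit"), "po", d = 1)
#' @export
mixed_link_spec <- function(structure, links, odds = c("npo", "po"), d,
                            covariate_names = NULL) {
  structure <- match_structure(structure)
  links <- vapply(links, match_link, character(1), USE.NAMES = FALSE)
  odds <- match.arg(odds)
  if (length(d) != 1L || d < 0 || d != round(d))
    stop("'d' must be a non-negative integer")
  d <- as.integer(d)
  J <- length(links) + 1L
  if (J < 2L) stop("need at least one link (J >= 2)")
  if (is.null(covariate_names)) {
    covariate_names <- if (d > 0) paste0("x", seq_len(d)) else character(0)
  }
  if (length(covariate_names) != d)
    stop("'covariate_names' must have length d")
  structure(
    list(structure = structure, links = links, odds = odds, d = d, J = J,
         covariate_names = covariate_names),
    class = "mml_spec")
}

#' Number of free parameters of a model specification
#'
#' @param spec An \code{"mml_spec"} object.
#' @return \eqn{(d+1)(J-1)} for npo, \eqn{d + J - 1} for po.
#' @export
n_params <- function(spec) {
  stopifnot(inherits(spec, "mml_spec"))
  q <- spec$J - 1L
  if (spec$odds == "npo") (spec$d + 1L) * q else spec$d + q
}

#' @export
print.mml_spec <- function(x, ...) {
  cat(sprintf("Multinomial mixed-link model spec (J = %d, d = %d)\n",
              x$J, x$d))
  cat(sprintf("  structure: %s (%s)\n  links: %s\n  parameters: %d\n",
              x$structure, x$odds, paste(x$links, collapse = ", "),
              n_params(x)))
  invisible(x)
}

# coefficient labels in theta order: intercepts first, then slopes
coef_names <- function(spec) {
  q <- spec$J - 1L
  ic <- paste0("beta0_", seq_len(q))
  if (spec$d == 0L) return(ic)
  if (spec$odds == "po") {
    c(ic, spec$covariate_names)
  } else {
    c(ic, as.vector(vapply(seq_len(q), function(j)
      paste0(spec$covariate_names, "_", j), character(spec$d))))
  }
}

# split theta into intercepts beta0 (length J-1) and slope matrix B
# (d x (J-1)); for po the shared slope is recycled across columns
theta_parts <- function(spec, theta) {
  q <- spec$J - 1L
  p <- n_params(spec)
  if (length(theta) != p)
    stop(sprintf("theta must have length %d for this spec", p))
  beta0 <- theta[seq_len(q)]
  if (spec$d == 0L) {
    B <- matrix(0, 0L, q)
  } else if (spec$odds == "po") {
    B <- matrix(theta[-seq_len(q)], spec$d, q)
  } else {
    B <- matrix(theta[-seq_len(q)], spec$d, q)
  }
  list(beta0 = beta0, B = B)
}

#' Linear predictors of a mixed-link model
#'
#' \eqn{\eta_{ij} = \beta_{0j} + \beta_j^T x_i} (npo) or
#' \eqn{\beta_{0j} + \beta^T x_i} (po).
#'
#' @param spec An \code{"mml_spec"}.
#' @param theta Parameter vector: J-1 intercepts, then slopes (shared vector
#'   for po; per-comparison columns stacked for npo).
#' @param x A covariate vector of length d, or an n x d matrix.
#' @return Vector of length J-1, or an n x (J-1) matrix.
#' @export
linear_predictor <- function(spec, theta, x) {
  stopifnot(inherits(spec, "mml_spec"))
  vec <- is.null(dim(x))
  if (spec$d == 0L) {
    # intercept-only: 'x' gives the number of settings (rows)
    n <- if (vec && length(x) == 1L && is.numeric(x)) as.integer(x)
         else if (vec) 1L else nrow(as.matrix(x))
    X <- matrix(0, n, 0L)
  } else if (vec) {
    if (length(x) != spec$d) stop("covariate dimension mismatch with spec$d")
    X <- matrix(x, 1L, spec$d, byrow = TRUE)
  } else {
    X <- as.matrix(x)
  }
  if (ncol(X) != spec$d) stop("covariate dimension mismatch with spec$d")
  pr <- theta_parts(spec, theta)
  eta <- matrix(pr$beta0, nrow(X), spec$J - 1L, byrow = TRUE)
  if (spec$d > 0L) eta <- eta + X %*% pr$B
  if (vec) drop(eta) else eta
}

# eta -> rho -> pi with feasibility tracking (internal, matrix in / out)
compute_probs <- function(spec, theta, X, eps = 1e-12) {
  eta <- linear_predictor(spec, theta, X)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
  q <- spec$J - 1L
  rho <- eta
  for (j in seq_len(q))
    rho[, j] <- link_inverse(spec$links[j], eta[, j], eps = eps)
  feasible <- rep(TRUE, nrow(rho))
  if (spec$structure == "cumulative" && q > 1L) {
    mono <- rho[, -1L, drop = FALSE] > rho[, -q, drop = FALSE]
    feasible <- rowSums(!mono) == 0L
  }
  pi <- matrix(NA_real_, nrow(rho), spec$J)
  if (any(feasible)) {
    pi[feasible, ] <- .pi_from_rho_matrix(spec$structure,
                                          rho[feasible, , drop = FALSE])
  }
  list(eta = eta, rho = rho, pi = pi, feasible = feasible)
}

#' Category probabilities under a mixed-link model
#'
#' Composes the linear predictor, the inverse links and the structure
#' inversion to give the full category probability vector
#' \eqn{(\pi_1, ..., \pi_J)} at each covariate setting.
#'
#' @inheritParams linear_predictor
#' @return Probability vector of length J, or an n x J matrix.
#' @examples
#' m1 <- study_model("model1")
#' category_probs(m1$spec, m1$theta, 9515.38)
#' @export
category_probs <- function(spec, theta, x) {
  vec <- is.null(dim(x))
  cp <- compute_probs(spec, theta, x)
  if (!all(cp$feasible))
    stop(sprintf(
      "infeasible parameters: non-monotone cumulative ratios at row %d",
      which(!cp$feasible)[1L]))
  if (vec && nrow(cp$pi) == 1L) drop(cp$pi) else cp$pi
}
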