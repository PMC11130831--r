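#' Multinomial log-likelihood of a mixed-link model
#'
#' \eqn{l(\theta) = \sum_i \sum_j Y_{ij} \log \pi_{ij}(\theta)}, omitting the
#' multinomial coefficient (constant in \eqn{\theta}).  Parameter values that
#' make the model infeasible (non-monotone cumulative ratios at some setting)
#' return \code{-Inf} rather than raising, so optimizers can step-halve
#' through them.
#'
#' @param spec An \code{"mml_spec"}.
#' @param theta Parameter vector of length \code{n_params(spec)}.
#' @param data An \code{"mml_data"} sample table.
#' @return A single number, \code{-Inf} when infeasible.
#' @export
log_likelihood <- function(spec, theta, data) {
  stopifnot(inherits(spec, "mml_spec"), inherits(data, "mml_data"))
  cp <- compute_probs(spec, theta, data$X)
  if (!all(cp$feasible)) return(-Inf)
  sum(data$Y * log(cp$pi))
}

# Analytic score (gradient of log_likelihood) and expected (Fisher)
# information, both assembled from the eta-space kernel
#   C[i,k,l] = sum_j A[i,j,k] A[i,j,l] / pi[i,j],
# where A = d pi / d eta via the structure Jacobian and link derivatives.
score_info <- function(spec, theta, data, want_info = TRUE) {
  cp <- compute_probs(spec, theta, data$X)
  if (!all(cp$feasible)) return(NULL)
  q <- spec$J - 1L
  d <- spec$d
  X <- data$X
  A <- .dpi_drho(spec$structure, cp$rho, cp$pi)
  for (k in seq_len(q))
    A[, , k] <- A[, , k] * link_inverse_deriv(spec$links[k], cp$eta[, k])
  slice <- function(arr, k) {
    out <- arr[, , k, drop = FALSE]
    dim(out) <- dim(arr)[1:2]
    out
  }
  ratio <- data$Y / cp$pi                          # m x J
  U <- vapply(seq_len(q),
              function(k) rowSums(ratio * slice(A, k)),
              numeric(nrow(X)))                    # m x q
  if (nrow(X) == 1L) U <- matrix(U, nrow = 1L)
  score <- c(colSums(U),
             if (d > 0L) {
               if (spec$odds == "po") drop(crossprod(X, rowSums(U)))
               else as.vector(vapply(seq_len(q),
                 function(k) drop(crossprod(X, U[, k])), numeric(d)))
             })
  out <- list(score = score)
  if (want_info) {
    p <- n_params(spec)
    info <- matrix(0, p, p)
    invpi <- data$n_i / cp$pi                      # weights n_i / pi_ij
    Ckl <- array(0, dim = c(nrow(X), q, q))
    for (k in seq_len(q)) for (l in k:q) {
      v <- rowSums(slice(A, k) * slice(A, l) * invpi)
      Ckl[, k, l] <- v
      Ckl[, l, k] <- v
    }
    # intercept block (colSums over the sample dimension of the array)
    info[seq_len(q), seq_len(q)] <- colSums(Ckl)
    if (d > 0L) {
      if (spec$odds == "po") {
        idx <- q + seq_len(d)
        wtot <- rowSums(Ckl, dims = 1L)
        info[idx, idx] <- crossprod(X, X * wtot)
        for (k in seq_len(q)) {
          sl <- Ckl[, k, , drop = FALSE]
          dim(sl) <- c(nrow(X), q)
          info[k, idx] <- drop(crossprod(X, rowSums(sl)))
          info[idx, k] <- info[k, idx]
        }
      } else {
        for (k in seq_len(q)) for (l in seq_len(q)) {
          ik <- q + (k - 1L) * d + seq_len(d)
          il <- q + (l - 1L) * d + seq_len(d)
          info[ik, il] <- crossprod(X, X * Ckl[, k, l])
          info[k, il] <- drop(crossprod(X, Ckl[, k, l]))
          info[il, k] <- info[k, il]
        }
      }
    }
    out$info <- info
  }
  out
}

# feasible starting value: intercepts from the pooled marginal category
# frequencies mapped through the structure and links, slopes at zero
initial_theta <- function(spec, data) {
  q <- spec$J - 1L
  pbar <- colSums(data$Y) / data$n
  pbar <- pmin(pmax(pbar, 1e-6), 1 - 1e-6)
  pbar <- pbar / sum(pbar)
  rho0 <- rho_from_pi(spec$structure, pbar)
  beta0 <- vapply(seq_len(q),
                  function(j) link_apply(spec$links[j], rho0[j]), numeric(1))
  c(beta0, rep(0, n_params(spec) - q))
}

#' Fit a multinomial mixed-link model by maximum likelihood
#'
#' Fisher scoring with step-halving: each iteration solves the expected
#' information system for a Newton-type step and halves it until the
#' log-likelihood does not decrease (infeasible cumulative iterates are
#' treated as a likelihood of \code{-Inf} and halved through).  If scoring
#' stalls before the tolerances are met, a quasi-Newton (BFGS) pass with the
#' analytic gradient is tried from the current iterate.  The reported
#' covariance is the inverse observed information, computed by
#' central-difference differentiation of the analytic score; if that matrix
#' is not positive definite the expected information is used, and a
#' pseudo-inverse (with \code{singular_vcov} flagged) as last resort.
#'
#' @param spec An \code{"mml_spec"}.
#' @param data An \code{"mml_data"} sample table.
#' @param init Optional starting value; default maps the pooled category
#'   frequencies through the structure and links (slopes zero).
#' @param max_iter Maximum scoring iterations (default 200).
#' @param tol_loglik Relative log-likelihood change declaring convergence
#'   (default 1e-10).
#' @param tol_grad Gradient max-norm declaring convergence (default 1e-6).
#' @param vcov Compute the covariance matrix (default \code{TRUE}); sweeps
#'   that only need the likelihood can skip it.
#' @param trace Record the log-likelihood after every accepted iteration in
#'   the \code{loglik_trace} element (default \code{FALSE}).
#' @return An object of class \code{"mml_fit"}: \code{theta} (named),
#'   \code{loglik}, \code{vcov}, \code{converged}, \code{iterations},
#'   \code{aic}, \code{bic}, \code{n}, \code{p}, plus the spec.
#' @export
fit_mle <- function(spec, data, init = NULL, max_iter = 200L,
                    tol_loglik = 1e-10, tol_grad = 1e-6, vcov = TRUE,
                    trace = FALSE) {
  stopifnot(inherits(spec, "mml_spec"), inherits(data, "mml_data"))
  if (spec$d != data$d) stop("spec$d does not match the data")
  if (spec$J != data$J) stop("spec$J does not match the data")
  # standardize covariates for the optimization (covariates like TNSC sit
  # at scale 1e4, which makes the information matrix numerically singular
  # in the raw parameterization); results are mapped back afterwards
  q <- spec$J - 1L
  d <- spec$d
  if (d > 0L) {
    cc <- colMeans(data$X)
    cs <- apply(data$X, 2L, stats::sd)
    cs[!is.finite(cs) | cs < 1e-12] <- 1
    Z <- sweep(sweep(data$X, 2L, cc), 2L, cs, "/")
    sdata <- mml_data(Z, data$Y, data$covariate_names, data$category_labels)
  } else {
    cc <- cs <- numeric(0)
    sdata <- data
  }
  # linear map from scaled-space theta back to the raw parameterization
  unscale <- function(th) {
    if (d == 0L) return(th)
    pr <- theta_parts(spec, th)
    ncolB <- if (spec$odds == "po") 1L else q
    Bs <- matrix(th[-seq_len(q)], d, ncolB)
    B <- Bs / cs
    beta0 <- pr$beta0 - drop(crossprod(Bs, cc / cs))
    c(beta0, as.vector(B))
  }
  rescale <- function(th) {
    if (d == 0L) return(th)
    ncolB <- if (spec$odds == "po") 1L else q
    B <- matrix(th[-seq_len(q)], d, ncolB)
    Bs <- B * cs
    beta0 <- th[seq_len(q)] + drop(crossprod(B, cc))
    c(beta0, as.vector(Bs))
  }
  p <- n_params(spec)
  theta <- if (is.null(init)) initial_theta(spec, sdata) else rescale(init)
  if (length(theta) != p) stop("'init' has the wrong length")
  data_raw <- data
  data <- sdata
  ll <- log_likelihood(spec, theta, data)
  if (!is.finite(ll)) stop("starting value is infeasible")
  # scoring step and Newton decrement at a point; the decrement
  # nd2 = score' I^{-1} score / 2 approximates the attainable likelihood
  # gain, giving a scale-free convergence measure (the gradient max-norm
  # alone is not comparable across covariate scales)
  newton_state <- function(th) {
    si <- score_info(spec, th, data)
    if (is.null(si) || anyNA(si$score)) return(NULL)
    step <- tryCatch(solve(si$info, si$score), error = function(e) NULL)
    if (is.null(step))
      step <- drop(MASS::ginv(si$info) %*% si$score)
    list(score = si$score, info = si$info, step = step,
         nd2 = max(sum(si$score * step) / 2, 0))
  }
  tol_nd2 <- max(tol_grad^2, 1e-12)      # likelihood-gain tolerance
  converged <- FALSE
  iter <- 0L
  grad_norm <- Inf
  nd2 <- Inf
  exit <- "maxiter"
  flat <- 0L
  deep <- 0L
  ll_trace <- if (trace) ll else NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    ns <- newton_state(theta)
    if (is.null(ns)) { exit <- "boundary"; break }
    grad_norm <- max(abs(ns$score))
    nd2 <- ns$nd2
    if (nd2 < tol_nd2) { converged <- TRUE; exit <- "grad"; break }
    step <- ns$step
    ll_new <- -Inf
    accepted <- FALSE
    for (h in 0:30) {
      cand <- theta + step / 2^h
      ll_new <- log_likelihood(spec, cand, data)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { exit <- "stall"; break }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    theta <- cand
    ll <- ll_new
    if (trace) ll_trace <- c(ll_trace, ll)
    if (rel < tol_loglik) { exit <- "flat"; break }
    # repeated negligible gains, or steps that only survive extreme
    # halving, mean the likelihood is at its asymptote (e.g.
    # quasi-separation driving a boundary drift): stop early
    flat <- if (rel < 1e-8) flat + 1L else 0L
    deep <- if (h >= 12L) deep + 1L else 0L
    if (flat >= 5L || deep >= 3L) { exit <- "asymptote"; break }
  }
  ns <- newton_state(theta)
  if (!is.null(ns)) { grad_norm <- max(abs(ns$score)); nd2 <- ns$nd2 }
  else { grad_norm <- Inf; nd2 <- Inf }
  # quasi-Newton rescue when scoring stopped away from a stationary point
  # (failed step, boundary churn or iteration cap) while the Newton
  # decrement still promises a likelihood gain
  if (exit %in% c("stall", "asymptote", "maxiter") && nd2 > 1e-6) {
    pen_nll <- function(th) {
      v <- log_likelihood(spec, th, data)
      if (is.finite(v)) -v else 1e12
    }
    opt <- tryCatch(stats::optim(
      theta, fn = pen_nll,
      gr = function(th) {
        si <- score_info(spec, th, data, want_info = FALSE)
        if (is.null(si) || anyNA(si$score)) rep(0, p) else -si$score
      },
      method = "BFGS",
      control = list(maxit = 200L, reltol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      # optim's reported minimum can disagree with a re-evaluation when
      # the optimum sits on the feasibility boundary; only the re-check
      # is trusted
      ll_opt <- log_likelihood(spec, opt$par, data)
      if (is.finite(ll_opt) && ll_opt > ll) {
        theta <- opt$par
        ll <- ll_opt
      }
    }
    ns <- newton_state(theta)
    if (!is.null(ns)) { grad_norm <- max(abs(ns$score)); nd2 <- ns$nd2 }
    # on small instances an optimum pressed against the cumulative
    # feasibility boundary defeats gradient methods; a penalized
    # derivative-free polish (restarted simplex search from the stall
    # point and afresh) is cheap there and crawls along the boundary
    if (data$m <= 500L && nd2 > 1e-6) {
      for (st in list(theta, initial_theta(spec, data))) {
        par <- st
        for (restart in 1:3)
          par <- tryCatch(
            stats::optim(par, pen_nll, method = "Nelder-Mead",
                         control = list(maxit = 5000L,
                                        reltol = 1e-13))$par,
            error = function(e) par)
        ll_nm <- log_likelihood(spec, par, data)
        if (is.finite(ll_nm) && ll_nm > ll) {
          theta <- par
          ll <- ll_nm
        }
      }
      ns <- newton_state(theta)
      if (!is.null(ns)) { grad_norm <- max(abs(ns$score)); nd2 <- ns$nd2 }
    }
  }
  converged <- is.finite(nd2) &&
    (nd2 < tol_nd2 || (exit %in% c("flat", "grad") && nd2 < 1e-6))
  vc <- if (vcov) fit_vcov(spec, theta, data)
        else list(vcov = NULL, singular = NA)
  if (!is.null(vc$vcov) && d > 0L) {
    # delta-method transform of the covariance back to the raw scale
    Tm <- diag(p)
    if (spec$odds == "po") {
      for (k in seq_len(q)) Tm[k, q + seq_len(d)] <- -cc / cs
      for (j in seq_len(d)) Tm[q + j, q + j] <- 1 / cs[j]
    } else {
      for (k in seq_len(q)) {
        idx <- q + (k - 1L) * d + seq_len(d)
        Tm[k, idx] <- -cc / cs
        for (j in seq_len(d)) Tm[idx[j], idx[j]] <- 1 / cs[j]
      }
    }
    vc$vcov <- Tm %*% vc$vcov %*% t(Tm)
    dimnames(vc$vcov) <- list(coef_names(spec), coef_names(spec))
  }
  fit <- structure(
    list(spec = spec, theta = stats::setNames(unscale(theta),
                                              coef_names(spec)),
         loglik = ll, vcov = vc$vcov, singular_vcov = vc$singular,
         converged = converged, iterations = iter, grad_norm = grad_norm,
         n = data_raw$n, p = p,
         aic = -2 * ll + 2 * p, bic = -2 * ll + log(data_raw$n) * p),
    class = "mml_fit")
  if (trace) fit$loglik_trace <- ll_trace
  fit
}

# observed information via central differences of the analytic score;
# per-coordinate steps scaled by each coordinate's eta-sensitivity so tiny
# slopes on large covariates (e.g. TNSC in the thousands) are perturbed
# proportionately
fit_vcov <- function(spec, theta, data) {
  p <- length(theta)
  q <- spec$J - 1L
  scale <- rep(1, p)
  if (spec$d > 0L) {
    colscale <- pmax(colMeans(abs(data$X)), 1e-8)
    if (spec$odds == "po") {
      scale[q + seq_len(spec$d)] <- colscale
    } else {
      scale[-seq_len(q)] <- rep(colscale, q)
    }
  }
  h <- 1e-5 / scale
  H <- matrix(NA_real_, p, p)
  ok <- TRUE
  for (j in seq_len(p)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    sp <- score_info(spec, tp, data, want_info = FALSE)
    sm <- score_info(spec, tm, data, want_info = FALSE)
    if (is.null(sp) || is.null(sm)) { ok <- FALSE; break }
    H[, j] <- (sp$score - sm$score) / (2 * h[j])
  }
  singular <- FALSE
  vc <- NULL
  if (ok) {
    obs <- -(H + t(H)) / 2
    vc <- tryCatch(solve(obs), error = function(e) NULL)
    if (!is.null(vc) && any(diag(vc) < 0)) vc <- NULL
  }
  if (is.null(vc)) {
    si <- score_info(spec, theta, data)
    if (is.null(si)) {
      vc <- matrix(NA_real_, p, p)
      singular <- TRUE
    } else {
      vc <- tryCatch(solve(si$info), error = function(e) NULL)
      if (is.null(vc) || any(diag(vc) < 0)) {
        vc <- MASS::ginv(si$info)
        singular <- TRUE
      }
    }
  }
  dimnames(vc) <- list(coef_names(spec), coef_names(spec))
  list(vcov = vc, singular = singular)
}

#' @export
print.mml_fit <- function(x, ...) {
  cat(sprintf("Mixed-link fit: %s %s, links %s\n", x$spec$structure,
              x$spec$odds, paste(x$spec$links, collapse = "/")))
  cat(sprintf("  logLik %.4f on %d parameters (n = %d)%s\n", x$loglik, x$p,
              x$n, if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  AIC %.2f  BIC %.2f\n", x$aic, x$bic))
  print(round(x$theta, 6))
  invisible(x)
}

#' @export
coef.mml_fit <- function(object, ...) object$theta

#' @export
logLik.mml_fit <- function(object, ...) {
  structure(object$loglik, df = object$p, class = "logLik")
}

#' @export
vcov.mml_fit <- function(object, ...) object$vcov

#' Wald confidence interval and test for one coefficient
#'
#' \eqn{\hat\theta_k \mp z_{(1+level)/2} \cdot SE_k} with the two-sided
#' normal p-value for \eqn{H_0: \theta_k = 0}.
#'
#' @param model A converged \code{"mml_fit"}.
#' @param coef Coefficient index or name.
#' @param level Confidence level (default 0.95).
#' @return Named vector \code{c(estimate, lower, upper, p_value)}.
#' @export
wald_inference <- function(model, coef, level = 0.95) {
  stopifnot(inherits(model, "mml_fit"))
  if (!model$converged) stop("Wald inference requires a converged fit")
  if (is.null(model$vcov))
    stop("fit has no covariance matrix; refit with vcov = TRUE")
  if (is.character(coef)) coef <- match(coef, names(model$theta))
  if (is.na(coef) || coef < 1 || coef > model$p) stop("unknown coefficient")
  est <- unname(model$theta[coef])
  se <- sqrt(model$vcov[coef, coef])
  z <- stats::qnorm((1 + level) / 2)
  c(estimate = est, lower = est - z * se, upper = est + z * se,
    p_value = 2 * stats::pnorm(-abs(est / se)))
}

#' Serialize a fitted model to JSON
#'
#' @param model An \code{"mml_fit"}.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when written to file.
#' @export
fit_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mml_fit"))
  doc <- list(
    structure = model$spec$structure,
    links = model$spec$links,
    odds = model$spec$odds,
    J = model$spec$J,
    d = model$spec$d,
    coefficients = as.list(model$theta),
    loglik = model$loglik,
    aic = model$aic,
    bic = model$bic,
    n = model$n,
    p = model$p,
    converged = model$converged,
    iterations = model$iterations)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
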