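#' Response structures for multinomial mixed-link models
#'
#' A structure defines the category ratio \eqn{\rho_j} modelled for each
#' non-baseline comparison j = 1, ..., J-1 (category J is the baseline;
#' here Normal = 1, MIM = 2, IM = 3 with IM the baseline):
#' \itemize{
#'   \item baseline: \eqn{\rho_j = \pi_j / (\pi_j + \pi_J)}
#'   \item cumulative: \eqn{\rho_j = \pi_1 + \cdots + \pi_j}
#'   \item adjacent: \eqn{\rho_j = \pi_j / (\pi_j + \pi_{j+1})}
#'   \item continuation: \eqn{\rho_j = \pi_j / (\pi_j + \cdots + \pi_J)}
#' }
#' Every structure can equivalently be written
#' \eqn{\rho_j = L_j^T \pi / (R_j^T \pi + \pi_J b_j)} with constant 0/1
#' matrices L, R and vector b returned by \code{structure_matrices}.
#'
#' @name structures
#' @keywords internal
NULL

.MML_STRUCTURES <- c("baseline", "cumulative", "adjacent", "continuation")

match_structure <- function(structure) {
  match.arg(structure, .MML_STRUCTURES)
}

#' Constant (L, R, b) matrices of a response structure
#'
#' @param structure One of \code{"baseline"}, \code{"cumulative"},
#'   \code{"adjacent"}, \code{"continuation"}.
#' @param J Number of response categories (>= 2).
#' @return A list with components \code{L}, \code{R} ((J-1) x (J-1) 0/1
#'   matrices) and \code{b} (0/1 vector of length J-1), such that
#'   \eqn{\rho_j = L_j^T \pi / (R_j^T \pi + \pi_J b_j)} where
#'   \eqn{\pi = (\pi_1, ..., \pi_{J-1})}.
#' @examples
#' structure_matrices("cumulative", 3)
#' @export
structure_matrices <- function(structure, J) {
  structure <- match_structure(structure)
  if (length(J) != 1L || !is.finite(J) || J < 2 || J != round(J))
    stop("'J' must be an integer >= 2")
  J <- as.integer(J)
  q <- J - 1L
  I <- diag(q)
  lowtri <- 1 * (row(I) >= col(I))          # lower-triangular ones
  uptri <- 1 * (row(I) <= col(I))           # upper-triangular ones
  ones <- matrix(1, q, q)
  updiag <- 1 * (col(I) - row(I) == 1)      # first superdiagonal
  out <- switch(structure,
    baseline     = list(L = I, R = I, b = rep(1, q)),
    cumulative   = list(L = lowtri, R = ones, b = rep(1, q)),
    adjacent     = list(L = I, R = I + updiag, b = c(rep(0, q - 1L), 1)),
    continuation = list(L = I, R = uptri, b = rep(1, q))
  )
  out$structure <- structure
  out$J <- J
  out
}

#' Category ratios from category probabilities
#'
#' Computes \eqn{\rho_j = L_j^T \pi / (R_j^T \pi + \pi_J b_j)} for a given
#' structure.  Accepts a single probability vector of length J or a matrix
#' with J columns (one row per sample).
#'
#' @inheritParams structure_matrices
#' @param pi Probability vector of length J on the open simplex, or an
#'   n x J matrix of such rows.
#' @return Vector of length J-1, or an n x (J-1) matrix.
#' @export
rho_from_pi <- function(structure, pi) {
  structure <- match_structure(structure)
  vec <- is.null(dim(pi))
  P <- if (vec) matrix(pi, nrow = 1L) else as.matrix(pi)
  J <- ncol(P)
  if (J < 2) stop("'pi' must have at least 2 categories")
  if (any(P <= 0) || any(P >= 1))
    stop("'pi' must lie on the open simplex (all entries in (0,1))")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("rows of 'pi' must sum to 1")
  mats <- structure_matrices(structure, J)
  Pm <- P[, -J, drop = FALSE]               # pi_1 ... pi_{J-1}
  piJ <- P[, J]
  num <- Pm %*% t(mats$L)
  den <- Pm %*% t(mats$R) + outer(piJ, mats$b)
  rho <- num / den
  if (vec) drop(rho) else rho
}

#' Category probabilities from category ratios
#'
#' Inverts the structure mapping: given \eqn{\rho_1, ..., \rho_{J-1}}
#' recovers the full probability vector \eqn{\pi_1, ..., \pi_J}.  For the
#' cumulative structure the ratios must be strictly increasing; violation
#' raises an infeasibility error naming the first offending index.
#' The adjacent and continuation normalizations work in log space so that
#' extreme ratios do not underflow.
#'
#' @inheritParams structure_matrices
#' @param rho Vector of length J-1 with entries in (0, 1), or an n x (J-1)
#'   matrix.
#' @return Probability vector of length J, or an n x J matrix.
#' @export
pi_from_rho <- function(structure, rho) {
  structure <- match_structure(structure)
  vec <- is.null(dim(rho))
  R <- if (vec) matrix(rho, nrow = 1L) else as.matrix(rho)
  if (any(R <= 0) || any(R >= 1))
    stop("'rho' entries must lie strictly inside (0, 1)")
  if (structure == "cumulative" && ncol(R) > 1) {
    mono <- R[, -1L, drop = FALSE] > R[, -ncol(R), drop = FALSE]
    if (!all(mono)) {
      bad <- which(!mono, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "cumulative structure infeasible: rho[%d] >= rho[%d]",
        bad[2L], bad[2L] + 1L))
    }
  }
  pi <- .pi_from_rho_matrix(structure, R)
  if (vec) drop(pi) else pi
}

# row-wise cumulative sum of a matrix, by running sum over the few columns
.row_cumsum <- function(M) {
  if (ncol(M) > 1L)
    for (j in 2:ncol(M)) M[, j] <- M[, j - 1L] + M[, j]
  M
}

# vectorized inversion; assumes rho already validated / feasible
.pi_from_rho_matrix <- function(structure, R) {
  q <- ncol(R)
  switch(structure,
    baseline = {
      o <- R / (1 - R)
      den <- 1 + rowSums(o)
      cbind(o / den, 1 / den, deparse.level = 0)
    },
    cumulative = {
      cum <- cbind(R, 1, deparse.level = 0)
      cbind(R[, 1L], cum[, -1L, drop = FALSE] - R, deparse.level = 0)
    },
    adjacent = {
      # pi_j / pi_{j+1} = rho_j/(1-rho_j); log pi_j rel. pi_J is the
      # reverse cumulative sum of log-odds, normalized by log-sum-exp
      logo <- log(R) - log1p(-R)
      logu <- cbind(.row_cumsum(logo[, q:1, drop = FALSE])[, q:1,
                                                          drop = FALSE],
                    0, deparse.level = 0)
      mx <- do.call(pmax, as.data.frame(logu))
      w <- exp(logu - mx)
      w / rowSums(w)
    },
    continuation = {
      # pi_j = rho_j * prod_{k<j}(1 - rho_k), pi_J = prod_k (1 - rho_k)
      lsurv <- .row_cumsum(log1p(-R))             # cumulative log(1-rho)
      lprev <- cbind(0, lsurv[, -q, drop = FALSE], deparse.level = 0)
      cbind(exp(log(R) + lprev), exp(lsurv[, q]), deparse.level = 0)
    }
  )
}

# Derivative d pi / d rho as an n x J x (J-1) array (closed form per
# structure); used by the scoring algorithm through the chain rule.
.dpi_drho <- function(structure, R, P) {
  q <- ncol(R)
  J <- q + 1L
  n <- nrow(R)
  A <- array(0, dim = c(n, J, q))
  switch(structure,
    cumulative = {
      for (k in seq_len(q)) {
        A[, k, k] <- 1
        A[, k + 1L, k] <- -1
      }
    },
    continuation = {
      for (k in seq_len(q)) {
        A[, k, k] <- P[, k] / R[, k]
        if (k < J) {
          for (j in seq.int(k + 1L, J))
            A[, j, k] <- -P[, j] / (1 - R[, k])
        }
      }
    },
    baseline = {
      # through odds o_k: d pi_j / d o_k = (1{j==k} - pi_j) * pi_J,
      # d o_k / d rho_k = 1 / (1 - rho_k)^2
      piJ <- P[, J]
      for (k in seq_len(q)) {
        dodr <- 1 / (1 - R[, k])^2
        for (j in seq_len(J)) {
          d <- ((j == k) - P[, j]) * piJ
          A[, j, k] <- d * dodr
        }
      }
    },
    adjacent = {
      # pi proportional to u_j = prod_{l>=j} o_l (u_J = 1):
      # d pi_j / d o_k = pi_j (1{j<=k} - C_k) / o_k, C_k = pi_1+...+pi_k
      o <- R / (1 - R)
      Ck <- .row_cumsum(P[, seq_len(q), drop = FALSE])
      for (k in seq_len(q)) {
        dodr <- 1 / (1 - R[, k])^2
        for (j in seq_len(J)) {
          A[, j, k] <- P[, j] * ((j <= k) - Ck[, k]) / o[, k] * dodr
        }
      }
    }
  )
  A
}
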