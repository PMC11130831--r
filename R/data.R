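#' Construct a multinomial sample table
#'
#' The internal data container for fitting: one row per covariate setting,
#' with a multinomial count vector per row.  Individual-level data are the
#' special case where every row has a single observation (all \code{n_i = 1}
#' and \code{Y} one-hot); grouped counts are supported identically.
#'
#' @param X An n x d numeric covariate matrix (n x 0 for intercept-only).
#' @param Y An n x J matrix of non-negative integer counts, each row summing
#'   to at least 1.
#' @param covariate_names Optional column labels for \code{X}.
#' @param category_labels Optional labels for the J categories (default
#'   \code{Normal, MIM, IM} when J = 3).
#' @return An object of class \code{"mml_data"} with elements \code{X},
#'   \code{Y}, \code{n_i}, \code{n}, \code{m}, \code{J}, \code{d}.
#' @export
mml_data <- function(X, Y, covariate_names = NULL, category_labels = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(Y) == 0L) stop("data must be nonempty")
  if (any(Y < 0) || any(Y != round(Y))) stop("Y must hold non-negative counts")
  n_i <- rowSums(Y)
  if (any(n_i < 1)) stop("every retained row must have at least one count")
  J <- ncol(Y)
  if (J < 2) stop("need at least two response categories")
  d <- ncol(X)
  if (is.null(covariate_names))
    covariate_names <- if (d > 0) {
      if (!is.null(colnames(X))) colnames(X) else paste0("x", seq_len(d))
    } else character(0)
  if (is.null(category_labels))
    category_labels <- if (J == 3L) c("Normal", "MIM", "IM")
                       else paste0("cat", seq_len(J))
  colnames(X) <- covariate_names
  colnames(Y) <- category_labels
  structure(
    list(X = X, Y = Y, n_i = n_i, n = sum(n_i), m = nrow(Y), J = J, d = d,
         covariate_names = covariate_names, category_labels = category_labels),
    class = "mml_data")
}

#' @export
print.mml_data <- function(x, ...) {
  cat(sprintf(
    "Multinomial sample table: n = %d observations, %d settings, J = %d, d = %d\n",
    x$n, x$m, x$J, x$d))
  invisible(x)
}

# one-hot response matrix from integer labels 1..J
labels_to_counts <- function(labels, J) {
  Y <- matrix(0L, length(labels), J)
  Y[cbind(seq_along(labels), labels)] <- 1L
  Y
}

# subset rows of an mml_data
mml_data_subset <- function(data, idx) {
  mml_data(data$X[idx, , drop = FALSE], data$Y[idx, , drop = FALSE],
           data$covariate_names, data$category_labels)
}
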