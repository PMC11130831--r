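#' Random balanced k-fold partition
#'
#' Divides \{1, ..., n\} into k non-overlapping blocks of sizes differing by
#' at most one, by a uniformly random assignment reproducible from the seed.
#'
#' @param n Number of samples.
#' @param k Number of blocks (1 <= k <= n).
#' @param seed Integer seed.
#' @return An object of class \code{"mml_partition"}: \code{assignment}
#'   (block label per sample), \code{n}, \code{k}, \code{seed}.
#' @export
make_partition <- function(n, k, seed) {
  if (k < 1 || k > n) stop("'k' must satisfy 1 <= k <= n")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  assignment <- sample(rep(seq_len(k), length.out = n))
  structure(list(assignment = assignment, n = as.integer(n),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "mml_partition")
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cross-entropy of predicted probabilities
#'
#' \eqn{-(1/n) \sum_i \log \hat\pi_{i, y_i}} with probabilities clipped at
#' \code{eps} before the logarithm.
#'
#' @param probs n x J matrix of predictive probabilities.
#' @param labels Integer labels in 1..J.
#' @param eps Clipping bound (default 1e-12).
#' @return Non-negative number.
#' @export
ce_value <- function(probs, labels, eps = 1e-12) {
  probs <- as.matrix(probs)
  if (length(labels) != nrow(probs)) stop("labels/probs length mismatch")
  p <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p, eps)))
}

#' Cross-validated cross-entropy loss of a model specification
#'
#' For each block of the partition the model is refitted on the complement
#' and the held-out samples' predictive probabilities of their true labels
#' are scored: \eqn{CE(B) = -(1/n) \sum_i \log \hat\pi_{i, y_i}^{k(i)}}.
#' The model form is fixed across folds (no per-fold re-selection).  A fold
#' whose refit does not converge is still scored with its best available
#' fit, with a warning.
#'
#' @param spec An \code{"mml_spec"}.
#' @param data An \code{"mml_data"} with one observation per row
#'   (individual-level, all \code{n_i = 1}).
#' @param partition An \code{"mml_partition"} over the rows of \code{data}.
#' @param eps Probability clipping bound before the logarithm.
#' @return The CE value, with attribute \code{"fold_converged"} (logical per
#'   block).
#' @export
cross_entropy_loss <- function(spec, data, partition, eps = 1e-12) {
  stopifnot(inherits(spec, "mml_spec"), inherits(data, "mml_data"),
            inherits(partition, "mml_partition"))
  if (partition$n != data$m)
    stop("partition size does not match the data")
  if (any(data$n_i != 1))
    stop("cross-validation expects individual-level data (all n_i = 1)")
  labels <- max.col(data$Y)
  logp <- numeric(data$m)
  fold_ok <- logical(partition$k)
  for (b in seq_len(partition$k)) {
    test <- partition$assignment == b
    train <- mml_data_subset(data, !test)
    fit <- fit_mle(spec, train, vcov = FALSE)
    fold_ok[b] <- fit$converged
    if (!fit$converged)
      warning(sprintf("fold %d refit did not converge; scoring best fit", b))
    probs <- compute_probs(spec, fit$theta, data$X[test, , drop = FALSE])
    p <- probs$pi[cbind(seq_len(sum(test)), labels[test])]
    p[!probs$feasible] <- eps
    logp[test] <- log(pmax(p, eps))
  }
  structure(-mean(logp), fold_converged = fold_ok)
}

#' One-sided paired t-test for cross-entropy improvement
#'
#' Tests \eqn{H_1: \mathrm{mean}(ce_a) < \mathrm{mean}(ce_b)} on CE values
#' paired by partition.  With zero variance of the differences the result is
#' taken at the limit: p = 0 when the mean difference is negative, p = 1
#' when positive, and an error when all differences are exactly zero.
#'
#' @param ce_a,ce_b Numeric vectors of equal length >= 2, paired by
#'   partition.
#' @return The one-sided p-value.
#' @export
compare_models_ttest <- function(ce_a, ce_b) {
  if (length(ce_a) != length(ce_b)) stop("CE vectors must be paired")
  if (length(ce_a) < 2) stop("need at least two partitions")
  diffs <- ce_a - ce_b
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0))
      stop("all paired differences are exactly zero; t-test undefined")
    return(if (mean(diffs) < 0) 0 else 1)
  }
  stats::t.test(ce_a, ce_b, paired = TRUE, alternative = "less")$p.value
}

#' Cross-entropy comparison of several models over repeated partitions
#'
#' Runs k-fold CV cross-entropy for each model over a set of random
#' partitions (default ten partitions of ten folds, seeds
#' \code{seed_base + 0:9}) and computes the matrix of one-sided paired
#' t-test p-values.
#'
#' @param specs Named list of \code{"mml_spec"} objects.
#' @param data Individual-level \code{"mml_data"}.
#' @param folds Number of folds (default 10).
#' @param partitions Number of random partitions (default 10).
#' @param seed_base First partition seed (default 1; partition r uses
#'   \code{seed_base + r - 1}).
#' @return List with \code{ce} (partitions x models matrix) and
#'   \code{p_values} (models x models; entry [a, b] tests mean CE(a) <
#'   mean CE(b)).
#' @export
cv_compare <- function(specs, data, folds = 10L, partitions = 10L,
                       seed_base = 1L) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, spec_label, character(1))
  ce <- matrix(NA_real_, partitions, length(specs),
               dimnames = list(NULL, names(specs)))
  for (r in seq_len(partitions)) {
    part <- make_partition(data$m, folds, seed_base + r - 1L)
    for (s in seq_along(specs))
      ce[r, s] <- cross_entropy_loss(specs[[s]], data, part)
  }
  pv <- matrix(NA_real_, length(specs), length(specs),
               dimnames = list(names(specs), names(specs)))
  for (a in seq_along(specs)) for (b in seq_along(specs)) {
    if (a != b)
      pv[a, b] <- tryCatch(compare_models_ttest(ce[, a], ce[, b]),
                           error = function(e) NA_real_)
  }
  list(ce = ce, p_values = pv,
       seeds = seed_base + seq_len(partitions) - 1L)
}
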