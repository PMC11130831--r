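#' Simulate study-shaped covariates
#'
#' Draws TNSC values uniformly over a study-scale range and gastric-atrophy
#' classes from a categorical distribution, then expands the atrophy factor
#' to the study's dummy coding.  Defaults emulate the study design: TNSC on
#' Uniform(2000, 20000) — the range where the selected models' linear
#' predictors traverse the informative probability region — and atrophy
#' class probabilities (Marked 0.024, Moderate 0.2, Mild 0.3, Negative 0.29,
#' Unknown 0.186) for the 5-class set, (Negative 0.37, Mild 0.38,
#' Moderate 0.25) for the 3-class set.
#'
#' @param n Number of samples.
#' @param covariate_set \code{"tnsc"}, \code{"tnsc_atrophy5"} or
#'   \code{"tnsc_atrophy3"}.
#' @param seed Integer seed.
#' @param tnsc_range Length-2 numeric, the Uniform bounds for TNSC.
#' @param atrophy_probs Optional named probability vector over the atrophy
#'   classes of the chosen set (must sum to 1).
#' @return Data frame with columns \code{sample_id}, \code{tnsc},
#'   \code{atrophy}.
#' @export
simulate_covariates <- function(n, covariate_set = .COVARIATE_SETS,
                                seed = 1L,
                                tnsc_range = c(2000, 20000),
                                atrophy_probs = NULL) {
  covariate_set <- match.arg(covariate_set)
  if (length(tnsc_range) != 2L || tnsc_range[1L] >= tnsc_range[2L])
    stop("'tnsc_range' must be (low, high) with low < high")
  levels <- if (covariate_set == "tnsc_atrophy3") .ATROPHY3 else .ATROPHY5
  if (is.null(atrophy_probs)) {
    atrophy_probs <- if (covariate_set == "tnsc_atrophy3")
      c(Negative = 0.37, Mild = 0.38, Moderate = 0.25)
    else
      c(Marked = 0.024, Moderate = 0.2, Mild = 0.3, Negative = 0.29,
        Unknown = 0.186)
  }
  if (!setequal(names(atrophy_probs), levels))
    stop("'atrophy_probs' must be named by the atrophy classes of the set")
  atrophy_probs <- atrophy_probs[levels]
  if (any(atrophy_probs < 0) || abs(sum(atrophy_probs) - 1) > 1e-8)
    stop("'atrophy_probs' must be non-negative and sum to 1")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    tnsc = stats::runif(n, tnsc_range[1L], tnsc_range[2L]),
    atrophy = sample(levels, n, replace = TRUE, prob = atrophy_probs),
    stringsAsFactors = FALSE)
}

#' Simulate multinomial responses under a mixed-link model
#'
#' Each sample's label is drawn from the model's category probabilities at
#' its covariate setting (one observation per sample, matching the study
#' design).
#'
#' @param spec An \code{"mml_spec"}.
#' @param theta Generating parameter vector.
#' @param X n x d covariate matrix (e.g. \code{build_design} output).
#' @param seed Integer seed.
#' @return Integer labels in 1..J.
#' @export
simulate_responses <- function(spec, theta, X, seed = 1L) {
  cp <- compute_probs(spec, theta, X)
  if (!all(cp$feasible))
    stop(sprintf("generating parameters infeasible at row %d",
                 which(!cp$feasible)[1L]))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  u <- stats::runif(nrow(cp$pi))
  cum <- t(apply(cp$pi, 1L, cumsum))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}

#' Simulate a complete study-shaped dataset
#'
#' Generates covariates with \code{\link{simulate_covariates}} and responses
#' from one of the selected study models (or any spec/theta pair), returning
#' the same CSV schema the fitting pipeline reads.
#'
#' @param model \code{"model1"}, \code{"model2"}, \code{"model3"}, or a list
#'   with elements \code{spec}, \code{theta}, \code{covariate_set}.
#' @param n Number of samples (default 124, the study size).
#' @param seed Integer seed (covariates use \code{seed}, responses
#'   \code{seed + 1}).
#' @param ... Passed to \code{\link{simulate_covariates}}
#'   (\code{tnsc_range}, \code{atrophy_probs}).
#' @return Data frame with columns \code{sample_id}, \code{tnsc},
#'   \code{atrophy}, \code{im_label}.
#' @examples
#' head(simulate_study_data("model1", n = 10, seed = 7))
#' @export
simulate_study_data <- function(model = "model1", n = 124L, seed = 1L, ...) {
  if (is.character(model)) model <- study_model(model)
  covs <- simulate_covariates(n, model$covariate_set, seed = seed, ...)
  X <- build_design(covs, model$covariate_set)
  labels <- simulate_responses(model$spec, model$theta, X, seed = seed + 1L)
  covs$im_label <- .IM_LABELS[labels]
  covs
}

#' Fabricate a synthetic epiTOC2 parameter table
#'
#' A stand-in for the published clock's delta table (which is an external
#' input, not vendored): \code{nc} probe IDs with de novo methylation
#' probabilities drawn uniformly from \code{delta_range}.  The default range
#' (2e-5, 8e-5) lets beta values in [0, 1] realize TNSC scores up to
#' ~25000, covering the study-scale thousands-to-tens-of-thousands range.
#'
#' @param nc Number of CpGs (default 163, the clock's size).
#' @param seed Integer seed.
#' @param delta_range Uniform bounds for delta.
#' @return Data frame with columns \code{cpg_id}, \code{delta}, \code{w}.
#' @export
synthetic_epitoc_params <- function(nc = 163L, seed = 1L,
                                    delta_range = c(2e-5, 8e-5)) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  delta <- stats::runif(nc, delta_range[1L], delta_range[2L])
  data.frame(cpg_id = sprintf("cgSYN%05d", seq_len(nc)), delta = delta,
             w = 2 / delta, stringsAsFactors = FALSE)
}

#' Simulate a beta-value matrix with prescribed TNSC scores
#'
#' Constructs \eqn{\beta_{is} = t_s \delta_i / 2} plus feasible mean-zero
#' jitter, so that \code{\link{tnsc}} of the result reproduces the target
#' scores exactly (to numerical precision).  The jitter is projected
#' orthogonally to the TNSC weights and shrunk until all beta values stay
#' in [0, 1].
#'
#' @param params epiTOC2 parameter table (\code{cpg_id}, \code{delta}).
#' @param target_tnsc Numeric vector of target scores, one per sample; each
#'   must satisfy \eqn{t_s \le 2/\max_i \delta_i} so the flat construction
#'   stays within [0, 1].
#' @param seed Integer seed for the jitter.
#' @param jitter_sd Standard deviation of the raw jitter (default 0.01).
#' @return Beta matrix, CpGs x samples, with probe IDs as rownames and
#'   \code{sample_id}s \code{S0001, ...} as colnames.
#' @export
simulate_beta_matrix <- function(params, target_tnsc, seed = 1L,
                                 jitter_sd = 0.01) {
  check_epitoc_params(params)
  nc <- nrow(params)
  if (any(target_tnsc < 0) || any(target_tnsc > 2 / max(params$delta)))
    stop(sprintf(
      "infeasible target TNSC: must lie in [0, %.6g] for this delta table",
      2 / max(params$delta)))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  w <- 2 / (nc * params$delta)
  B <- outer(params$delta / 2, target_tnsc)        # flat construction
  for (s in seq_along(target_tnsc)) {
    e <- stats::rnorm(nc, 0, jitter_sd)
    e <- e - w * sum(w * e) / sum(w * w)           # preserve the weighted sum
    shrink <- 1
    repeat {
      cand <- B[, s] + shrink * e
      if (all(cand >= 0 & cand <= 1)) break
      shrink <- shrink / 2
      if (shrink < 1e-12) { shrink <- 0; break }
    }
    B[, s] <- B[, s] + shrink * e
  }
  dimnames(B) <- list(params$cpg_id,
                      sprintf("S%04d", seq_along(target_tnsc)))
  B
}
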