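#' Enumerate the candidate model space
#'
#' The full cross-product of response structures, per-comparison link
#' functions and odds assumptions.  With all four structures, all four links
#' for each of the J-1 comparisons and both odds types this gives
#' \eqn{4 \times 4^{J-1} \times 2} specifications (128 when J = 3).
#'
#' @param J Number of response categories.
#' @param links Character vector of link names to consider.
#' @param structures Character vector of structure names to consider.
#' @param odds Character vector among \code{c("po", "npo")}.
#' @param d Number of covariates each candidate uses.
#' @param covariate_names Optional covariate labels passed to each spec.
#' @return A list of \code{"mml_spec"} objects.
#' @export
enumerate_candidates <- function(J = 3L, links = .MML_LINKS,
                                 structures = .MML_STRUCTURES,
                                 odds = c("npo", "po"), d = 1L,
                                 covariate_names = NULL) {
  if (length(links) == 0L || length(structures) == 0L || length(odds) == 0L)
    stop("'links', 'structures' and 'odds' must be nonempty")
  if (J < 2) stop("'J' must be >= 2")
  links <- vapply(links, match_link, character(1), USE.NAMES = FALSE)
  structures <- vapply(structures, match_structure, character(1),
                       USE.NAMES = FALSE)
  odds <- vapply(odds, function(o) match.arg(o, c("npo", "po")),
                 character(1), USE.NAMES = FALSE)
  q <- J - 1L
  link_grid <- expand.grid(rep(list(links), q), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (s in structures) for (o in odds) for (r in seq_len(nrow(link_grid))) {
    out[[length(out) + 1L]] <- mixed_link_spec(
      s, unlist(link_grid[r, ], use.names = FALSE), o, d = d,
      covariate_names = covariate_names)
  }
  out
}

#' Akaike and Bayesian information criteria
#'
#' \eqn{AIC = -2 l(\hat\theta) + 2p} and
#' \eqn{BIC = -2 l(\hat\theta) + \log(n) p}, so that
#' \eqn{BIC - AIC = (\log n - 2) p} exactly.
#'
#' @param loglik Maximized log-likelihood.
#' @param p Number of free parameters.
#' @param n Total number of observations.
#' @return Named vector \code{c(AIC, BIC)}.
#' @examples
#' information_criteria(-69.145, 3, 124)
#' @export
information_criteria <- function(loglik, p, n) {
  if (n < 1 || p < 0) stop("need n >= 1 and p >= 0")
  c(AIC = -2 * loglik + 2 * p, BIC = -2 * loglik + log(n) * p)
}

spec_label <- function(spec) {
  sprintf("%s-%s-%s", spec$structure, spec$odds,
          paste(spec$links, collapse = ","))
}

#' Fit and rank a set of candidate models
#'
#' Fits every candidate by maximum likelihood and ranks ascending by the
#' chosen information criterion.  Non-convergent candidates are retained but
#' flagged and ranked last; ties are broken by smaller parameter count, then
#' by the lexicographic spec label.  The per-(structure, odds) summary keeps
#' the best link combination of each of the (up to) eight groups — the shape
#' of the published selection tables.
#'
#' @param data An \code{"mml_data"} sample table.
#' @param candidates List of \code{"mml_spec"} objects
#'   (e.g. from \code{\link{enumerate_candidates}}).
#' @param criterion \code{"AIC"} (default) or \code{"BIC"}.
#' @return A list of class \code{"mml_sweep"}: \code{ranking}, a data frame
#'   with one row per candidate (columns \code{structure}, \code{odds},
#'   \code{link_1}, ..., \code{AIC}, \code{BIC}, \code{loglik}, \code{p},
#'   \code{converged}, \code{rank}); \code{groups}, the per-(structure, odds)
#'   best rows; \code{fits}, the fitted models in ranking order; and
#'   \code{criterion}.
#' @export
select_best <- function(data, candidates, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0L) stop("'candidates' must be nonempty")
  fits <- lapply(candidates, function(sp) {
    tryCatch(fit_mle(sp, data, vcov = FALSE), error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("all candidate fits failed")
  candidates <- candidates[keep]
  fits <- fits[keep]
  q <- candidates[[1L]]$J - 1L
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    row <- data.frame(structure = f$spec$structure, odds = f$spec$odds,
                      stringsAsFactors = FALSE)
    for (j in seq_len(q)) row[[paste0("link_", j)]] <- f$spec$links[j]
    row$AIC <- f$aic
    row$BIC <- f$bic
    row$loglik <- f$loglik
    row$p <- f$p
    row$converged <- f$converged
    row$label <- spec_label(f$spec)
    row
  })
  tab <- do.call(rbind, rows)
  crit <- if (criterion == "AIC") tab$AIC else tab$BIC
  ord <- order(!tab$converged, crit, tab$p, tab$label)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  grp_key <- paste(tab$structure, tab$odds)
  groups <- tab[!duplicated(grp_key), , drop = FALSE]
  groups <- groups[order(groups$rank), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(ranking = tab, groups = groups, fits = fits,
                 criterion = criterion, n = data$n),
            class = "mml_sweep")
}

#' @export
print.mml_sweep <- function(x, ...) {
  cat(sprintf("Model-selection sweep over %d candidates (criterion %s, n = %d)\n",
              nrow(x$ranking), x$criterion, x$n))
  cat("Best link combination per (structure, odds) group:\n")
  print(x$groups[, setdiff(names(x$groups), "label")], digits = 6)
  invisible(x)
}

#' Write a sweep report to TSV
#'
#' @param sweep An \code{"mml_sweep"}.
#' @param path Output file for the group summary.
#' @param full_path Optional output file for the complete per-candidate
#'   ranking.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(sweep, path, full_path = NULL) {
  stopifnot(inherits(sweep, "mml_sweep"))
  cols <- setdiff(names(sweep$groups), "label")
  utils::write.table(sweep$groups[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(full_path))
    utils::write.table(sweep$ranking[, cols], full_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
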