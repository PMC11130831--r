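#' epiTOC2 mitotic-age score (TNSC) from beta values
#'
#' The simplified epiTOC2 estimator of the total number of stem-cell
#' divisions per stem cell for sample s is the weighted average
#' \deqn{TNSC(s) = (1/n_c) \sum_i 2 \beta_{is} / \delta_i}
#' over the clock's \eqn{n_c} CpG sites (163 in the published clock), where
#' \eqn{\beta_{is} \in [0,1]} is the methylation beta value and
#' \eqn{\delta_i \in (0,1]} the site's probability of de novo methylation of
#' parent and daughter strands.
#'
#' @param betas CpG x sample matrix of beta values in [0, 1], rownames the
#'   probe IDs.
#' @param params Data frame with columns \code{cpg_id} and \code{delta}
#'   (e.g. from \code{\link{read_epitoc_params}} or
#'   \code{\link{synthetic_epitoc_params}}).
#' @param missing_policy \code{"strict"} (default: every parameter CpG must
#'   be present in \code{betas}) or \code{"intersect"} (average over the
#'   present subset with its own count, with a warning).
#' @return Data frame with columns \code{sample_id}, \code{tnsc},
#'   \code{n_probes_used}.
#' @examples
#' pars <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
#'                    delta = c(0.01, 0.02, 0.04))
#' B <- matrix(c(0.1, 0.2, 0.3), 3, 1,
#'             dimnames = list(pars$cpg_id, "s1"))
#' tnsc(B, pars)   # (20 + 20 + 15) / 3
#' @export
tnsc <- function(betas, params, missing_policy = c("strict", "intersect")) {
  missing_policy <- match.arg(missing_policy)
  betas <- as.matrix(betas)
  check_epitoc_params(params)
  bad <- !is.na(betas) & (betas < 0 | betas > 1)
  if (any(bad))
    stop("beta values outside [0, 1] found")
  present <- params$cpg_id %in% rownames(betas)
  if (!any(present))
    stop("none of the parameter CpGs are present in the beta matrix")
  if (!all(present)) {
    if (missing_policy == "strict")
      stop(sprintf("missing CpGs under strict policy: %s",
                   paste(params$cpg_id[!present], collapse = ", ")))
    warning(sprintf(
      "%d of %d parameter CpGs absent; averaging over the %d present",
      sum(!present), nrow(params), sum(present)))
  }
  sub <- params[present, , drop = FALSE]
  B <- betas[sub$cpg_id, , drop = FALSE]
  w <- 2 / sub$delta
  vals <- colSums(B * w) / nrow(sub)
  data.frame(sample_id = colnames(betas), tnsc = unname(vals),
             n_probes_used = nrow(sub), stringsAsFactors = FALSE)
}

check_epitoc_params <- function(params) {
  if (!is.data.frame(params) ||
      !all(c("cpg_id", "delta") %in% names(params)))
    stop("'params' must be a data frame with columns cpg_id and delta")
  if (any(!is.finite(params$delta)) || any(params$delta <= 0) ||
      any(params$delta > 1))
    stop("'delta' values must lie in (0, 1]")
  if (anyDuplicated(params$cpg_id)) stop("duplicated CpG IDs in 'params'")
  invisible(params)
}

#' Read an epiTOC2 parameter table
#'
#' CSV with columns \code{cpg_id} and \code{delta}.  The published clock's
#' delta values ship with the original epiTOC2 code and are supplied by the
#' user; \code{\link{synthetic_epitoc_params}} fabricates a stand-in for
#' testing.
#'
#' @param path CSV file path.
#' @return Validated data frame with columns \code{cpg_id}, \code{delta}
#'   and the derived weight \code{w = 2/delta}.
#' @export
read_epitoc_params <- function(path) {
  params <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_epitoc_params(params)
  params$w <- 2 / params$delta
  params
}

#' Read a beta-value matrix
#'
#' TSV/CSV with probe IDs in the first column and one column per sample
#' (GEO series-matrix orientation accepted via \code{transpose}).
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (.csv comma, otherwise tab).
#' @param transpose Set \code{TRUE} when rows are samples.
#' @return Numeric matrix, CpGs x samples.
#' @export
read_beta_matrix <- function(path, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  m
}
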