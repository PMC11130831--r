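.ATROPHY5 <- c("Marked", "Moderate", "Mild", "Negative", "Unknown")
.ATROPHY3 <- c("Negative", "Mild", "Moderate")
.IM_LABELS <- c("Normal", "MIM", "IM")
.COVARIATE_SETS <- c("tnsc", "tnsc_atrophy5", "tnsc_atrophy3")

# design matrix for a covariate set; df needs columns tnsc and (for the
# atrophy sets) atrophy.  Dummy baselines follow the study coding: Marked
# for the 5-class set, Negative for the 3-class set.
build_design <- function(df, covariate_set = .COVARIATE_SETS) {
  covariate_set <- match.arg(covariate_set)
  if (covariate_set == "tnsc") {
    X <- cbind(tnsc = df$tnsc)
    return(X)
  }
  at <- as.character(df$atrophy)
  if (covariate_set == "tnsc_atrophy5") {
    bad <- !(at %in% .ATROPHY5)
    if (any(bad))
      stop(sprintf("unknown atrophy level '%s' at row %d",
                   at[which(bad)[1L]], which(bad)[1L]))
    cbind(tnsc = df$tnsc,
          mild = as.numeric(at == "Mild"),
          moderate = as.numeric(at == "Moderate"),
          negative = as.numeric(at == "Negative"),
          unknown = as.numeric(at == "Unknown"))
  } else {
    bad <- !(at %in% .ATROPHY3)
    if (any(bad))
      stop(sprintf(
        "atrophy level '%s' at row %d is outside the 3-class set",
        at[which(bad)[1L]], which(bad)[1L]))
    cbind(tnsc = df$tnsc,
          mild = as.numeric(at == "Mild"),
          moderate = as.numeric(at == "Moderate"))
  }
}

# common validation + conversion of a study data frame to mml_data;
# for the 3-class set Marked/Unknown rows are dropped (count recorded)
prepare_sample_table <- function(df, covariate_set = .COVARIATE_SETS) {
  covariate_set <- match.arg(covariate_set)
  need <- c("sample_id", "tnsc", "im_label")
  if (covariate_set != "tnsc") need <- c(need, "atrophy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required columns: %s",
                 paste(missing_cols, collapse = ", ")))
  if (any(!is.finite(df$tnsc))) stop("non-finite TNSC values")
  lab_raw <- as.character(df$im_label)
  lab_idx <- match(tolower(lab_raw), tolower(.IM_LABELS))
  if (any(is.na(lab_idx)))
    stop(sprintf("unknown IM label '%s' at row %d",
                 lab_raw[which(is.na(lab_idx))[1L]], which(is.na(lab_idx))[1L]))
  dropped <- 0L
  if (covariate_set == "tnsc_atrophy3") {
    at <- as.character(df$atrophy)
    bad <- !(at %in% .ATROPHY5)
    if (any(bad))
      stop(sprintf("unknown atrophy level '%s' at row %d",
                   at[which(bad)[1L]], which(bad)[1L]))
    keep <- at %in% .ATROPHY3
    dropped <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    lab_idx <- lab_idx[keep]
  }
  if (nrow(df) == 0L) stop("no rows remain after filtering")
  X <- build_design(df, covariate_set)
  Y <- labels_to_counts(lab_idx, 3L)
  data <- mml_data(X, Y, covariate_names = colnames(X),
                   category_labels = .IM_LABELS)
  attr(data, "dropped") <- dropped
  attr(data, "sample_id") <- as.character(df$sample_id)
  data
}

#' Read a study sample table
#'
#' CSV with columns \code{sample_id}, \code{tnsc}, \code{atrophy},
#' \code{im_label}.  IM labels (case-insensitive Normal / MIM / IM) are
#' mapped to categories 1-3 with IM the baseline.  The covariate set
#' determines the design: \code{"tnsc"} (d = 1); \code{"tnsc_atrophy5"}
#' (d = 5: TNSC plus mild/moderate/negative/unknown dummies, Marked
#' baseline); \code{"tnsc_atrophy3"} (d = 3: TNSC plus mild/moderate,
#' Negative baseline, with Marked and Unknown rows dropped and the count
#' recorded in the \code{"dropped"} attribute).
#'
#' @param path CSV file path.
#' @param covariate_set One of \code{"tnsc"}, \code{"tnsc_atrophy5"},
#'   \code{"tnsc_atrophy3"}.
#' @return An \code{"mml_data"} table with attributes \code{"dropped"} and
#'   \code{"sample_id"}.
#' @export
read_sample_table <- function(path, covariate_set = .COVARIATE_SETS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prepare_sample_table(df, covariate_set)
}

#' Run the full study pipeline on one dataset
#'
#' Reproduces the study's analysis sequence on a sample table: the
#' 128-candidate model-selection sweep (ranked by the chosen criterion,
#' with the per-(structure, odds) group summary), a refit of the winning
#' specification with Wald inference for the TNSC slope, and optionally a
#' cross-validated cross-entropy comparison of the winner against named
#' baseline specifications with one-sided paired t-tests.
#'
#' @param data_path CSV sample table (see \code{\link{read_sample_table}}).
#' @param covariate_set Covariate set for the design matrix.
#' @param criterion \code{"AIC"} (default) or \code{"BIC"}.
#' @param out_dir Output directory; created if needed.  Writes
#'   \code{sweep_groups.tsv}, \code{sweep_full.tsv}, \code{best_model.json},
#'   \code{wald_tnsc.tsv} and, when CV is run, \code{ce.tsv} and
#'   \code{ce_pvalues.tsv}.
#' @param cv_baselines Optional named list of \code{"mml_spec"} objects to
#'   compare against the winner by cross-validated cross-entropy.
#' @param folds,partitions,seed_base CV settings (defaults 10, 10, 1).
#' @return Invisibly, a list with \code{sweep}, \code{best_fit},
#'   \code{wald} and (optionally) \code{cv}.
#' @export
run_study_pipeline <- function(data_path,
                               covariate_set = .COVARIATE_SETS,
                               criterion = c("AIC", "BIC"),
                               out_dir = ".",
                               cv_baselines = NULL,
                               folds = 10L, partitions = 10L,
                               seed_base = 1L) {
  covariate_set <- match.arg(covariate_set)
  criterion <- match.arg(criterion)
  data <- read_sample_table(data_path, covariate_set)
  message(sprintf("read %d observations (d = %d, %d rows dropped)",
                  data$n, data$d, attr(data, "dropped")))
  candidates <- enumerate_candidates(J = 3L, d = data$d,
                                     covariate_names = data$covariate_names)
  sweep <- select_best(data, candidates, criterion)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_sweep(sweep, file.path(out_dir, "sweep_groups.tsv"),
              file.path(out_dir, "sweep_full.tsv"))
  best <- fit_mle(sweep$fits[[1L]]$spec, data)   # refit with covariance
  fit_to_json(best, file.path(out_dir, "best_model.json"))
  wald <- wald_inference(best, "tnsc")
  utils::write.table(
    data.frame(coefficient = "tnsc", t(wald)),
    file.path(out_dir, "wald_tnsc.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(sweep = sweep, best_fit = best, wald = wald)
  if (!is.null(cv_baselines)) {
    specs <- c(list(selected = best$spec), cv_baselines)
    cv <- cv_compare(specs, data, folds = folds, partitions = partitions,
                     seed_base = seed_base)
    utils::write.table(cv$ce, file.path(out_dir, "ce.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cv$p_values, file.path(out_dir, "ce_pvalues.tsv"),
                       sep = "\t", quote = FALSE)
    out$cv <- cv
  }
  invisible(out)
}
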