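#!/usr/bin/env Rscript

# Step 3: cross-validated cross-entropy comparison.
#
# The winning TNSC-only specification from step 2 is compared against the
# two conventional alternatives -- the baseline-category logit model with
# npo (multiclass logistic regression) and the cumulative logit model with
# npo -- by ten-fold cross-validation over ten random partitions, scoring
# held-out samples with the cross-entropy loss
# CE(B) = -(1/n) sum_i log pihat_{i, y_i}, and testing each improvement
# with a one-sided paired t-test across the ten partitions.

library(mmlink)

best_path <- "results/sweep_tnsc/best_model.json"
if (!file.exists(best_path))
  stop("run analysis/02_model_selection.R first")
best <- jsonlite::fromJSON(best_path)
selected <- mixed_link_spec(best$structure, best$links, best$odds,
                            d = best$d, covariate_names = "tnsc")
cat(sprintf("selected model: %s %s (%s)\n", best$structure, best$odds,
            paste(best$links, collapse = ", ")))

data <- read_sample_table("results/synthetic_study.csv", "tnsc")
specs <- list(
  selected = selected,
  baseline_npo_logit = mixed_link_spec("baseline", c("logit", "logit"),
                                       "npo", d = 1,
                                       covariate_names = "tnsc"),
  cumulative_npo_logit = mixed_link_spec("cumulative", c("logit", "logit"),
                                         "npo", d = 1,
                                         covariate_names = "tnsc"))

cv <- suppressWarnings(
  cv_compare(specs, data, folds = 10, partitions = 10, seed_base = 1))

out <- "results"
write.table(cv$ce, file.path(out, "cv_ce.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cv$p_values, file.path(out, "cv_pvalues.tsv"), sep = "\t",
            quote = FALSE)

cat("\nmean CE over ten partitions:\n")
print(colMeans(cv$ce), digits = 4)
for (alt in c("baseline_npo_logit", "cumulative_npo_logit"))
  cat(sprintf("selected < %s: one-sided paired-t p = %.3g\n",
              alt, cv$p_values["selected", alt]))
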