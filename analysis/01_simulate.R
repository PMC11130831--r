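#!/usr/bin/env Rscript

# Step 1: build the synthetic study dataset.
#
# The study design this emulates: 124 antrum tissue samples, each with a
# DNA-methylation-derived mitotic-age score (TNSC), a 5-class gastric
# atrophy status and a 3-level IM risk label (Normal / MIM / IM).  Labels
# are drawn from the fitted adjacent-categories po logit model over TNSC
# and atrophy (the richest of the three selected models), so every
# downstream step has a known ground truth.  The methylation route is also
# exercised: a synthetic epiTOC2 delta table and a beta-value matrix
# constructed to reproduce each sample's TNSC through the clock formula
# TNSC(s) = (1/nc) sum_i 2 beta_is / delta_i.

library(mmlink)

out <- "results"
dir.create(out, showWarnings = FALSE)
set.seed(1)

n <- 124L
df <- simulate_study_data("model2", n = n, seed = 20240501)
write.csv(df, file.path(out, "synthetic_study.csv"), row.names = FALSE)
cat(sprintf("wrote %d samples; label counts: %s\n", n,
            paste(names(table(df$im_label)), table(df$im_label),
                  collapse = " ", sep = "=")))

# methylation route: delta table -> beta matrix -> recomputed TNSC
pars <- synthetic_epitoc_params(nc = 163L, seed = 7)
write.csv(pars[, c("cpg_id", "delta")],
          file.path(out, "synthetic_epitoc_params.csv"), row.names = FALSE)
betas <- simulate_beta_matrix(pars, df$tnsc, seed = 8)
scores <- tnsc(betas, pars)
stopifnot(max(abs(scores$tnsc - df$tnsc)) < 1e-6)
write.csv(scores, file.path(out, "tnsc_from_betas.csv"), row.names = FALSE)
cat(sprintf(
  "beta matrix %d CpGs x %d samples; max |TNSC - target| = %.2e\n",
  nrow(betas), ncol(betas), max(abs(scores$tnsc - df$tnsc))))
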