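# mmlink — multinomial mixed-link models for gastric IM risk

Gastric intestinal metaplasia (IM) is a precancerous change of the stomach
mucosa.  This package models a sample's three-level IM risk — Normal, MIM
(mild IM) and IM — from its DNA-methylation mitotic age and gastric-atrophy
grade, for biostatisticians analysing methylation-based cancer-risk cohorts.

The mitotic-age covariate is **TNSC**, the total number of stem-cell
divisions per stem cell, computed from beta values by the simplified
epiTOC2 clock

    TNSC(s) = (1/nc) * sum_i 2 * beta_is / delta_i        (nc = 163 CpGs)

The regression family is the **multinomial mixed-link model**: for
categories j = 1, …, J−1 (J = 3, IM the baseline),

    g_j(rho_ij) = beta_0j + beta_j' x_i

where the category ratio `rho_ij` follows one of four response structures
(baseline-category, cumulative, adjacent-categories, continuation-ratio),
each comparison j may use its **own** link g_j (logit, probit, loglog,
cloglog) — the feature that distinguishes the family from classical
multinomial logit models — and the slopes are either shared (proportional
odds, po) or per-comparison (npo).  With J = 3 that is a 4 × 4² × 2 = 128
candidate space.  The package provides maximum-likelihood fitting by Fisher
scoring, Wald inference, exhaustive AIC/BIC selection sweeps, ten-fold
cross-validated cross-entropy comparison with one-sided paired t-tests,
TNSC computation from beta matrices, and a seeded generator of study-shaped
synthetic data.

## Worked example

Simulate a study-sized dataset (124 samples) from the selected cumulative
po model with loglog/logit links, run the full 128-candidate AIC sweep, and
test the TNSC effect:

```r
library(mmlink)
df <- simulate_study_data("model1", n = 124, seed = 42)
path <- tempfile(fileext = ".csv"); write.csv(df, path, row.names = FALSE)
data <- read_sample_table(path, "tnsc")
sw <- select_best(data, enumerate_candidates(J = 3, d = 1,
                                             covariate_names = "tnsc"))
print(sw)
```

```
Model-selection sweep over 128 candidates (criterion AIC, n = 124)
Best link combination per (structure, odds) group:
     structure odds link_1 link_2     AIC     BIC   loglik p converged rank
1   cumulative   po loglog  logit 148.241 156.702 -71.1204 3      TRUE    1
2   cumulative  npo loglog probit 149.270 160.551 -70.6350 4      TRUE    2
3     baseline  npo loglog loglog 150.577 161.858 -71.2886 4      TRUE    5
...
```

One row per (structure, odds) group with that group's best link pair; the
generating family — cumulative po with loglog/logit links — wins on AIC,
and BIC − AIC = (log 124 − 2)·p holds exactly on every row.  Wald inference
for the TNSC slope on the refitted winner:

```r
best <- fit_mle(sw$fits[[1]]$spec, data)
wald_inference(best, "tnsc")
#      estimate         lower         upper       p_value
# -4.384469e-04 -5.592633e-04 -3.176305e-04  1.137316e-12
```

The slope estimate −4.38 × 10⁻⁴ per stem-cell division brackets the
generating value −4.228 × 10⁻⁴, and the effect is strongly significant:
higher mitotic age lowers the probability of the Normal category.

## Analysis workflow

`analysis/` holds the numbered drivers of the full study-shaped analysis,
each writing its tables under `results/`:

1. `01_simulate.R` — synthetic study table (124 samples, atrophy + TNSC),
   plus the methylation route: synthetic delta table → beta matrix → TNSC.
2. `02_model_selection.R` — 128-candidate sweeps for the three covariate
   scenarios (TNSC only; TNSC + 5-class atrophy; 3-class subset), winner
   refits and TNSC Wald tests.
3. `03_crossval.R` — ten-fold CV cross-entropy of the selected model
   against baseline-npo-logit and cumulative-npo-logit, with one-sided
   paired t-tests over ten partitions.
4. `04_recovery.R` — 20-replicate parameter recovery for all three
   selected models' coefficients.

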