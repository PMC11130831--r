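test_that("covariate simulation honours seed, range and dummy coding", {
  c1 <- simulate_covariates(124, "tnsc_atrophy5", seed = 7)
  c2 <- simulate_covariates(124, "tnsc_atrophy5", seed = 7)
  expect_identical(c1, c2)
  expect_true(all(c1$tnsc >= 2000 & c1$tnsc <= 20000))
  X <- mmlink:::build_design(c1, "tnsc_atrophy5")
  expect_equal(colnames(X), c("tnsc", "mild", "moderate", "negative",
                              "unknown"))
  # at most one dummy active per sample; Marked rows have none
  expect_true(all(rowSums(X[, -1]) <= 1))
  expect_true(all(rowSums(X[c1$atrophy == "Marked", -1, drop = FALSE]) == 0))
  # point mass on the baseline class
  cm <- simulate_covariates(30, "tnsc_atrophy5", seed = 1,
                            atrophy_probs = c(Marked = 1, Moderate = 0,
                                              Mild = 0, Negative = 0,
                                              Unknown = 0))
  Xm <- mmlink:::build_design(cm, "tnsc_atrophy5")
  expect_true(all(Xm[, -1] == 0))
  expect_error(simulate_covariates(10, "tnsc", tnsc_range = c(5, 2)),
               "tnsc_range")
  expect_error(simulate_covariates(10, "tnsc_atrophy3",
                                   atrophy_probs = c(Negative = 0.5,
                                                     Mild = 0.2,
                                                     Moderate = 0.2)),
               "sum to 1")
})

test_that("responses are drawn from the model's category probabilities", {
  m1 <- study_model("model1")
  X <- matrix(9515.38, 50000, 1, dimnames = list(NULL, "tnsc"))
  labs <- simulate_responses(m1$spec, m1$theta, X, seed = 5)
  expect_identical(labs, simulate_responses(m1$spec, m1$theta, X, seed = 5))
  freq <- tabulate(labs, 3) / length(labs)
  target <- category_probs(m1$spec, m1$theta, 9515.38)
  expect_equal(freq, unname(target), tolerance = 0.01)
  expect_equal(round(unname(target), 3), c(0.368, 0.339, 0.293),
               tolerance = 1e-3)
  # extreme intercepts force a degenerate first category
  sp <- mixed_link_spec("cumulative", c("logit", "logit"), "po", d = 1)
  labs1 <- simulate_responses(sp, c(20, 21, 0), X, seed = 2)
  expect_true(all(labs1 == 1L))
})

test_that("study datasets carry the pipeline's CSV schema", {
  df <- simulate_study_data("model2", n = 124, seed = 13)
  expect_equal(names(df), c("sample_id", "tnsc", "atrophy", "im_label"))
  expect_true(all(df$im_label %in% c("Normal", "MIM", "IM")))
  expect_true(all(df$atrophy %in% c("Marked", "Moderate", "Mild",
                                    "Negative", "Unknown")))
  expect_identical(df, simulate_study_data("model2", n = 124, seed = 13))
  df3 <- simulate_study_data("model3", n = 98, seed = 13)
  expect_true(all(df3$atrophy %in% c("Negative", "Mild", "Moderate")))
})

test_that("simulated beta matrices reproduce their target TNSC", {
  pars <- synthetic_epitoc_params(nc = 50, seed = 8)
  targets <- runif(6, 0.5, 1.5)
  B <- simulate_beta_matrix(pars, targets, seed = 9)
  expect_true(all(B >= 0 & B <= 1))
  expect_equal(tnsc(B, pars)$tnsc, targets, tolerance = 1e-8)
  # study-scale targets round-trip as well
  big <- c(2000, 9515.38, 20000)
  Bb <- simulate_beta_matrix(pars, big, seed = 10)
  expect_equal(tnsc(Bb, pars)$tnsc, big, tolerance = 1e-6)
  expect_equal(tnsc(simulate_beta_matrix(pars, 0), pars)$tnsc, 0)
  expect_error(simulate_beta_matrix(pars, 1e9), "infeasible")
})

test_that("the generator plus fitter closes the loop on Model 2", {
  m2 <- study_model("model2")
  ests <- sapply(1:5, function(s) {
    df <- simulate_study_data("model2", n = 4000, seed = 400 + s)
    dat <- mmlink:::prepare_sample_table(df, "tnsc_atrophy5")
    fit <- fit_mle(m2$spec, dat, vcov = FALSE)
    expect_true(fit$converged)
    fit$theta
  })
  mean_est <- rowMeans(ests)
  mc_se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  for (k in seq_along(m2$theta)) {
    expect_lt(abs(mean_est[k] - m2$theta[k]),
              4 * mc_se[k] + 0.02 * max(1, abs(m2$theta[k])))
  }
})
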