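test_that("partitions are balanced, exhaustive and reproducible", {
  p <- make_partition(10, 10, 1)
  expect_equal(sort(p$assignment), 1:10)
  p124 <- make_partition(124, 10, 5)
  sizes <- tabulate(p124$assignment, 10)
  expect_equal(sort(sizes), c(rep(12, 6), rep(13, 4)))
  expect_equal(sum(sizes), 124)
  expect_identical(make_partition(124, 10, 5)$assignment, p124$assignment)
  expect_false(identical(make_partition(124, 10, 6)$assignment,
                         p124$assignment))
  expect_error(make_partition(5, 6, 1), "k")
})

test_that("cross-entropy hits its closed-form landmarks", {
  labs <- c(1L, 2L, 3L, 2L)
  perfect <- matrix(0, 4, 3)
  perfect[cbind(1:4, labs)] <- 1
  expect_equal(ce_value(perfect, labs), 0)
  uniform <- matrix(1 / 3, 4, 3)
  expect_equal(ce_value(uniform, labs), log(3))
  expect_gte(ce_value(matrix(c(0.9, 0.05, 0.05), 1, 3, byrow = TRUE), 3L),
             0)
})

test_that("CV cross-entropy is order-invariant and favors the true model", {
  df <- simulate_study_data("model1", n = 300, seed = 21)
  dat <- mmlink:::prepare_sample_table(df, "tnsc")
  m1 <- study_model("model1")
  part <- make_partition(dat$m, 10, 3)
  ce <- cross_entropy_loss(m1$spec, dat, part)
  expect_gte(as.numeric(ce), 0)
  # permuting samples together with their block labels leaves CE unchanged
  set.seed(8)
  perm <- sample(dat$m)
  dperm <- mmlink:::mml_data_subset(dat, perm)
  pperm <- part
  pperm$assignment <- part$assignment[perm]
  expect_equal(as.numeric(cross_entropy_loss(m1$spec, dperm, pperm)),
               as.numeric(ce), tolerance = 1e-10)
  # the generating specification beats a misspecified alternative on
  # average over partitions
  wrong <- mixed_link_spec("baseline", c("cloglog", "cloglog"), "npo",
                           d = 1, covariate_names = "tnsc")
  ce_true <- ce_wrong <- numeric(5)
  for (r in 1:5) {
    pr <- make_partition(dat$m, 10, 30 + r)
    ce_true[r] <- cross_entropy_loss(m1$spec, dat, pr)
    ce_wrong[r] <- cross_entropy_loss(wrong, dat, pr)
  }
  expect_lt(mean(ce_true), mean(ce_wrong))
})

test_that("the one-sided paired t-test matches the t distribution", {
  # differences (-0.1, -0.2, -0.3): t = -3.464, df = 2
  b <- c(0.5, 0.6, 0.7)
  a <- b + c(-0.1, -0.2, -0.3)
  p <- compare_models_ttest(a, b)
  tstat <- mean(a - b) / (sd(a - b) / sqrt(3))
  expect_equal(tstat, -3.464102, tolerance = 1e-6)
  expect_equal(p, pt(tstat, df = 2), tolerance = 1e-12)
  expect_equal(p, 0.03709, tolerance = 1e-3)
  # wrong-direction alternative
  expect_gt(compare_models_ttest(b + 0.2 + rnorm(3, 0, 1e-3), b), 0.9)
  # degenerate cases
  expect_error(compare_models_ttest(b, b), "zero")
  expect_equal(compare_models_ttest(b - 0.1, b), 0)
  expect_equal(compare_models_ttest(b + 0.1, b), 1)
  expect_error(compare_models_ttest(1:3, 1:4), "paired")
})

test_that("paired t-test p-values are Uniform(0,1) under exchangeability", {
  set.seed(99)
  pvals <- replicate(500, {
    base <- rnorm(10, 1, 0.2)
    a <- base + rnorm(10, 0, 0.05)
    b <- base + rnorm(10, 0, 0.05)
    compare_models_ttest(a, b)
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cv_compare returns a CE matrix and p-value matrix", {
  df <- simulate_study_data("model1", n = 200, seed = 23)
  dat <- mmlink:::prepare_sample_table(df, "tnsc")
  m1 <- study_model("model1")
  wrong <- mixed_link_spec("baseline", c("cloglog", "cloglog"), "npo",
                           d = 1, covariate_names = "tnsc")
  cv <- suppressWarnings(
    cv_compare(list(true = m1$spec, wrong = wrong), dat,
               folds = 5, partitions = 3, seed_base = 11))
  expect_equal(dim(cv$ce), c(3L, 2L))
  expect_true(all(cv$ce >= 0))
  expect_equal(cv$seeds, 11:13)
  expect_true(is.na(cv$p_values["true", "true"]))
  expect_true(cv$p_values["true", "wrong"] >= 0 &&
                cv$p_values["true", "wrong"] <= 1)
})
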