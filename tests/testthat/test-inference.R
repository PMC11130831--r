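test_that("linear predictors reproduce the published fitted equations", {
  m1 <- study_model("model1")
  expect_equal(linear_predictor(m1$spec, m1$theta, 0), c(4.023, 4.905))
  # at TNSC = 9515.38 the first predictor crosses zero
  eta <- linear_predictor(m1$spec, m1$theta, 9515.38)
  expect_equal(eta[1], 4.023 - 4.228e-4 * 9515.38, tolerance = 1e-12)
  m2 <- study_model("model2")
  # negative-atrophy sample at TNSC = 0: intercepts plus the negative dummy
  x <- c(0, 0, 0, 1, 0)
  expect_equal(linear_predictor(m2$spec, m2$theta, x),
               c(-1.859 + 6.469, 0.136 + 6.469))
  sp <- mixed_link_spec("baseline", c("logit", "logit"), "npo", d = 2)
  expect_equal(linear_predictor(sp, rep(0, 6), c(1, 2)), c(0, 0))
  expect_error(linear_predictor(sp, rep(0, 6), c(1, 2, 3)), "dimension")
})

test_that("category probabilities compose links and structure", {
  m1 <- study_model("model1")
  # closed-form composition at TNSC = 9515.38
  eta <- c(4.023 - 4.228e-4 * 9515.38, 4.905 - 4.228e-4 * 9515.38)
  rho <- c(exp(-exp(-eta[1])), plogis(eta[2]))
  expect_equal(category_probs(m1$spec, m1$theta, 9515.38),
               c(rho[1], rho[2] - rho[1], 1 - rho[2]), tolerance = 1e-12)
  expect_equal(category_probs(m1$spec, m1$theta, 9515.38)[1], exp(-1),
               tolerance = 1e-3)
  sp <- mixed_link_spec("baseline", c("logit", "logit"), "npo", d = 1)
  expect_equal(category_probs(sp, rep(0, 4), 2.5), rep(1 / 3, 3))
})

test_that("all-logit mixed-link probabilities equal the classical models", {
  set.seed(5)
  for (s in c("baseline", "cumulative", "adjacent", "continuation")) {
    sp <- mixed_link_spec(s, c("logit", "logit"), "npo", d = 1)
    for (r in 1:20) {
      theta <- rnorm(4, 0, 0.8)
      if (s == "cumulative") theta[2] <- theta[1] + abs(theta[2]) + 0.1
      x <- rnorm(1)
      eta <- linear_predictor(sp, theta, x)
      ok <- tryCatch({
        p <- category_probs(sp, theta, x)
        expect_equal(p, classical_logit_probs(s, eta), tolerance = 1e-10,
                     info = s)
        TRUE
      }, error = function(e) FALSE)   # cumulative npo can be infeasible
      if (s != "cumulative") expect_true(ok)
    }
  }
})

test_that("log-likelihood matches a direct per-observation summation", {
  dat <- tiny_study_data("model1", n = 80, seed = 9)
  m1 <- study_model("model1")
  theta <- unname(m1$theta) * 0.9
  ll <- log_likelihood(m1$spec, theta, dat)
  # naive loop oracle
  acc <- 0
  for (i in seq_len(dat$m)) {
    p <- category_probs(m1$spec, theta, dat$X[i, ])
    acc <- acc + sum(dat$Y[i, ] * log(p))
  }
  expect_equal(ll, acc, tolerance = 1e-10)
  expect_lt(ll, 0)
  # single observation: the log of its label probability
  one <- mml_data(dat$X[1, , drop = FALSE], dat$Y[1, , drop = FALSE])
  p1 <- category_probs(m1$spec, theta, dat$X[1, ])
  expect_equal(log_likelihood(m1$spec, theta, one),
               log(p1[which(dat$Y[1, ] == 1)]))
})

test_that("infeasible parameters give -Inf, not an exception", {
  sp <- mixed_link_spec("cumulative", c("logit", "logit"), "npo", d = 1)
  dat <- tiny_study_data("model1", n = 40, seed = 2)
  # crossing intercepts with opposite slopes force non-monotone ratios
  theta <- c(2, -2, 0, 0)
  expect_identical(log_likelihood(sp, theta, dat), -Inf)
  expect_error(category_probs(sp, theta, dat$X), "infeasible")
})

test_that("intercept-only saturated fit recovers empirical frequencies", {
  counts <- c(30, 40, 54)
  Y <- matrix(0, 124, 3)
  labs <- rep(1:3, counts)
  Y[cbind(1:124, labs)] <- 1
  dat <- mml_data(matrix(0, 124, 0), Y)
  for (s in c("baseline", "cumulative", "adjacent", "continuation")) {
    sp <- mixed_link_spec(s, c("logit", "logit"), "npo", d = 0)
    fit <- fit_mle(sp, dat)
    expect_true(fit$converged, info = s)
    expect_equal(unname(category_probs(sp, unname(fit$theta), 1)),
                 counts / 124, tolerance = 1e-6, info = s)
    expect_equal(fit$loglik, sum(counts * log(counts / 124)),
                 tolerance = 1e-8, info = s)
  }
})
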