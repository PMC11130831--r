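test_that("accepted scoring iterations never decrease the log-likelihood", {
  dat <- tiny_study_data("model1", n = 300, seed = 4)
  for (m in list(c("cumulative", "po"), c("adjacent", "npo"),
                 c("baseline", "po"))) {
    sp <- mixed_link_spec(m[1], c("loglog", "logit"), m[2], d = 1,
                          covariate_names = "tnsc")
    fit <- fit_mle(sp, dat, trace = TRUE)
    expect_true(all(diff(fit$loglik_trace) >= -1e-12),
                info = paste(m, collapse = "-"))
  }
})

test_that("all-logit fits agree with nnet::multinom and MASS::polr", {
  skip_if_not_installed("nnet")
  dat <- tiny_study_data("model2", n = 124, seed = 3)
  labs <- max.col(dat$Y)
  Xdf <- as.data.frame(dat$X)
  # baseline-category npo logit == multiclass logistic regression
  spb <- mixed_link_spec("baseline", c("logit", "logit"), "npo", d = 5,
                         covariate_names = dat$covariate_names)
  fb <- fit_mle(spb, dat)
  Xdf$y <- relevel(factor(c("Normal", "MIM", "IM")[labs],
                          levels = c("Normal", "MIM", "IM")), ref = "IM")
  mn <- nnet::multinom(y ~ tnsc + mild + moderate + negative + unknown,
                       Xdf, trace = FALSE, maxit = 1000, reltol = 1e-14)
  expect_equal(fb$loglik, as.numeric(logLik(mn)), tolerance = 1e-5)
  # cumulative po logit == proportional-odds logistic regression
  spc <- mixed_link_spec("cumulative", c("logit", "logit"), "po", d = 5,
                         covariate_names = dat$covariate_names)
  fc <- fit_mle(spc, dat)
  Xdf$yo <- factor(c("Normal", "MIM", "IM")[labs],
                   levels = c("Normal", "MIM", "IM"), ordered = TRUE)
  pl <- MASS::polr(yo ~ tnsc + mild + moderate + negative + unknown, Xdf,
                   method = "logistic")
  expect_gte(fc$loglik, as.numeric(logLik(pl)) - 1e-5)
  # polr models log odds of lower categories with -beta slopes
  expect_equal(unname(fc$theta["tnsc"]), -unname(coef(pl)["tnsc"]),
               tolerance = 1e-3)
})

test_that("scoring matches a derivative-free optimizer on small instances", {
  dat <- tiny_study_data("model1", n = 30, seed = 6)
  for (m in list(c("baseline", "npo"), c("adjacent", "po"),
                 c("continuation", "npo"), c("cumulative", "po"))) {
    sp <- mixed_link_spec(m[1], c("logit", "logit"), m[2], d = 1,
                          covariate_names = "tnsc")
    fit <- fit_mle(sp, dat)
    # generic optimizer from the same (scaled) starting point
    sdat <- dat
    sdat$X <- scale(dat$X)
    sdat <- mml_data(sdat$X, dat$Y)
    nll <- function(th) {
      ll <- log_likelihood(sp, th, sdat)
      if (!is.finite(ll)) 1e10 else -ll
    }
    par <- mmlink:::initial_theta(sp, sdat)
    for (restart in 1:4)
      par <- optim(par, nll, method = "Nelder-Mead",
                   control = list(maxit = 20000, reltol = 1e-14))$par
    expect_lt(abs(fit$loglik - (-nll(par))), 1e-6)
  }
})

test_that("Wald inference gives textbook intervals and p-values", {
  mock <- structure(list(
    spec = mixed_link_spec("baseline", c("logit", "logit"), "npo", d = 0),
    theta = c(beta0_1 = 0, beta0_2 = 1.959963984540054),
    vcov = diag(2), converged = TRUE, p = 2L), class = "mml_fit")
  w0 <- wald_inference(mock, 1)
  expect_equal(unname(w0[c("lower", "upper")]),
               c(-1.959964, 1.959964), tolerance = 1e-6)
  expect_equal(unname(w0["p_value"]), 1)
  w1 <- wald_inference(mock, 2)
  expect_equal(unname(w1["p_value"]), 0.05, tolerance = 1e-8)
  mock$converged <- FALSE
  expect_error(wald_inference(mock, 1), "converged")
})

test_that("TNSC slope is recovered and significant on simulated data", {
  m1 <- study_model("model1")
  df <- simulate_study_data("model1", n = 4000, seed = 77)
  dat <- mmlink:::prepare_sample_table(df, "tnsc")
  fit <- fit_mle(m1$spec, dat)
  expect_true(fit$converged)
  w <- wald_inference(fit, "tnsc")
  expect_lt(w[["p_value"]], 1e-6)
  se <- sqrt(fit$vcov["tnsc", "tnsc"])
  expect_lt(abs(fit$theta[["tnsc"]] - (-4.228e-4)), 4 * se)
  expect_true(all(diag(fit$vcov) >= 0))
  # standard errors shrink roughly like n^{-1/2}
  df2 <- simulate_study_data("model1", n = 1000, seed = 78)
  fit2 <- fit_mle(m1$spec, mmlink:::prepare_sample_table(df2, "tnsc"))
  ratio <- sqrt(fit2$vcov["tnsc", "tnsc"]) / se
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("fitted models serialize to JSON and back", {
  dat <- tiny_study_data("model1", n = 80, seed = 10)
  fit <- fit_mle(study_model("model1")$spec, dat)
  path <- tempfile(fileext = ".json")
  fit_to_json(fit, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$structure, "cumulative")
  expect_equal(doc$odds, "po")
  expect_equal(doc$loglik, fit$loglik)
  expect_equal(doc$coefficients$tnsc, unname(fit$theta["tnsc"]))
  expect_equal(doc$aic, fit$aic)
})
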