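# shared fixtures, all generated in code

# random points on the open probability simplex
random_simplex <- function(n, J, seed = 1) {
  set.seed(seed)
  g <- matrix(stats::rgamma(n * J, shape = 1), n, J)
  g / rowSums(g)
}

# small individual-level dataset from a given study model
tiny_study_data <- function(model = "model1", n = 60, seed = 42) {
  df <- simulate_study_data(model, n = n, seed = seed)
  m <- study_model(model)
  mmlink:::prepare_sample_table(df, m$covariate_set)
}

# classical multinomial logit probabilities (models with a shared logit
# link), computed straight from their defining ratio equations -- the
# independent oracle for the all-logit special case
classical_logit_probs <- function(structure, eta) {
  # eta: vector length J-1
  q <- length(eta)
  J <- q + 1L
  switch(structure,
    baseline = {
      e <- exp(c(eta, 0))
      e / sum(e)
    },
    cumulative = {
      gamma <- stats::plogis(eta)          # P(Y <= j)
      diff(c(0, gamma, 1))
    },
    adjacent = {
      # log(pi_j / pi_{j+1}) = eta_j
      logpi <- rev(cumsum(rev(c(eta, 0))))
      e <- exp(logpi - max(logpi))
      e / sum(e)
    },
    continuation = {
      # log(pi_j / (pi_{j+1} + ... + pi_J)) = eta_j
      pi <- numeric(J)
      rest <- 1
      for (j in seq_len(q)) {
        rho <- stats::plogis(eta[j])
        pi[j] <- rho * rest
        rest <- rest * (1 - rho)
      }
      pi[J] <- rest
      pi
    })
}

# write a study CSV to a temp file and return the path
write_study_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
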