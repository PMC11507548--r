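test_that("OLS recovers the truth on near-noiseless data and matches the
           normal-equation oracle", {
  m <- fixed_linear_model(tau = 1e12)
  set.seed(21)
  p <- draw_true_parameters(m)
  d <- simulate_dataset(m, p, predictor_design(c("age", "weight")),
                        data_structure(40))
  fit <- fit_ols_linear(d)
  expect_true(fit$success)
  expect_equal(unname(fit$diagnostics$coefficients),
               unname(p[c("beta0", "beta1", "beta2")]), tolerance = 1e-6)
  expect_equal(fit$predicted_length,
               mean_length(m, p, 34, 2.5), tolerance = 1e-6)

  # independent oracle: solve the normal equations directly
  m2 <- fixed_linear_model(tau = 100)
  set.seed(22)
  p2 <- draw_true_parameters(m2)
  d2 <- simulate_dataset(m2, p2, predictor_design(c("age", "weight")),
                         data_structure(20, age_bias = 0.8, weight_bias = 1.2))
  X <- cbind(1, log(d2$recorded$age), d2$recorded$weight)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d2$length)
  fit2 <- fit_ols_linear(d2)
  expect_equal(unname(fit2$diagnostics$coefficients),
               as.numeric(beta_oracle), tolerance = 1e-8)
})

test_that("OLS flags rank-deficient designs instead of predicting", {
  d <- structure(list(
    recorded = data.frame(age = rep(10, 8), weight = rep(3, 8)),
    truth = data.frame(age = rep(10, 8), weight = rep(3, 8)),
    length = rnorm(8, 2.5, 0.1), true_params = NULL, model_version = 1L,
    n = 8L), class = "growth_dataset")
  fit <- fit_ols_linear(d)
  expect_false(fit$success)
  expect_equal(fit$failure_reason, "singular design")
  expect_true(is.na(fit$predicted_length))
})

test_that("nonlinear least squares recovers the truth and beats a grid
           search", {
  m <- fixed_nonlinear_model(tau = 1e10)
  set.seed(31)
  p <- draw_true_parameters(m)
  d <- simulate_dataset(m, p, predictor_design("age"), data_structure(60))
  fit <- fit_nls_nonlinear(d)
  expect_true(fit$success)
  expect_equal(unname(fit$diagnostics$coefficients),
               unname(p[c("alpha", "beta3", "gamma")]), tolerance = 1e-4)

  # grid-search oracle on a noisy fixture: the optimizer's RSS must be at
  # least as small as the best of 50^3 grid points
  m2 <- fixed_nonlinear_model(tau = 100)
  set.seed(32)
  p2 <- draw_true_parameters(m2)
  d2 <- simulate_dataset(m2, p2, predictor_design("age"), data_structure(25))
  fit2 <- fit_nls_nonlinear(d2)
  expect_true(fit2$success)
  alphas <- seq(1, 3, length.out = 50)
  beta3s <- seq(0.5, 3, length.out = 50)
  gammas <- seq(0.02, 0.98, length.out = 50)
  gx <- outer(gammas, d2$recorded$age, `^`)     # 50 x n
  best <- Inf
  for (a in alphas) {
    for (j in seq_along(beta3s)) {
      resid <- matrix(a, nrow = 50, ncol = d2$n) - beta3s[j] * gx -
        matrix(d2$length, nrow = 50, ncol = d2$n, byrow = TRUE)
      best <- min(best, min(rowSums(resid^2)))
    }
  }
  expect_lte(fit2$diagnostics$rss, best)
})

test_that("nonlinear least squares refuses tiny samples", {
  m <- fixed_nonlinear_model()
  set.seed(33)
  d <- simulate_dataset(m, draw_true_parameters(m), predictor_design("age"),
                        data_structure(2))
  fit <- fit_nls_nonlinear(d)
  expect_false(fit$success)
  expect_true(is.na(fit$predicted_length))
})

test_that("vague-prior posterior means agree with OLS on a clean n=100
           fixture", {
  m <- fixed_linear_model(tau = 100)
  set.seed(41)
  p <- draw_true_parameters(m)
  d <- simulate_dataset(m, p, predictor_design(c("age", "weight")),
                        data_structure(100))
  ols <- fit_ols_linear(d)
  set.seed(42)
  bay <- fit_bayes(d, m)
  expect_true(bay$success)
  pm <- bay$diagnostics$posterior_mean[c("beta0", "beta1", "beta2")]
  ps <- bay$diagnostics$posterior_sd[c("beta0", "beta1", "beta2")]
  expect_true(all(abs(pm - ols$diagnostics$coefficients) < 3 * ps))
  expect_equal(bay$predicted_length, ols$predicted_length, tolerance = 0.02)
  expect_equal(bay$diagnostics$n_retained, 1000L)
})

test_that("the Metropolis-within-Gibbs chain is reproducible under a seed", {
  m <- fixed_nonlinear_model()
  set.seed(51)
  d <- simulate_dataset(m, draw_true_parameters(m), predictor_design("age"),
                        data_structure(40))
  set.seed(52)
  a <- fit_bayes(d, m)
  set.seed(52)
  b <- fit_bayes(d, m)
  expect_identical(a$predicted_length, b$predicted_length)
  expect_identical(a$diagnostics$posterior_mean, b$diagnostics$posterior_mean)
})

test_that("the sampler agrees with an independent Gibbs implementation", {
  # cross-check posterior means against JAGS on one nonlinear fixture
  m <- fixed_nonlinear_model(tau = 100)
  set.seed(61)
  p <- draw_true_parameters(m)
  d <- simulate_dataset(m, p, predictor_design("age"), data_structure(100))
  set.seed(62)
  mine <- fit_bayes(d, m, settings = mcmc_settings(burn_in = 1000,
                                                   samples = 2000))
  jm <- rjags::jags.model(textConnection("
    model {
      for (i in 1:n) { y[i] ~ dnorm(alpha - beta3 * pow(gamma, x[i]), tau) }
      alpha ~ dnorm(0, 1.0E-6)
      beta3 ~ dnorm(0, 1.0E-6)
      gamma ~ dunif(0, 1)
      tau ~ dgamma(1.0E-3, 1.0E-3)
    }"), data = list(y = d$length, x = d$recorded$age, n = d$n),
    n.chains = 1, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("alpha", "beta3", "gamma"), 4000,
                           progress.bar = "none")
  ref <- summary(s)$statistics
  for (par in c("alpha", "beta3", "gamma")) {
    expect_lt(abs(mine$diagnostics$posterior_mean[[par]] - ref[par, "Mean"]),
              ref[par, "SD"])
  }
})

test_that("fit dispatch routes by estimator family and model", {
  m1 <- fixed_linear_model()
  m2 <- fixed_nonlinear_model()
  set.seed(71)
  d1 <- simulate_dataset(m1, draw_true_parameters(m1),
                         predictor_design(c("age", "weight")),
                         data_structure(30))
  d2 <- simulate_dataset(m2, draw_true_parameters(m2),
                         predictor_design("age"), data_structure(30))
  ls <- least_squares_method()
  expect_equal(fit_growth_model(ls, m1, d1)$predicted_length,
               fit_ols_linear(d1)$predicted_length)
  expect_equal(fit_growth_model(ls, m2, d2)$predicted_length,
               fit_nls_nonlinear(d2)$predicted_length)
  set.seed(72)
  via_dispatch <- fit_growth_model(bayesian_method(), m2, d2)
  set.seed(72)
  direct <- fit_bayes(d2, m2)
  expect_identical(via_dispatch$predicted_length, direct$predicted_length)
  expect_true(is.finite(via_dispatch$predicted_length))
})
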