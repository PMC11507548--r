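test_that("true parameters are drawn uniformly inside the stated bounds", {
  set.seed(2024)
  m1 <- linear_growth_model()
  draws <- replicate(1000, draw_true_parameters(m1))
  for (p in rownames(draws)) {
    b <- m1$param_bounds[[p]]
    expect_true(all(draws[p, ] >= b[1] & draws[p, ] <= b[2]))
  }
  # uniform-mean oracle: E[beta0] = (0+3)/2, se = sqrt(9/12/n)
  n <- 1e5
  b0 <- replicate(n, draw_true_parameters(m1)[["beta0"]])
  expect_lt(abs(mean(b0) - 1.5), 3 * sqrt(0.75 / n))
})

test_that("degenerate bounds and fixed parameters pin the truth", {
  m <- linear_growth_model(beta0_bounds = c(2, 2), beta1_bounds = c(0, 0),
                           beta2_bounds = c(0.5, 0.5), tau_bounds = c(100, 100))
  expect_equal(unname(draw_true_parameters(m)),
               c(2, 0, 0.5, 100))
  expect_equal(draw_true_parameters(fixed_nonlinear_model()),
               c(alpha = 2.6, beta3 = 1.2, gamma = 0.85, tau = 100))
})

test_that("mean functions evaluate to hand-checked values", {
  m1 <- linear_growth_model()
  # slope-free model: mean equals the intercept everywhere
  expect_equal(mean_length(m1, c(beta0 = 2.6, beta1 = 0, beta2 = 0, tau = 100),
                           age = 12, weight = 7), 2.6)
  # hand evaluation: 1 + 0.3*ln(34) + 0.2*2.5
  expect_equal(mean_length(m1, c(beta0 = 1, beta1 = 0.3, beta2 = 0.2, tau = 100),
                           age = 34, weight = 2.5),
               2.5579081574, tolerance = 1e-9)
  m2 <- nonlinear_growth_model()
  # analytic limit: 3 - 0.5^34 is 3 up to 6e-11
  expect_equal(mean_length(m2, c(alpha = 3, beta3 = 1, gamma = 0.5, tau = 100),
                           age = 34), 3, tolerance = 1e-9)
  expect_error(mean_length(m2, c(alpha = 3, beta3 = 1, gamma = 1.4, tau = 100),
                           age = 34), "gamma")
  expect_error(mean_length(m1, c(beta0 = 1, beta1 = 0.3, beta2 = 0.2, tau = 100),
                           age = 34), "weight")
  expect_error(mean_length(m1, c(beta0 = 1, beta1 = 0.3, beta2 = 0.2, tau = 100),
                           age = -1, weight = 1), "positive")
})

test_that("nonlinear mean length increases with age over a grid", {
  m2 <- nonlinear_growth_model()
  set.seed(5)
  for (i in 1:20) {
    p <- draw_true_parameters(m2)
    mu <- mean_length(m2, p, age = seq(0.5, 70, by = 0.5))
    # non-decreasing everywhere (gamma^age underflows to 0 at high ages,
    # where the curve is flat at machine precision), strictly rising early
    expect_true(all(diff(mu) >= 0))
    expect_gt(mu[10] - mu[1], 0)
  }
})

test_that("simulated datasets apply recording bias to predictors only", {
  set.seed(9)
  m1 <- fixed_linear_model()
  d <- simulate_dataset(m1, draw_true_parameters(m1),
                        predictor_design(c("age", "weight")),
                        data_structure(50, age_bias = 0.8, weight_bias = 1.2))
  expect_equal(d$recorded$age, 0.8 * d$truth$age)
  expect_equal(d$recorded$weight, 1.2 * d$truth$weight)
  # unit bias factors record the truth exactly
  d2 <- simulate_dataset(m1, draw_true_parameters(m1),
                         predictor_design(c("age", "weight")),
                         data_structure(50))
  expect_identical(d2$recorded, d2$truth)
  expect_true(all(is.finite(d$length)))
  expect_true(all(d$truth$age > 0))
})

test_that("response noise follows the stated precision", {
  # near-noiseless limit: responses match the mean function
  m <- fixed_linear_model(tau = 1e9)
  set.seed(3)
  p <- draw_true_parameters(m)
  d <- simulate_dataset(m, p, predictor_design(c("age", "weight")),
                        data_structure(100))
  mu <- mean_length(m, p, d$truth$age, d$truth$weight)
  expect_lt(max(abs(d$length - mu)), 1e-3)

  # variance oracle: Var(y - mu) = 1/tau
  m100 <- fixed_nonlinear_model(tau = 100)
  set.seed(4)
  p <- draw_true_parameters(m100)
  big <- simulate_dataset(m100, p, predictor_design("age"),
                          data_structure(1e5))
  resid <- big$length - mean_length(m100, p, big$truth$age)
  expect_equal(var(resid), 0.01, tolerance = 0.05)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- fixed_nonlinear_model()
  set.seed(77)
  a <- simulate_dataset(m, draw_true_parameters(m), predictor_design("age"),
                        data_structure(30))
  set.seed(77)
  b <- simulate_dataset(m, draw_true_parameters(m), predictor_design("age"),
                        data_structure(30))
  expect_identical(a, b)
})

test_that("a design missing a model-required predictor cannot simulate", {
  m1 <- fixed_linear_model()
  expect_error(
    simulate_dataset(m1, draw_true_parameters(m1), predictor_design("age"),
                     data_structure(10)),
    "non-permutable")
})

test_that("breeding status uses a strict 2.50 m threshold", {
  m1 <- linear_growth_model()
  certain <- c(beta0 = 2.6, beta1 = 0, beta2 = 0, tau = 100)
  exactly <- c(beta0 = 2.5, beta1 = 0, beta2 = 0, tau = 100)
  short <- c(beta0 = 2.2, beta1 = 0, beta2 = 0, tau = 100)
  expect_equal(true_status(m1, certain), "certain_to_breed")
  expect_equal(true_status(m1, exactly), "not_certain_to_breed")
  expect_equal(true_status(m1, short), "not_certain_to_breed")
})
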