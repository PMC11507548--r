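#' Fit-result container
#'
#' Every post-data method returns a `fit_result`.  On failure the predicted
#' length is absent (`NA`), never a silent placeholder, and the reason is
#' recorded; downstream rate estimation excludes failed fits from the
#' denominator.
#'
#' @param predicted_length Predicted mean length at the query (meters).
#' @param success Logical.
#' @param failure_reason Text reason when `success` is `FALSE`.
#' @param diagnostics Optional list (iteration counts, acceptance rates,
#'   coefficient estimates).
#' @return A `fit_result` object.
#' @keywords internal
#' @export
fit_result <- function(predicted_length = NA_real_, success = TRUE,
                       failure_reason = "", diagnostics = list()) {
  if (!success) predicted_length <- NA_real_
  structure(list(predicted_length = predicted_length, success = success,
                 failure_reason = failure_reason, diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<fit_result> predicted length %.4f m\n", x$predicted_length))
  } else {
    cat("<fit_result> FAILED:", x$failure_reason, "\n")
  }
  invisible(x)
}

#' Ordinary least squares fit of the linear growth model
#'
#' Regresses length on log recorded age and recorded weight by QR-based
#' least squares and predicts the mean length at the query point from the
#' point estimates.
#'
#' @param dataset A `growth_dataset` whose recorded predictors include both
#'   age and weight.
#' @param query A [query_point()].
#' @return A [fit_result()].  Rank-deficient designs fail with reason
#'   `"singular design"`.
#' @export
fit_ols_linear <- function(dataset, query = query_point()) {
  rec <- dataset$recorded
  if (is.null(rec$weight)) {
    stop("dataset does not record weight; OLS linear fit needs both predictors",
         call. = FALSE)
  }
  if (dataset$n <= 3) {
    return(fit_result(success = FALSE,
                      failure_reason = "fewer observations than parameters"))
  }
  X <- cbind(1, log(rec$age), rec$weight)
  fit <- stats::lm.fit(X, dataset$length)
  if (fit$rank < 3L) {
    return(fit_result(success = FALSE, failure_reason = "singular design"))
  }
  beta <- fit$coefficients
  pred <- beta[1] + beta[2] * log(query$age) + beta[3] * query$weight
  fit_result(predicted_length = unname(pred),
             diagnostics = list(coefficients = unname(beta)))
}

#' Nonlinear least squares fit of the asymptotic growth model
#'
#' Minimizes the residual sum of squares of
#' \eqn{y = \alpha - \beta_3\gamma^{x}} over \eqn{(\alpha, \beta_3,
#' \gamma)} with the Levenberg--Marquardt algorithm
#' ([minpack.lm::nls.lm()]), \eqn{\gamma} box-constrained to (0, 1).
#' Starts from a small deterministic grid
#' (\eqn{\alpha = \max y}, \eqn{\beta_3 = \max y - \min y},
#' \eqn{\gamma \in \{0.5, 0.9\}}) and keeps the converged solution with the
#' smallest RSS; if no start converges the fit fails (the "NA" case, later
#' excluded from rate denominators).
#'
#' @param dataset A `growth_dataset` (recorded age is used).
#' @param query A [query_point()].
#' @return A [fit_result()].
#' @export
fit_nls_nonlinear <- function(dataset, query = query_point()) {
  x <- dataset$recorded$age
  y <- dataset$length
  if (dataset$n < 3) {
    return(fit_result(success = FALSE,
                      failure_reason = "fewer observations than parameters"))
  }
  resid_fn <- function(p) y - (p[1] - p[2] * p[3]^x)
  starts <- list(c(max(y), max(max(y) - min(y), 0.1), 0.5),
                 c(max(y), max(max(y) - min(y), 0.1), 0.9))
  lower <- c(-Inf, -Inf, 1e-8)
  upper <- c(Inf, Inf, 1 - 1e-8)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:3 || !all(is.finite(fit$par))) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(fit_result(success = FALSE,
                      failure_reason = "nonlinear least squares did not converge from any start"))
  }
  p <- best$par
  pred <- p[1] - p[2] * p[3]^query$age
  if (!is.finite(pred)) {
    return(fit_result(success = FALSE,
                      failure_reason = "non-finite prediction"))
  }
  fit_result(predicted_length = pred,
             diagnostics = list(coefficients = stats::setNames(
               p, c("alpha", "beta3", "gamma")),
               rss = best$deviance, niter = best$niter))
}

#' Bayesian fit via Metropolis-within-Gibbs
#'
#' Samples the posterior of either growth model under the supplied priors
#' with component-wise random-walk Metropolis updates for the location
#' parameters (and the decay rate, with its Uniform(0, 1) prior enforced by
#' rejection), and a conjugate Gibbs draw for the error precision from its
#' conditional Gamma.  Proposal scales adapt toward a 40% acceptance rate
#' in batches during burn-in only, then freeze.  The reported prediction is
#' the posterior-predictive mean of the noiseless mean length at the query
#' point, i.e. the average of the mean function over the retained draws
#' (the additive noise term has mean zero and would only add Monte Carlo
#' variance).
#'
#' @param dataset A `growth_dataset`.
#' @param model The growth model to fit (its bounds are not used in the
#'   likelihood; priors come from `priors`).
#' @param priors A [vague_priors()] specification.
#' @param settings [mcmc_settings()].
#' @param query A [query_point()].
#' @return A [fit_result()] with acceptance-rate diagnostics and posterior
#'   means.  A chain whose retained draws are non-finite, or in which a
#'   random-walk coordinate never accepted after burn-in, fails with reason
#'   `"sampler failure"`.
#' @export
fit_bayes <- function(dataset, model, priors = vague_priors(),
                      settings = mcmc_settings(), query = query_point()) {
  stopifnot(inherits(priors, "prior_spec"), inherits(settings, "mcmc_settings"))
  if (!isTRUE(priors$vague)) {
    stop("informative priors cannot be assigned to this model ",
         "(non-permutable; should have been caught upstream)", call. = FALSE)
  }
  y <- dataset$length
  if (model$family == "linear") {
    rec <- dataset$recorded
    if (is.null(rec$weight)) {
      stop("dataset does not record weight; Bayesian linear fit needs both predictors",
           call. = FALSE)
    }
    out <- mcmc_linear_cpp(y, log(rec$age), rec$weight,
                           priors$location_precision,
                           priors$tau_shape, priors$tau_rate,
                           settings$burn_in, settings$samples,
                           settings$adapt_batch)
    draws <- out$draws
    pred_draws <- draws[, 1] + draws[, 2] * log(query$age) +
      draws[, 3] * query$weight
    par_names <- c("beta0", "beta1", "beta2", "tau")
  } else {
    out <- mcmc_nonlinear_cpp(y, dataset$recorded$age,
                              priors$location_precision,
                              priors$tau_shape, priors$tau_rate,
                              settings$burn_in, settings$samples,
                              settings$adapt_batch)
    draws <- out$draws
    pred_draws <- draws[, 1] - draws[, 2] * draws[, 3]^query$age
    par_names <- c("alpha", "beta3", "gamma", "tau")
  }
  accept <- out$accept_rate
  if (!all(is.finite(draws)) || any(accept == 0)) {
    return(fit_result(success = FALSE, failure_reason = "sampler failure",
                      diagnostics = list(accept_rate = accept)))
  }
  colnames(draws) <- par_names
  fit_result(
    predicted_length = mean(pred_draws),
    diagnostics = list(
      accept_rate = stats::setNames(accept, par_names[seq_along(accept)]),
      posterior_mean = colMeans(draws),
      posterior_sd = apply(draws, 2, stats::sd),
      n_retained = nrow(draws))
  )
}

#' Dispatch a post-data method on a dataset
#'
#' Routes to [fit_ols_linear()] (least squares, linear model),
#' [fit_nls_nonlinear()] (least squares, nonlinear model) or [fit_bayes()]
#' according to the estimator family and the model that generated the
#' permuted experiment.
#'
#' @param method An `estimator_method`.
#' @param model The growth model being fitted.
#' @param dataset A `growth_dataset`.
#' @param query A [query_point()].
#' @return A [fit_result()].
#' @export
fit_growth_model <- function(method, model, dataset, query = query_point()) {
  stopifnot(inherits(method, "estimator_method"),
            inherits(model, "growth_model"))
  if (method$family == "least_squares") {
    if (model$family == "linear") {
      fit_ols_linear(dataset, query)
    } else {
      fit_nls_nonlinear(dataset, query)
    }
  } else {
    fit_bayes(dataset, model, method$priors, method$mcmc, query)
  }
}
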