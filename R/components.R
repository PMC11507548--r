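#' Component roles of an idealized experiment
#'
#' An idealized experiment is the ordered tuple of five components:
#' background knowledge, pre-data methods, statistical model, post-data
#' methods, and data structure.  The ordering encodes epistemic precedence
#' (each component is conditional on components to its left).  Background
#' knowledge is carried as free-text annotation and is never permuted; the
#' remaining four roles are the permutable coordinates of the replication
#' distance.
#'
#' @return Character vector of the five roles in epistemic order.
#' @seealso [permutable_roles()]
#' @export
#' @examples
#' component_roles()
component_roles <- function() {
  c("background_k", "pre_data", "model", "post_data", "data_structure")
}

#' @rdname component_roles
#' @return For `permutable_roles()`, the four permutable roles, using the
#'   short column names (`spre`, `model`, `spost`, `dstruct`) that rate and
#'   distance tables use.
#' @export
permutable_roles <- function() {
  c("spre", "model", "spost", "dstruct")
}

#' Pre-data methods: which predictors a study provides
#'
#' The pre-data component (Spre) captures design-stage choices preceding
#' data collection.  In the growth-curve setting it reduces to the set of
#' predictor variables a study measures and the biologically plausible
#' ranges they are sampled from.
#'
#' @param variables Character subset of `c("age", "weight")`.  Age is in
#'   half-years, weight in units of 100 kg.
#' @param age_range Sampling range for age (half-years).  The default lower
#'   bound 0.5 respects half-year resolution and keeps `log(age)` finite.
#' @param weight_range Sampling range for weight (100 kg units).
#' @param label Optional display label.
#' @return A `predictor_design` object.
#' @export
#' @examples
#' predictor_design(c("age", "weight"))
#' predictor_design("age")
predictor_design <- function(variables = c("age", "weight"),
                             age_range = c(0.5, 70),
                             weight_range = c(0.2, 9),
                             label = NULL) {
  variables <- match.arg(variables, c("age", "weight"), several.ok = TRUE)
  if (!"age" %in% variables) {
    stop("a predictor design must provide at least `age`", call. = FALSE)
  }
  stopifnot(length(age_range) == 2, age_range[1] > 0,
            diff(age_range) >= 0, length(weight_range) == 2,
            diff(weight_range) >= 0)
  structure(
    list(variables = variables, age_range = as.numeric(age_range),
         weight_range = as.numeric(weight_range),
         label = label %||% paste("predictors:", paste(variables, collapse = ", "))),
    class = "predictor_design"
  )
}

#' Growth-curve models for the simulated studies
#'
#' Two generative models for dugong length are available.
#' `linear_growth_model()` is a Gauss--Markov linear regression on
#' log-transformed age and linear weight,
#' \deqn{y_i = \beta_0 + \beta_1 \log(x_{1i}) + \beta_2 x_{2i} + \epsilon_i,}
#' and `nonlinear_growth_model()` is an asymptotic growth curve on age only,
#' \deqn{y_i = \alpha - \beta_3 \gamma^{x_{1i}} + \epsilon_i,}
#' both with independent Gaussian errors of precision \eqn{\tau}
#' (variance \eqn{1/\tau}).
#'
#' True parameter values used to generate data are drawn uniformly from the
#' stated bounds on every simulated replicate (see
#' [draw_true_parameters()]); pass `fixed_params` to pin them instead.
#'
#' @param beta0_bounds,beta1_bounds,beta2_bounds,tau_bounds Parameter bounds
#'   for the linear model: intercept (m), log-age slope (m per log
#'   half-year), weight slope (m per 100 kg), and error precision.
#' @param fixed_params Optional named numeric vector overriding the uniform
#'   draw with fixed true values.
#' @param reject_params Optional predicate `function(params)` returning
#'   `TRUE` for parameter draws to discard (a pilot-style exclusion of
#'   sub-regions that generate degenerate results); off (`NULL`) by
#'   default.
#' @param label Optional display label.
#' @return A `growth_model` object.
#' @export
#' @examples
#' linear_growth_model()
#' nonlinear_growth_model(fixed_params = c(alpha = 2.6, beta3 = 1.2,
#'                                         gamma = 0.85, tau = 100))
linear_growth_model <- function(beta0_bounds = c(0, 3),
                                beta1_bounds = c(0, 1),
                                beta2_bounds = c(0, 1),
                                tau_bounds = c(50, 250),
                                fixed_params = NULL,
                                reject_params = NULL,
                                label = "linear (log-age + weight)") {
  new_growth_model(
    version = 1L, family = "linear", label = label,
    required_predictors = c("age", "weight"),
    param_bounds = list(beta0 = beta0_bounds, beta1 = beta1_bounds,
                        beta2 = beta2_bounds, tau = tau_bounds),
    fixed_params = fixed_params, reject_params = reject_params
  )
}

#' @param alpha_bounds,beta3_bounds,gamma_bounds Parameter bounds for the
#'   nonlinear model: asymptotic length (m), length deficit at age zero (m),
#'   and dimensionless decay rate in (0, 1).
#' @rdname linear_growth_model
#' @export
nonlinear_growth_model <- function(alpha_bounds = c(1, 3),
                                   beta3_bounds = c(1, 3),
                                   gamma_bounds = c(0, 1),
                                   tau_bounds = c(50, 250),
                                   fixed_params = NULL,
                                   reject_params = NULL,
                                   label = "nonlinear (asymptotic, age only)") {
  new_growth_model(
    version = 2L, family = "nonlinear", label = label,
    required_predictors = "age",
    param_bounds = list(alpha = alpha_bounds, beta3 = beta3_bounds,
                        gamma = gamma_bounds, tau = tau_bounds),
    fixed_params = fixed_params, reject_params = reject_params
  )
}

new_growth_model <- function(version, family, label, required_predictors,
                             param_bounds, fixed_params,
                             reject_params = NULL) {
  stopifnot(is.null(reject_params) || is.function(reject_params))
  for (b in param_bounds) stopifnot(length(b) == 2, diff(b) >= 0)
  if (!is.null(fixed_params)) {
    missing <- setdiff(names(param_bounds), names(fixed_params))
    if (length(missing)) {
      stop("fixed_params must name: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    fixed_params <- fixed_params[names(param_bounds)]
  }
  structure(
    list(version = version, family = family, label = label,
         required_predictors = required_predictors,
         param_bounds = lapply(param_bounds, as.numeric),
         fixed_params = fixed_params, reject_params = reject_params),
    class = "growth_model"
  )
}

#' Data structure: sample size and recording quality
#'
#' The data-structure component (Ds) describes how many observations a
#' study collects and how faithfully predictors are recorded.  Bias factors
#' multiply the *recorded* predictor values used for fitting (a data
#' processing error); responses are always generated from the true values.
#'
#' @param n Sample size (positive integer).
#' @param age_bias,weight_bias Multipliers applied to recorded age and
#'   weight.  1 means faithful recording.
#' @param label Optional display label.
#' @return A `data_structure` object.
#' @export
#' @examples
#' data_structure(20, age_bias = 0.8, weight_bias = 1.2) # small, biased
#' data_structure(100)                                   # large, clean
data_structure <- function(n, age_bias = 1, weight_bias = 1, label = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1, n > 0, age_bias > 0, weight_bias > 0)
  structure(
    list(n = n, age_bias = as.numeric(age_bias),
         weight_bias = as.numeric(weight_bias),
         label = label %||% sprintf("n=%d (age bias %.2g, weight bias %.2g)",
                                    n, age_bias, weight_bias)),
    class = "data_structure"
  )
}

#' Post-data methods: how a dataset is turned into a prediction
#'
#' The post-data component (Spost) is the statistical analysis applied to a
#' simulated dataset.  `least_squares_method()` fits the linear model by
#' ordinary least squares and the nonlinear model by Levenberg--Marquardt
#' nonlinear least squares.  `bayesian_method()` fits either model by
#' Metropolis-within-Gibbs MCMC under the supplied priors and reports the
#' posterior-predictive mean length at the query point.
#'
#' @param label Optional display label.
#' @return An `estimator_method` object.
#' @seealso [vague_priors()], [mcmc_settings()], [fit_growth_model()]
#' @export
#' @examples
#' least_squares_method()
#' bayesian_method()
least_squares_method <- function(label = "least squares (OLS / Levenberg-Marquardt NLS)") {
  structure(list(family = "least_squares", priors = NULL, mcmc = NULL,
                 label = label),
            class = "estimator_method")
}

#' @param priors A prior specification, normally [vague_priors()].
#' @param mcmc Sampler settings from [mcmc_settings()].
#' @rdname least_squares_method
#' @export
bayesian_method <- function(priors = vague_priors(),
                            mcmc = mcmc_settings(),
                            label = "Bayesian (MCMC, posterior-predictive mean)") {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_settings"))
  structure(list(family = "bayesian", priors = priors, mcmc = mcmc,
                 label = label),
            class = "estimator_method")
}

#' Prior specifications for the Bayesian post-data method
#'
#' `vague_priors()` declares the standard diffuse prior set: Normal(0,
#' precision 1e-6) on every location/slope parameter (note the
#' *precision* parameterization, so the variance is 1e6), Uniform(0, 1) on
#' the decay rate of the nonlinear model, and Gamma(1e-3, 1e-3) on the
#' error precision.  Because the location priors carry essentially no
#' information, they transfer unchanged to the parameters of *any* growth
#' model, which is what makes cross-permutations of a Bayesian method onto
#' the other study's model performable.
#'
#' `informative_priors()` declares priors tied to named parameters of one
#' particular model.  Without a declared transform they do not transfer, so
#' permutations onto a model with different parameters are flagged
#' non-permutable by [is_permutable()].
#'
#' @param location_mean,location_precision Normal prior mean and precision
#'   for location/slope parameters.
#' @param tau_shape,tau_rate Gamma prior shape and rate for the error
#'   precision.
#' @return A `prior_spec` object.
#' @export
#' @examples
#' vague_priors()
#' informative_priors(declared_for = c("alpha", "beta3", "gamma", "tau"))
vague_priors <- function(location_mean = 0, location_precision = 1e-6,
                         tau_shape = 1e-3, tau_rate = 1e-3) {
  structure(
    list(vague = TRUE, declared_for = NULL,
         location_mean = location_mean,
         location_precision = location_precision,
         tau_shape = tau_shape, tau_rate = tau_rate),
    class = "prior_spec"
  )
}

#' @param declared_for Character vector naming the model parameters the
#'   informative priors are declared for.
#' @param transforms Reserved; transforms between model parameterizations
#'   are not implemented, so informative priors never transfer.
#' @rdname vague_priors
#' @export
informative_priors <- function(declared_for, transforms = NULL) {
  if (!is.null(transforms)) {
    stop("prior transforms between model parameterizations are not supported",
         call. = FALSE)
  }
  structure(
    list(vague = FALSE, declared_for = as.character(declared_for),
         location_mean = NA_real_, location_precision = NA_real_,
         tau_shape = NA_real_, tau_rate = NA_real_),
    class = "prior_spec"
  )
}

#' MCMC settings for the Bayesian post-data method
#'
#' One chain, burn-in-only proposal adaptation, no thinning.  The retained
#' sample count equals `samples` exactly.
#'
#' @param chains Number of chains; only 1 is supported.
#' @param burn_in Burn-in iterations (proposal scales adapt during burn-in
#'   only, in batches of `adapt_batch`).
#' @param samples Retained post-burn-in iterations.
#' @param adapt_batch Batch size for acceptance-rate based proposal
#'   adaptation during burn-in.
#' @return An `mcmc_settings` object.
#' @export
#' @examples
#' mcmc_settings()
mcmc_settings <- function(chains = 1L, burn_in = 1000L, samples = 1000L,
                          adapt_batch = 50L) {
  chains <- as.integer(chains)
  if (chains != 1L) stop("only single-chain MCMC is supported", call. = FALSE)
  stopifnot(burn_in >= 0, samples >= 1, adapt_batch >= 1)
  structure(list(chains = chains, burn_in = as.integer(burn_in),
                 samples = as.integer(samples),
                 adapt_batch = as.integer(adapt_batch)),
            class = "mcmc_settings")
}

#' Prediction query point
#'
#' The fixed covariate values at which every fitted study predicts mean
#' length: age 34 half-years (17 years, the latest age at which dugongs
#' reach breeding age) and weight 2.5 in 100 kg units (250 kg, the minimum
#' mean breeding weight at that age).  The query always uses the nominal
#' scientific values even when a study fitted on biased recordings: the
#' recording bias is a property of the data, not of the question.
#'
#' @param age Age in half-years (must be positive).
#' @param weight Weight in 100 kg units.
#' @return A `query_point` object.
#' @export
#' @examples
#' query_point()
query_point <- function(age = 34, weight = 2.5) {
  stopifnot(age > 0)
  structure(list(age = as.numeric(age), weight = as.numeric(weight)),
            class = "query_point")
}

#' Breeding-status classification rule
#'
#' A dugong with predicted mean length strictly greater than the threshold
#' (2.50 m by default) is classified `"certain_to_breed"`, otherwise
#' `"not_certain_to_breed"`.  Exactly 2.50 m is *not* certain to breed.
#'
#' @param length Numeric vector of mean lengths in meters.
#' @param threshold Classification threshold in meters.
#' @return Character vector of statuses.
#' @export
#' @examples
#' classify_breeding(c(2.2, 2.5, 2.6))
classify_breeding <- function(length, threshold = 2.5) {
  ifelse(length > threshold, "certain_to_breed", "not_certain_to_breed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.predictor_design <- function(x, ...) {
  cat("<predictor_design>", x$label, "\n")
  invisible(x)
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model v%d> %s\n", x$version, x$label))
  for (p in names(x$param_bounds)) {
    cat(sprintf("  %-6s in [%g, %g]%s\n", p, x$param_bounds[[p]][1],
                x$param_bounds[[p]][2],
                if (!is.null(x$fixed_params))
                  sprintf("  (fixed at %g)", x$fixed_params[[p]]) else ""))
  }
  invisible(x)
}

#' @export
print.data_structure <- function(x, ...) {
  cat("<data_structure>", x$label, "\n")
  invisible(x)
}

#' @export
print.estimator_method <- function(x, ...) {
  cat("<estimator_method>", x$family, "-", x$label, "\n")
  invisible(x)
}
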