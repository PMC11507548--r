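#' Draw true generating parameters for a growth model
#'
#' Each parameter is drawn independently and uniformly over the model's
#' bounds.  By default this happens anew for every Monte Carlo replicate,
#' so reproducibility rates integrate over the biologically plausible
#' parameter box rather than conditioning on one true value; models built
#' with `fixed_params` return those values instead (useful for pinning the
#' truth in tests or sensitivity studies).  A model's optional
#' `reject_params` hook discards draws from excluded sub-regions
#' (rejection sampling, capped at 1000 consecutive rejections).
#'
#' @param model A growth model.
#' @return Named numeric vector of parameter values.
#' @export
#' @examples
#' set.seed(1)
#' draw_true_parameters(linear_growth_model())
draw_true_parameters <- function(model) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.null(model$fixed_params)) {
    return(model$fixed_params)
  }
  for (try in 1:1000) {
    p <- vapply(model$param_bounds, function(b) runif(1, b[1], b[2]),
                numeric(1))
    if (is.null(model$reject_params) || !isTRUE(model$reject_params(p))) {
      return(p)
    }
  }
  stop("reject_params discarded 1000 consecutive draws; the retained ",
       "region is (near-)empty", call. = FALSE)
}

#' Noiseless mean length under a growth model
#'
#' Evaluates the mean function: for the linear model
#' \eqn{\beta_0 + \beta_1\log(x_1) + \beta_2 x_2}; for the nonlinear model
#' \eqn{\alpha - \beta_3\gamma^{x_1}} (the weight argument, if supplied, is
#' ignored).  Vectorized over `age` and `weight`.
#'
#' @param model A growth model.
#' @param params Named parameter vector (see [draw_true_parameters()]).
#' @param age Age in half-years; must be positive for the linear model.
#' @param weight Weight in 100 kg units (linear model only).
#' @return Numeric vector of mean lengths in meters.
#' @export
#' @examples
#' mean_length(linear_growth_model(),
#'             c(beta0 = 1, beta1 = 0.3, beta2 = 0.2, tau = 100),
#'             age = 34, weight = 2.5)
mean_length <- function(model, params, age, weight = NULL) {
  stopifnot(inherits(model, "growth_model"))
  if (model$family == "linear") {
    if (is.null(weight)) {
      stop("the linear model requires `weight`", call. = FALSE)
    }
    if (any(age <= 0)) stop("age must be positive (log transform)", call. = FALSE)
    params[["beta0"]] + params[["beta1"]] * log(age) +
      params[["beta2"]] * weight
  } else {
    g <- params[["gamma"]]
    if (g < 0 || g > 1) {
      stop("gamma outside [0, 1]: mean function undefined", call. = FALSE)
    }
    params[["alpha"]] - params[["beta3"]] * g^age
  }
}

#' Simulate one dataset for a permuted experiment
#'
#' Draws `n` true predictor vectors uniformly from the design's sampling
#' ranges, computes responses as the model's mean length plus Gaussian
#' noise with precision `tau`, and records predictors *after* applying the
#' data structure's bias factors.  The response is generated from the true
#' (unbiased) predictors and is never truncated.
#'
#' @param model A growth model.
#' @param params Named true parameter vector.
#' @param design A [predictor_design()]; must provide every variable the
#'   model requires.
#' @param dstruct A [data_structure()].
#' @return A `growth_dataset`: list with `recorded` (data frame of biased
#'   predictors used for fitting), `truth` (unbiased predictors), `length`
#'   (responses in meters), `true_params`, `model_version`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(nonlinear_growth_model(),
#'                       c(alpha = 2.6, beta3 = 1.2, gamma = 0.85, tau = 100),
#'                       predictor_design("age"), data_structure(20))
#' head(as.data.frame(d))
simulate_dataset <- function(model, params, design, dstruct) {
  stopifnot(inherits(design, "predictor_design"),
            inherits(dstruct, "data_structure"))
  missing <- setdiff(model$required_predictors, design$variables)
  if (length(missing)) {
    stop("non-permutable: design does not provide ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- dstruct$n
  age <- runif(n, design$age_range[1], design$age_range[2])
  weight <- if ("weight" %in% design$variables) {
    runif(n, design$weight_range[1], design$weight_range[2])
  }
  mu <- mean_length(model, params, age, weight)
  y <- mu + rnorm(n, 0, 1 / sqrt(params[["tau"]]))
  recorded <- data.frame(age = age * dstruct$age_bias)
  truth <- data.frame(age = age)
  if (!is.null(weight)) {
    recorded$weight <- weight * dstruct$weight_bias
    truth$weight <- weight
  }
  structure(
    list(recorded = recorded, truth = truth, length = y,
         true_params = params, model_version = model$version, n = n),
    class = "growth_dataset"
  )
}

#' @export
as.data.frame.growth_dataset <- function(x, ...) {
  cbind(x$recorded, length = x$length)
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("<growth_dataset> n=%d, generated under model v%d\n",
              x$n, x$model_version))
  print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Breeding status under the true generating model
#'
#' Applies the classification rule to the noiseless mean length at the
#' query point under the *true* (generating) parameters.
#'
#' @param model A growth model.
#' @param params Named true parameter vector.
#' @param query A [query_point()].
#' @param threshold Classification threshold in meters.
#' @return `"certain_to_breed"` or `"not_certain_to_breed"`.
#' @export
true_status <- function(model, params, query = query_point(),
                        threshold = 2.5) {
  classify_breeding(mean_length(model, params, query$age, query$weight),
                    threshold)
}
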