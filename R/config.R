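#' Read a study pair from a declarative config file
#'
#' Builds two experiments and the shared result from a YAML file with one
#' block per experiment (naming its four components and their parameters)
#' and one block for the result.  A minimal example ships with the
#' package; the recognized keys are:
#'
#' ```yaml
#' original:
#'   label: Study 1
#'   pre_data: {variables: [age, weight]}
#'   model: {family: linear}
#'   post_data: {family: least_squares}
#'   data_structure: {sample_size: 20, age_bias: 0.8, weight_bias: 1.2}
#' replication:
#'   label: Study 2
#'   pre_data: {variables: [age]}
#'   model: {family: nonlinear}
#'   post_data: {family: bayesian, burn_in: 1000, samples: 1000}
#'   data_structure: {sample_size: 100}
#' result: {type: breeding_status_match, threshold: 2.5}
#' ```
#'
#' Model blocks accept optional `fixed_params` (a named mapping) to pin
#' the generating truth.  The only supported result type is the
#' breeding-status match.
#'
#' @param path Path to the YAML config.
#' @return A list with `original`, `replication` ([experiment_spec()]s)
#'   and `result` (a [result_spec()]).
#' @export
#' @examples
#' cfg <- system.file("extdata", "dugong_config.yaml", package = "repdist")
#' st <- read_experiment_config(cfg)
#' st$original
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (block in c("original", "replication", "result")) {
    if (is.null(cfg[[block]])) {
      stop("config ", path, " is missing the `", block, "` block",
           call. = FALSE)
    }
  }
  result <- switch(
    as.character(cfg$result$type %||% "breeding_status_match"),
    breeding_status_match =
      breeding_match_result(threshold = cfg$result$threshold %||% 2.5),
    stop("unsupported result type: ", cfg$result$type, call. = FALSE)
  )
  list(original = config_experiment(cfg$original, "original"),
       replication = config_experiment(cfg$replication, "replication"),
       result = result)
}

config_experiment <- function(block, name) {
  for (field in c("pre_data", "model", "post_data", "data_structure")) {
    if (is.null(block[[field]])) {
      stop("experiment block `", name, "` is missing `", field, "`",
           call. = FALSE)
    }
  }
  pre <- predictor_design(variables = unlist(block$pre_data$variables))
  fixed <- if (!is.null(block$model$fixed_params)) {
    unlist(block$model$fixed_params)
  }
  model <- switch(
    as.character(block$model$family),
    linear = linear_growth_model(fixed_params = fixed),
    nonlinear = nonlinear_growth_model(fixed_params = fixed),
    stop("unknown model family in `", name, "`: ", block$model$family,
         call. = FALSE)
  )
  post <- switch(
    as.character(block$post_data$family),
    least_squares = least_squares_method(),
    bayesian = bayesian_method(
      mcmc = mcmc_settings(
        burn_in = block$post_data$burn_in %||% 1000,
        samples = block$post_data$samples %||% 1000)),
    stop("unknown post-data family in `", name, "`: ",
         block$post_data$family, call. = FALSE)
  )
  if (is.null(block$data_structure$sample_size)) {
    stop("data_structure block in `", name, "` needs `sample_size`",
         call. = FALSE)
  }
  ds <- data_structure(n = block$data_structure$sample_size,
                       age_bias = block$data_structure$age_bias %||% 1,
                       weight_bias = block$data_structure$weight_bias %||% 1)
  experiment_spec(label = block$label %||% name, pre_data = pre,
                  model = model, post_data = post, data_structure = ds,
                  background = block$background %||% "")
}

#' Run manifest
#'
#' Records everything needed to reproduce a simulated rate table: master
#' seed, the derived per-cell sub-seeds, replicate budgets, package
#' version and a timestamp.  Two runs with identical manifests (ignoring
#' the timestamp) produce identical outputs.  [run_dugong_example()]
#' writes one alongside its CSVs.
#'
#' @param seed Master seed (may be `NULL` for non-reproducible runs).
#' @param n_reps,n_reps_bayes Replicate budgets per cell family.
#' @param n_cells Number of permutation cells.
#' @return A list; write it with `yaml::write_yaml()`.
#' @export
run_manifest <- function(seed, n_reps, n_reps_bayes, n_cells = 16L) {
  list(
    package = "repdist",
    version = as.character(utils::packageVersion("repdist")),
    master_seed = seed,
    cell_seeds = if (!is.null(seed)) {
      stats::setNames(vapply(seq_len(n_cells), function(i) {
        derive_seed(seed, i)
      }, integer(1)), paste0("study", seq_len(n_cells)))
    },
    n_reps = n_reps,
    n_reps_bayes = n_reps_bayes,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
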