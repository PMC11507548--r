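# shared deterministic fixtures; all data are generated in code

fixed_linear_model <- function(tau = 100) {
  linear_growth_model(fixed_params = c(beta0 = 1, beta1 = 0.3, beta2 = 0.2,
                                       tau = tau))
}

fixed_nonlinear_model <- function(tau = 100) {
  nonlinear_growth_model(fixed_params = c(alpha = 2.6, beta3 = 1.2,
                                          gamma = 0.85, tau = tau))
}

# a clean (unbiased) dataset from either fixed model
make_dataset <- function(model, n = 20, seed = 101,
                         design = NULL, dstruct = NULL) {
  design <- design %||% predictor_design(
    if (model$family == "linear") c("age", "weight") else "age")
  dstruct <- dstruct %||% data_structure(n)
  set.seed(seed)
  simulate_dataset(model, draw_true_parameters(model), design, dstruct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# result whose predicate ignores the data (for rate sanity checks)
constant_result <- function(value = TRUE) {
  result_spec("constant", as.character(value),
              function(true_summary, fitted_summary) value)
}

# result with rate near 1/2: is the prediction above the truth?
coinflip_result <- function() {
  result_spec("sign of prediction error", "overestimate",
              function(true_summary, fitted_summary) {
                fitted_summary > true_summary
              })
}

# a fully-valid study pair: same design and model, different post-data
# method and data structure, so all 16 permutation cells are performable
fully_valid_pair <- function() {
  design <- predictor_design(c("age", "weight"))
  model <- linear_growth_model()
  list(
    original = experiment_spec("A", design, model, least_squares_method(),
                               data_structure(20)),
    replication = experiment_spec("B", design, model, bayesian_method(),
                                  data_structure(50)),
    result = breeding_match_result()
  )
}

# pair differing in the data structure only
dstruct_only_pair <- function() {
  design <- predictor_design(c("age", "weight"))
  model <- linear_growth_model()
  method <- least_squares_method()
  list(
    original = experiment_spec("small", design, model, method,
                               data_structure(20)),
    replication = experiment_spec("large", design, model, method,
                                  data_structure(100)),
    result = breeding_match_result()
  )
}

# per-cell sub-seed used by the acceptance checks: independent,
# reproducible streams for the large simulation cells
derive_seed_for_test <- function(master, cell) {
  as.integer(((master %% 2147483647) * 48271 + cell * 9973) %% 2147483647)
}

# hand-built rate table (for distance oracles independent of simulation)
manual_rate_table <- function(phi) {
  stopifnot(length(phi) == 16)
  grid <- expand.grid(dstruct = 1:2, spost = 1:2, model = 1:2, spre = 1:2)
  tab <- data.frame(study = 1:16, spre = grid$spre, model = grid$model,
                    spost = grid$spost, dstruct = grid$dstruct,
                    valid = TRUE, phi = phi, n_valid = NA_integer_,
                    n_failed = NA_integer_, mc_se = NA_real_)
  structure(tab, class = c("rate_table", "data.frame"))
}
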