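#' Idealized experiment specification
#'
#' Bundles the five components of an idealized experiment.  The four
#' permutable components (pre-data design, model, post-data method, data
#' structure) must be present; background knowledge is free-text metadata
#' that is stored but never permuted, and a replication never inherits the
#' original's background text -- it adopts the permutable components and
#' the result specification instead.
#'
#' Two specs are exact-replication-equivalent when all four permutable
#' components are identical; data values are always regenerated
#' independently.
#'
#' @param label Display label for the study.
#' @param pre_data A [predictor_design()].
#' @param model A growth model, e.g. [linear_growth_model()].
#' @param post_data An estimator, e.g. [least_squares_method()].
#' @param data_structure A [data_structure()].
#' @param background Free-text background-knowledge annotation (may be
#'   empty; never permuted).
#' @return An `experiment_spec` object.
#' @export
#' @examples
#' experiment_spec("toy", predictor_design(), linear_growth_model(),
#'                 least_squares_method(), data_structure(20))
experiment_spec <- function(label, pre_data, model, post_data,
                            data_structure, background = "") {
  stopifnot(inherits(pre_data, "predictor_design"),
            inherits(model, "growth_model"),
            inherits(post_data, "estimator_method"),
            inherits(data_structure, "data_structure"),
            is.character(background))
  structure(
    list(label = label, background = background, pre_data = pre_data,
         model = model, post_data = post_data,
         data_structure = data_structure),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("<experiment_spec>", x$label, "\n")
  cat("  pre-data :", x$pre_data$label, "\n")
  cat("  model    :", x$model$label, "\n")
  cat("  post-data:", x$post_data$label, "\n")
  cat("  data     :", x$data_structure$label, "\n")
  if (nzchar(x$background)) cat("  background:", x$background, "\n")
  invisible(x)
}

#' Result specification
#'
#' A result type \eqn{R}, a target value \eqn{r}, and a deterministic
#' predicate deciding, for one simulated replicate, whether the replicate
#' reproduced the result (\eqn{I\{R = r\} = 1}).  The predicate receives
#' the true-model summary (the noiseless mean length at the query under the
#' generating parameters) and the fitted-model summary (the fitted
#' prediction at the query) and returns a single logical.
#'
#' @param result_type Text label for the result type.
#' @param target_value Text label for the target value.
#' @param predicate `function(true_summary, fitted_summary)` returning
#'   `TRUE`/`FALSE`.
#' @param complemented Internal flag marking a complement result.
#' @return A `result_spec` object.
#' @seealso [breeding_match_result()], [complement_result()]
#' @export
result_spec <- function(result_type, target_value, predicate,
                        complemented = FALSE) {
  stopifnot(is.function(predicate))
  structure(list(result_type = result_type, target_value = target_value,
                 predicate = predicate, complemented = complemented),
            class = "result_spec")
}

#' Breeding-status match result
#'
#' The bundled binary result of the growth-curve example: result = 1 when
#' the breeding status assigned under the true generating model matches the
#' status predicted by the fitted study (both lengths classified against
#' the same threshold, strictly greater than 2.50 m meaning certain to
#' breed).
#'
#' @param threshold Classification threshold in meters.
#' @return A [result_spec()].
#' @export
#' @examples
#' rs <- breeding_match_result()
#' rs$predicate(2.6, 2.7)  # both certain to breed -> TRUE
#' rs$predicate(2.6, 2.4)  # statuses differ       -> FALSE
breeding_match_result <- function(threshold = 2.5) {
  force(threshold)
  result_spec(
    result_type = "breeding-status match",
    target_value = "predicted status equals true status",
    predicate = function(true_summary, fitted_summary) {
      identical(classify_breeding(true_summary, threshold),
                classify_breeding(fitted_summary, threshold))
    }
  )
}

#' Complement of a result specification
#'
#' Returns the result specification for \eqn{\neg r}.  On every valid
#' replicate the two predicates satisfy
#' \eqn{I\{r\} + I\{\neg r\} = 1}, so rate estimates under the complement
#' on the same random stream are exactly one minus the originals.
#'
#' @param result A [result_spec()].
#' @return A [result_spec()] with the negated predicate.
#' @export
complement_result <- function(result) {
  stopifnot(inherits(result, "result_spec"))
  pred <- result$predicate
  result_spec(
    result_type = result$result_type,
    target_value = paste("NOT:", result$target_value),
    predicate = function(true_summary, fitted_summary) {
      !pred(true_summary, fitted_summary)
    },
    complemented = !result$complemented
  )
}

#' Assemble a permuted experiment from two parent studies
#'
#' Builds the experiment whose permutable components are taken from the
#' original (version 1) or the replication (version 2) according to the
#' version indices.  Background text is taken from the parent supplying the
#' model, purely as annotation.  The operation is deterministic and
#' idempotent: reassembling with the same version vector yields an
#' identical spec.
#'
#' @param versions Integer vector of length 4 (values 1 or 2), ordered
#'   `(spre, model, spost, dstruct)`.
#' @param original,replication Parent [experiment_spec()]s.
#' @return An [experiment_spec()].
#' @export
#' @examples
#' st <- dugong_studies()
#' assemble(c(1, 1, 1, 1), st$original, st$replication)  # the original
#' assemble(c(1, 2, 1, 2), st$original, st$replication)  # a cross
assemble <- function(versions, original, replication) {
  stopifnot(inherits(original, "experiment_spec"),
            inherits(replication, "experiment_spec"))
  versions <- as.integer(versions)
  if (length(versions) != 4 || !all(versions %in% c(1L, 2L))) {
    stop("`versions` must be four indices, each 1 or 2, ordered ",
         "(spre, model, spost, dstruct)", call. = FALSE)
  }
  pick <- function(field, v) {
    if (v == 1L) original[[field]] else replication[[field]]
  }
  experiment_spec(
    label = sprintf("permutation (Spre%d, M%d, Spost%d, D%d)",
                    versions[1], versions[2], versions[3], versions[4]),
    pre_data = pick("pre_data", versions[1]),
    model = pick("model", versions[2]),
    post_data = pick("post_data", versions[3]),
    data_structure = pick("data_structure", versions[4]),
    background = pick("background", versions[2])
  )
}

#' Is an assembled experiment performable?
#'
#' A permuted experiment is non-permutable (not performable) when (a) its
#' model requires a predictor variable the pre-data design does not
#' provide, or (b) its post-data method is Bayesian with priors that cannot
#' be assigned to the model's parameters (vague priors always transfer;
#' informative priors declared for a different parameterization do not).
#' This is a total function: it always returns a flag, never an error.
#'
#' @param spec An [experiment_spec()].
#' @return `TRUE` or `FALSE`, with a `reason` attribute naming the failing
#'   requirement when `FALSE`.
#' @export
#' @examples
#' st <- dugong_studies()
#' is_permutable(st$original)
#' bad <- assemble(c(2, 1, 1, 1), st$original, st$replication)
#' is_permutable(bad)  # FALSE: linear model needs weight, design has age only
is_permutable <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  missing <- setdiff(spec$model$required_predictors, spec$pre_data$variables)
  if (length(missing)) {
    return(structure(FALSE, reason = sprintf(
      "model requires %s; pre-data provides %s only",
      paste(missing, collapse = ", "),
      paste(spec$pre_data$variables, collapse = ", "))))
  }
  if (spec$post_data$family == "bayesian") {
    priors <- spec$post_data$priors
    if (!isTRUE(priors$vague)) {
      params <- names(spec$model$param_bounds)
      unassigned <- setdiff(params, priors$declared_for)
      if (length(unassigned)) {
        return(structure(FALSE, reason = sprintf(
          "informative priors declared for (%s) cannot be assigned to model parameters (%s)",
          paste(priors$declared_for, collapse = ", "),
          paste(unassigned, collapse = ", "))))
      }
    }
  }
  structure(TRUE, reason = "")
}

#' Enumerate all component permutations of two studies
#'
#' Lists all \eqn{2^4 = 16} experiments obtained by swapping the four
#' permutable components between an original study and a replication, in
#' canonical order: pre-data slowest-varying, then model, then post-data,
#' then data structure fastest-varying.  Each cell carries a validity flag
#' from [is_permutable()].  At least two cells must be valid (the
#' permutation axiom; the two parent studies themselves always are for
#' admissible inputs), otherwise the distance is undefined and an error is
#' raised.
#'
#' @param original,replication Parent [experiment_spec()]s.
#' @return A `permutation_grid` data frame with columns `study`, `spre`,
#'   `model`, `spost`, `dstruct`, `valid`, `reason`.
#' @export
#' @examples
#' st <- dugong_studies()
#' enumerate_permutations(st$original, st$replication)
enumerate_permutations <- function(original, replication) {
  grid <- expand.grid(dstruct = 1:2, spost = 1:2, model = 1:2, spre = 1:2,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("spre", "model", "spost", "dstruct")]
  grid <- cbind(study = seq_len(nrow(grid)), grid)
  rownames(grid) <- NULL
  checks <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- assemble(unlist(grid[i, c("spre", "model", "spost", "dstruct")]),
                     original, replication)
    is_permutable(spec)
  })
  grid$valid <- vapply(checks, function(x) as.logical(x), logical(1))
  grid$reason <- vapply(checks, function(x) attr(x, "reason"), character(1))
  if (sum(grid$valid) < 2) {
    stop("permutation axiom violated: fewer than two performable ",
         "permutations exist, so the replication distance is undefined",
         call. = FALSE)
  }
  structure(grid, class = c("permutation_grid", "data.frame"))
}

# canonical identity key of a component (labels excluded: two components
# with the same defining fields are the same scientific object)
component_key <- function(x) {
  fields <- unclass(x)
  fields$label <- NULL
  paste(deparse(fields, control = "all"), collapse = "")
}

spec_key <- function(spec) {
  paste(component_key(spec$pre_data), component_key(spec$model),
        component_key(spec$post_data), component_key(spec$data_structure),
        sep = "|")
}
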