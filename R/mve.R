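#' Planned-modification study sequences
#'
#' Rather than attempting exact replication, a sequence of purposefully
#' planned modification studies swaps components of the previous study in
#' a controlled manner -- canonically one component per step -- keeps
#' modifications that preserve or improve the result of interest, and
#' converges toward the minimum viable experiment (MVE): the simplest
#' study that still produces the result and is simple enough for
#' near-exact replication.  A sequence of \eqn{m} accepted studies carries
#' \eqn{m - 1} step-wise distance vectors; as the sequence approaches an
#' MVE, fluctuations in all distance coordinates should settle, and at an
#' acceptable MVE all distances are zero.
#'
#' @param initial The starting [experiment_spec()].
#' @param result The shared [result_spec()] the whole sequence conditions
#'   on.
#' @return A `study_sequence` object.
#' @seealso [extend_sequence()], [convergence_summary()]
#' @export
#' @examples
#' st <- dugong_studies()
#' seq0 <- study_sequence(st$original, st$result)
study_sequence <- function(initial, result) {
  stopifnot(inherits(initial, "experiment_spec"),
            inherits(result, "result_spec"))
  structure(
    list(experiments = list(initial), result = result,
         steps = data.frame(step = integer(), modified = character(),
                            accepted = logical(), phi_head = numeric(),
                            phi_new = numeric(), stringsAsFactors = FALSE),
         distances = list()),
    class = "study_sequence"
  )
}

#' Propose a planned modification
#'
#' Compares the proposed study against the current head of the sequence:
#' builds the full permutation rate table (the permutation axiom must hold
#' between the two, otherwise the step errors out and is rejected),
#' records the head-vs-proposal distance vector, and accepts or discards
#' the proposal by the acceptance rule applied to the two studies' own
#' reproducibility rates.  The default rule keeps a modification whose
#' rate does not decrease ("modifications that yield or improve the
#' desired result are maintained").  Accepted proposals become the new
#' head and their distance vector is appended; earlier distances are never
#' mutated.
#'
#' @param seq A [study_sequence()].
#' @param new_spec The proposed [experiment_spec()].
#' @param modified_components Optional character vector naming the roles
#'   changed by this step (inferred by comparing components when omitted).
#' @param n_reps,n_reps_bayes,seed,query,share_identical Passed to
#'   [build_rate_table()].
#' @param accept_rule `function(phi_new, phi_head)` returning `TRUE` to
#'   keep the proposal; default: `phi_new >= phi_head`.
#' @return The updated `study_sequence`.
#' @export
extend_sequence <- function(seq, new_spec, modified_components = NULL,
                            n_reps = 500, n_reps_bayes = n_reps,
                            seed = NULL, accept_rule = NULL,
                            query = query_point(), share_identical = TRUE) {
  stopifnot(inherits(seq, "study_sequence"),
            inherits(new_spec, "experiment_spec"))
  head_spec <- seq$experiments[[length(seq$experiments)]]
  tab <- build_rate_table(head_spec, new_spec, seq$result,
                          n_reps = n_reps, n_reps_bayes = n_reps_bayes,
                          seed = seed, query = query,
                          share_identical = share_identical)
  dv <- distance_vector(tab)
  phi_head <- tab$phi[tab$study == 1]   # all components from the head
  phi_new <- tab$phi[tab$study == 16]   # all components from the proposal
  if (is.null(accept_rule)) {
    accept_rule <- function(phi_new, phi_head) {
      !is.na(phi_new) && phi_new >= phi_head
    }
  }
  accepted <- isTRUE(accept_rule(phi_new, phi_head))
  if (is.null(modified_components)) {
    modified_components <- infer_modified(head_spec, new_spec)
  }
  seq$steps <- rbind(seq$steps, data.frame(
    step = nrow(seq$steps) + 1L,
    modified = paste(modified_components, collapse = "+"),
    accepted = accepted, phi_head = phi_head, phi_new = phi_new,
    stringsAsFactors = FALSE))
  if (accepted) {
    seq$experiments <- c(seq$experiments, list(new_spec))
    seq$distances <- c(seq$distances, list(dv))
  }
  seq
}

infer_modified <- function(a, b) {
  fields <- c(spre = "pre_data", model = "model", spost = "post_data",
              dstruct = "data_structure")
  changed <- vapply(fields, function(f) {
    !identical(component_key(a[[f]]), component_key(b[[f]]))
  }, logical(1))
  if (!any(changed)) "none" else names(fields)[changed]
}

#' Convergence diagnostics of a planned-modification sequence
#'
#' Returns, per distance coordinate, the step-wise distance series and a
#' rolling-range statistic (max minus min over a window of `k` steps), and
#' flags whether the rolling range is non-increasing over the last `k`
#' windows.  This is a heuristic indicator of approach to a minimum viable
#' experiment -- the theory states only the limit (all distances zero at
#' an acceptable MVE), not a stopping rule.
#'
#' @param seq A [study_sequence()] with at least 3 accepted experiments.
#' @param k Rolling window length.
#' @return A list with the distance matrix `distances` (one row per
#'   accepted step), `rolling_range` matrix, per-coordinate logical
#'   `converged`, and overall flag `all_converged`.
#' @export
convergence_summary <- function(seq, k = 3) {
  stopifnot(inherits(seq, "study_sequence"))
  m <- length(seq$experiments)
  if (m < 3) {
    stop("sequence too short: need at least 3 accepted experiments (have ",
         m, ")", call. = FALSE)
  }
  D <- do.call(rbind, lapply(seq$distances, as.numeric))
  colnames(D) <- permutable_roles()
  n_steps <- nrow(D)
  roll <- matrix(NA_real_, n_steps, ncol(D), dimnames = dimnames(D))
  for (t in seq_len(n_steps)) {
    win <- max(1, t - k + 1):t
    roll[t, ] <- apply(D[win, , drop = FALSE], 2, function(z) diff(range(z)))
  }
  tail_idx <- max(1, n_steps - k + 1):n_steps
  converged <- apply(roll[tail_idx, , drop = FALSE], 2, function(z) {
    all(diff(z) <= 0)
  })
  list(distances = D, rolling_range = roll, converged = converged,
       all_converged = all(converged))
}

#' @export
print.study_sequence <- function(x, ...) {
  cat(sprintf("<study_sequence> %d accepted experiment(s), %d proposal step(s)\n",
              length(x$experiments), nrow(x$steps)))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' Export a sequence report
#'
#' One row per proposal step: which components were modified, whether the
#' step was accepted, the two studies' own rates, and (for accepted steps)
#' the four distance coordinates.
#'
#' @param seq A [study_sequence()].
#' @return A data frame.
#' @export
sequence_report <- function(seq) {
  stopifnot(inherits(seq, "study_sequence"))
  steps <- seq$steps
  d <- matrix(NA_real_, nrow(steps), 4,
              dimnames = list(NULL, paste0("d_", permutable_roles())))
  di <- 0L
  for (i in seq_len(nrow(steps))) {
    if (steps$accepted[i]) {
      di <- di + 1L
      d[i, ] <- as.numeric(seq$distances[[di]])
    }
  }
  cbind(steps, as.data.frame(d))
}
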