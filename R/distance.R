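#' Component-wise replication distance
#'
#' The distance between two experiments with respect to one permutable
#' component is the absolute difference between the mean reproducibility
#' rate over the 8 permutation cells holding that component at version 1
#' and the mean over the 8 cells holding it at version 2 -- averaging, for
#' each side, over all permutations of the remaining components.
#' Zero-by-convention rates of non-performable cells are included in the
#' means, keeping all four per-component permutation counts equal to 8.
#' Because rates live in \eqn{[0, 1]}, so does every distance coordinate.
#'
#' `component_distance()` returns one coordinate; `distance_vector()`
#' returns all four.
#'
#' @param table A complete `rate_table` (16 rows, studies 1--16), either
#'   freshly simulated by [build_rate_table()] or read from file by
#'   [read_rate_table()] (e.g. the printed reference rates of
#'   [dugong_printed_rates()]).
#' @param component One of `"spre"`, `"model"`, `"spost"`, `"dstruct"`.
#'   Background knowledge has no distance coordinate.
#' @return `component_distance()`: a single proportion.
#'   `distance_vector()`: a named numeric vector of class
#'   `distance_vector` with coordinates `spre`, `model`, `spost`,
#'   `dstruct` and attribute `n_permutations_per_side = 8`.
#' @export
#' @examples
#' tab <- dugong_printed_rates()
#' component_distance(tab, "model")
#' distance_vector(tab)
component_distance <- function(table, component = permutable_roles()) {
  component <- match.arg(component)
  check_complete_table(table)
  v <- table[[component]]
  abs(mean(table$phi[v == 1]) - mean(table$phi[v == 2]))
}

#' @rdname component_distance
#' @export
distance_vector <- function(table) {
  check_complete_table(table)
  d <- vapply(permutable_roles(), function(comp) {
    component_distance(table, comp)
  }, numeric(1))
  structure(d, class = "distance_vector", n_permutations_per_side = 8L)
}

check_complete_table <- function(table) {
  needed <- c("study", "spre", "model", "spost", "dstruct", "phi")
  miss_col <- setdiff(needed, names(table))
  if (length(miss_col)) {
    stop("rate table is missing columns: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(1:16, table$study)
  if (length(missing)) {
    stop("rate table is incomplete; missing studies: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$study)) {
    stop("rate table has duplicated study indices", call. = FALSE)
  }
  invisible(table)
}

#' @export
print.distance_vector <- function(x, digits = 3, ...) {
  cat("<distance_vector> (per-component replication distance)\n")
  labs <- c(spre = "pre-data methods", model = "model",
            spost = "post-data methods", dstruct = "data structure")
  for (nm in names(labs)) {
    cat(sprintf("  d(%-17s) = %.*f\n", labs[[nm]], digits, x[[nm]]))
  }
  invisible(x)
}

#' @export
format.distance_vector <- function(x, digits = 3, ...) {
  formatC(unclass(x), digits = digits, format = "f")
}

#' @export
as.data.frame.distance_vector <- function(x, ...) {
  data.frame(component = c("pre_data", "model", "post_data",
                           "data_structure"),
             distance = as.numeric(x))
}
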