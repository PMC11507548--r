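#' Read a reproducibility-rate table from CSV
#'
#' Validates and loads a rate table.  Required columns: `study`, `spre`,
#' `model`, `spost`, `dstruct`, `phi`.  Bookkeeping columns (`valid`,
#' `n_valid`, `n_failed`, `mc_se`) are tolerated when absent (fixture
#' mode) and filled with `NA`; a missing `valid` flag is inferred as
#' `NA` rather than guessed from a zero rate.
#'
#' @param path CSV path.
#' @return A `rate_table` data frame.
#' @export
#' @examples
#' read_rate_table(system.file("extdata", "dugong_table1.csv",
#'                             package = "repdist"))
read_rate_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("study", "spre", "model", "spost", "dstruct", "phi")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("rate table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- tab$study[duplicated(tab$study)]
  if (length(dup)) {
    stop("duplicate study index in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(tab$phi) | tab$phi < 0 | tab$phi > 1)
  if (length(bad)) {
    stop(sprintf("row %d of %s: phi = %s outside [0, 1]",
                 bad[1], path, format(tab$phi[bad[1]])), call. = FALSE)
  }
  for (col in c("n_valid", "n_failed")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_integer_
  }
  if (is.null(tab$mc_se)) tab$mc_se <- NA_real_
  tab$valid <- if (is.null(tab$valid)) NA else as.logical(tab$valid)
  tab <- tab[order(tab$study),
             c("study", "spre", "model", "spost", "dstruct", "valid",
               "phi", "n_valid", "n_failed", "mc_se")]
  rownames(tab) <- NULL
  structure(tab, class = c("rate_table", "data.frame"))
}

#' Write rate and distance tables as CSV
#'
#' `write_rate_table()` writes the machine-precision table by default;
#' `digits = 3` produces the report layout with the rate rounded the way
#' the reference table prints it.  `write_distance_table()` writes one row
#' per component with the distance at 3 decimals.
#'
#' @param table A `rate_table`.
#' @param path Output CSV path.
#' @param digits Optional rounding for `phi` and `mc_se`.
#' @return The path, invisibly.
#' @export
write_rate_table <- function(table, path, digits = NULL) {
  out <- as.data.frame(table)
  if (!is.null(digits)) {
    out$phi <- round(out$phi, digits)
    out$mc_se <- round(out$mc_se, digits)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param distances A [distance_vector()].
#' @param version1_label,version2_label Labels for the two studies.
#' @rdname write_rate_table
#' @export
write_distance_table <- function(distances, path,
                                 version1_label = "original",
                                 version2_label = "replication") {
  stopifnot(inherits(distances, "distance_vector"))
  out <- as.data.frame(distances)
  out$version1_label <- version1_label
  out$version2_label <- version2_label
  out$distance <- sprintf("%.3f", out$distance)
  out <- out[, c("component", "version1_label", "version2_label", "distance")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the permutation listing
#'
#' Writes the enumeration of [enumerate_permutations()] as CSV with
#' columns `study`, `spre`, `model`, `spost`, `dstruct`, `valid`.
#'
#' @param grid A `permutation_grid`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_permutation_grid <- function(grid, path) {
  stopifnot(inherits(grid, "permutation_grid"))
  write.csv(as.data.frame(grid)[, c("study", "spre", "model", "spost",
                                    "dstruct", "valid")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
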