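#' Classroom roster
#'
#' The roster fixes the canonical node set and ordering shared by every
#' adjacency matrix in an analysis: child identifiers, consent flags, and
#' (when observational data are present) the number of coding cycles and
#' per-child availability counts.
#'
#' Only consented children enter the analyzed network; the effective
#' classroom size is the number of consented children and must be at least
#' 2. Matrix order follows `child_ids` order everywhere, never sorted order.
#'
#' @param child_ids character vector of unique child labels, in canonical
#'   matrix order.
#' @param consented logical vector of per-child consent flags (default all
#'   `TRUE`).
#' @param n_cycles total number of observation cycles conducted (`NA` when
#'   no observational data exist).
#' @param available_cycles integer vector: for each child, the number of
#'   cycles in which the child could be observed. Must lie in
#'   `[0, n_cycles]`.
#'
#' @return An object of class `"roster"`.
#' @examples
#' r <- roster(c("a", "b", "c"), n_cycles = 44,
#'             available_cycles = c(40, 31, 28))
#' effective_size(r)
#' @export
roster <- function(child_ids, consented = rep(TRUE, length(child_ids)),
                   n_cycles = NA_integer_, available_cycles = NULL) {
  child_ids <- as.character(child_ids)
  if (anyDuplicated(child_ids)) {
    stop("roster child_ids must be unique", call. = FALSE)
  }
  if (length(consented) != length(child_ids) || !is.logical(consented)) {
    stop("consented must be a logical vector matching child_ids", call. = FALSE)
  }
  if (sum(consented) < 2) {
    stop("effective classroom size (consented children) must be >= 2",
         call. = FALSE)
  }
  if (!is.null(available_cycles)) {
    if (length(available_cycles) != length(child_ids)) {
      stop("available_cycles must match child_ids in length", call. = FALSE)
    }
    if (is.na(n_cycles)) {
      stop("n_cycles is required when available_cycles is given", call. = FALSE)
    }
    if (any(available_cycles < 0 | available_cycles > n_cycles)) {
      stop("available_cycles must lie in [0, n_cycles]", call. = FALSE)
    }
  }
  structure(
    list(child_ids = child_ids, consented = consented,
         n_cycles = as.integer(n_cycles),
         available_cycles = if (is.null(available_cycles)) NULL
                            else as.integer(available_cycles)),
    class = "roster"
  )
}

#' @export
print.roster <- function(x, ...) {
  cat("Roster of", length(x$child_ids), "children (",
      sum(x$consented), "consented )\n")
  invisible(x)
}

#' Effective classroom size
#'
#' Number of consented children on a roster: the `n` entering the
#' chance-level ratio threshold `1/(n - 1)` and the ordered-dyad count
#' `n * (n - 1)`.
#'
#' @param x a [roster()] or a network object carrying one.
#' @return integer count.
#' @export
effective_size <- function(x) {
  r <- if (inherits(x, "roster")) x else x$roster
  sum(r$consented)
}

#' Number of ordered dyads
#'
#' `n * (n - 1)` ordered off-diagonal pairs over the consented children:
#' the dyad universe over which densities, graph correlations and overlap
#' counts are computed (240 for a classroom of 16).
#'
#' @inheritParams effective_size
#' @return integer count of ordered dyads.
#' @export
n_dyads <- function(x) {
  n <- effective_size(x)
  n * (n - 1L)
}

#' Read a roster file
#'
#' Expects a CSV with columns `child_id`, `consented` and optionally
#' `available_cycles` and `n_cycles` (constant column).
#'
#' @param path file path.
#' @return a [roster()].
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(child_id = "character"))
  if (!"child_id" %in% names(df)) {
    stop("roster file must have a child_id column", call. = FALSE)
  }
  consented <- if ("consented" %in% names(df)) as.logical(df$consented)
               else rep(TRUE, nrow(df))
  n_cycles <- if ("n_cycles" %in% names(df)) as.integer(df$n_cycles[1])
              else NA_integer_
  avail <- if ("available_cycles" %in% names(df)) df$available_cycles else NULL
  roster(df$child_id, consented, n_cycles, avail)
}

#' Write a roster file
#'
#' @param x a [roster()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(x, path) {
  df <- data.frame(child_id = x$child_ids, consented = x$consented)
  if (!is.null(x$available_cycles)) {
    df$available_cycles <- x$available_cycles
    df$n_cycles <- x$n_cycles
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
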