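#' Valued informant network
#'
#' A square matrix of dyadic values over one roster. Three kinds are
#' supported, matching the three informant instruments:
#'
#' * `"nomination"` — directed 0/1 peer nominations (child report);
#' * `"rating"` — symmetric ordinal ratings on the 0--4 Likert scale
#'   (teacher report: 0 = never play, 4 = always play);
#' * `"count"` — symmetric nonnegative integer interaction frequencies
#'   accumulated over observation cycles (researcher report).
#'
#' The diagonal is formally undefined: it is stored as zero and excluded
#' from every statistic. Symmetric kinds are stored mirrored so that all
#' statistics run over the same `n * (n - 1)` ordered-dyad universe.
#'
#' @param values numeric square matrix.
#' @param kind one of `"nomination"`, `"rating"`, `"count"`.
#' @param roster optional [roster()]; taken from `dimnames(values)` or
#'   autogenerated labels when absent.
#' @param symmetrize for symmetric kinds only: if `TRUE`, an asymmetric
#'   input is symmetrized by averaging (ratings are rounded back to the
#'   scale); if `FALSE` (default) asymmetry is an error.
#'
#' @return An object of class `"value_network"` with fields `values`,
#'   `kind`, `directed`, `roster`.
#' @examples
#' m <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' net <- value_network(m, "rating")
#' node_strength(net)
#' @export
value_network <- function(values, kind = c("nomination", "rating", "count"),
                          roster = NULL, symmetrize = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  if (!is.numeric(values)) {
    stop("adjacency matrix must be numeric", call. = FALSE)
  }
  roster <- roster %||% roster_from_labels(values)
  if (length(roster$child_ids) != nrow(values)) {
    stop("matrix dimension does not match roster size", call. = FALSE)
  }
  dimnames(values) <- list(roster$child_ids, roster$child_ids)
  if (any(diag(values) != 0)) {
    warning("nonzero diagonal entries set to zero (self-ties are undefined)",
            call. = FALSE)
    diag(values) <- 0
  }
  directed <- kind == "nomination"
  off <- offdiag_values(values)
  if (kind == "nomination" && !all(off %in% c(0, 1))) {
    stop("nomination values must be 0 or 1", call. = FALSE)
  }
  if (kind == "rating" && !all(off %in% 0:4)) {
    stop("ratings must lie on the 0-4 scale", call. = FALSE)
  }
  if (kind == "count" && (any(off < 0) || !all(is_wholenumber(off)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (!directed && !isSymmetric(unname(values))) {
    if (!symmetrize) {
      stop(kind, " networks must be symmetric (or pass symmetrize = TRUE)",
           call. = FALSE)
    }
    values <- (values + t(values)) / 2
    if (kind %in% c("rating", "count")) values <- round(values)
    message("asymmetric ", kind, " matrix symmetrized by averaging")
  }
  structure(
    list(values = values, kind = kind, directed = directed, roster = roster),
    class = "value_network"
  )
}

roster_from_labels <- function(m) {
  rn <- rownames(m)
  cn <- colnames(m)
  if (!is.null(rn) && !is.null(cn)) {
    if (!identical(rn, cn)) {
      stop("row and column labels disagree", call. = FALSE)
    }
    return(roster(rn))
  }
  roster(paste0("c", seq_len(nrow(m))))
}

#' Binary informant network
#'
#' A 0/1 dyadic matrix over a roster, either native (peer nominations) or
#' produced by a binarization scheme, which it records.
#'
#' @param ties 0/1 square matrix.
#' @param roster optional [roster()].
#' @param scheme the [binarization spec][rating_scheme] that produced the
#'   ties, or `"native"` for nominations.
#' @param directed logical; nominations are directed, thresholded rating /
#'   frequency networks are symmetric, ratio-thresholded networks are
#'   directed.
#' @return An object of class `"binary_network"`.
#' @export
binary_network <- function(ties, roster = NULL, scheme = "native",
                           directed = TRUE) {
  ties <- as.matrix(ties)
  if (nrow(ties) != ncol(ties)) {
    stop("tie matrix must be square", call. = FALSE)
  }
  roster <- roster %||% roster_from_labels(ties)
  dimnames(ties) <- list(roster$child_ids, roster$child_ids)
  diag(ties) <- 0
  if (!all(offdiag_values(ties) %in% c(0, 1))) {
    stop("ties must be 0 or 1", call. = FALSE)
  }
  if (!directed && !isSymmetric(unname(ties))) {
    stop("undirected binary network must be symmetric", call. = FALSE)
  }
  structure(
    list(ties = ties, roster = roster, scheme = scheme, directed = directed),
    class = "binary_network"
  )
}

#' @export
print.value_network <- function(x, ...) {
  cat(sprintf("value_network [%s, %s] over %d children\n", x$kind,
              if (x$directed) "directed" else "symmetric",
              length(x$roster$child_ids)))
  invisible(x)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network [%s, %s] over %d children, density %.3f\n",
              if (is.character(x$scheme)) x$scheme else scheme_label(x$scheme),
              if (x$directed) "directed" else "symmetric",
              length(x$roster$child_ids), network_density(x)))
  invisible(x)
}

# matrix payload of either network class (or a bare matrix)
net_values <- function(x) {
  if (inherits(x, "value_network")) return(x$values)
  if (inherits(x, "binary_network")) return(x$ties)
  if (is.matrix(x)) return(x)
  stop("expected a value_network, binary_network, or matrix", call. = FALSE)
}

#' Network density
#'
#' Proportion of present ties among the `n * (n - 1)` ordered off-diagonal
#' dyads. For symmetric networks both mirrored cells are counted, which
#' equals the unordered-pair density.
#'
#' @param net a [binary_network()].
#' @return proportion in `[0, 1]`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1
#' network_density(binary_network(m))  # 2/6
#' @export
network_density <- function(net) {
  ties <- net_values(net)
  n <- nrow(ties)
  if (n < 2) stop("density needs at least 2 children", call. = FALSE)
  sum(offdiag_values(ties) != 0) / (n * (n - 1))
}

#' Per-child node strength
#'
#' Sum of dyadic values incident to each child. For directed networks,
#' `"in"` sums the column (e.g. nominations received), `"out"` the row, and
#' `"total"` their sum. For symmetric networks all three coincide with the
#' row sum (e.g. a child's total teacher-rating score or total observed
#' interactions).
#'
#' @param net a [value_network()] or [binary_network()].
#' @param mode `"total"`, `"in"`, or `"out"`.
#' @return named numeric vector of length n.
#' @export
node_strength <- function(net, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  m <- net_values(net)
  diag(m) <- 0
  directed <- if (is.matrix(net)) !isSymmetric(unname(m)) else net$directed
  if (!directed) return(rowSums(m))
  switch(mode,
         "in" = colSums(m),
         out = rowSums(m),
         total = rowSums(m) + colSums(m))
}

#' Read a labeled adjacency matrix
#'
#' Reads a CSV whose first row and first column hold identical child
#' labels, in canonical roster order, and validates the values for the
#' requested network kind. Nonzero diagonal entries are zeroed with a
#' warning; symmetric kinds are verified symmetric unless
#' `symmetrize = TRUE`.
#'
#' @param path CSV file path.
#' @inheritParams value_network
#' @return a [value_network()] (or, for `kind = "nomination"`, the same
#'   with 0/1 values).
#' @export
read_adjacency <- function(path, kind = c("nomination", "rating", "count"),
                           symmetrize = FALSE) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("adjacency file is not a square labeled matrix: ", path,
         call. = FALSE)
  }
  if (!is.numeric(m)) {
    stop("adjacency file contains non-numeric cells: ", path, call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels disagree in ", path, call. = FALSE)
  }
  value_network(m, kind, symmetrize = symmetrize)
}

#' Write a labeled adjacency matrix
#'
#' Inverse of [read_adjacency()]: integer matrices round-trip bit-exactly.
#'
#' @param net a [value_network()] or [binary_network()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  m <- net_values(net)
  utils::write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' Export a network as an edge list
#'
#' Returns (and optionally writes) a `source, target, weight` table of the
#' nonzero dyads, one row per unordered pair for symmetric networks, for
#' use with standard graph tools.
#'
#' @param net a [value_network()] or [binary_network()].
#' @param path optional CSV path to write to.
#' @return data frame with columns `source`, `target`, `weight`.
#' @export
as_edge_list <- function(net, path = NULL) {
  m <- net_values(net)
  directed <- net$directed %||% TRUE
  keep <- if (directed) offdiag_mask(nrow(m)) & m != 0
          else upper.tri(m) & m != 0
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(m)
  el <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                   weight = m[idx])
  el <- el[order(el$source, el$target), , drop = FALSE]
  rownames(el) <- NULL
  if (!is.null(path)) {
    utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
  }
  el
}
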