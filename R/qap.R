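#' Graph correlation between two networks
#'
#' Pearson correlation over the `n * (n - 1)` ordered off-diagonal cell
#' pairs of two networks on the same roster in the same order. Symmetric
#' networks contribute both mirrored cells, so a directed network can be
#' correlated with an undirected one without collapsing its
#' directionality.
#'
#' @param a,b [value_network()], [binary_network()] or square matrices on
#'   the same roster.
#' @return correlation in `[-1, 1]`.
#' @export
graph_correlation <- function(a, b) {
  A <- net_values(a)
  B <- net_values(b)
  check_comparable(A, B)
  mask <- offdiag_mask(nrow(A))
  av <- A[mask]
  bv <- B[mask]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop("graph correlation undefined: a network has no off-diagonal variance",
         call. = FALSE)
  }
  stats::cor(av, bv)
}

check_comparable <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    stop("networks differ in size", call. = FALSE)
  }
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("networks are not on the same roster order", call. = FALSE)
  }
  if (nrow(A) < 3) {
    stop("graph correlation needs at least 3 children", call. = FALSE)
  }
  invisible(TRUE)
}

qap_result <- function(r_obs, r_null, p_greater, p_two_sided, n_permutations,
                       seed = NA_integer_, exact = FALSE) {
  structure(
    list(r_observed = r_obs,
         p_greater = p_greater,
         p_two_sided = p_two_sided,
         n_permutations = n_permutations,
         null_summary = c(mean = mean(r_null), sd = stats::sd(r_null),
                          q2.5 = unname(stats::quantile(r_null, 0.025)),
                          q97.5 = unname(stats::quantile(r_null, 0.975))),
         seed = seed, exact = exact),
    class = "qap_result"
  )
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf("QAP %s: r = %.3f, p(greater) = %.4g, p(two-sided) = %.4g (%s permutations)\n",
              if (x$exact) "exact" else "test", x$r_observed, x$p_greater,
              x$p_two_sided, format(x$n_permutations, big.mark = ",")))
  cat(sprintf("null: mean %.3f, sd %.3f, 95%% [%.3f, %.3f]\n",
              x$null_summary["mean"], x$null_summary["sd"],
              x$null_summary["q2.5"], x$null_summary["q97.5"]))
  invisible(x)
}

#' Quadratic Assignment Procedure test
#'
#' Permutation test for the correlation between two networks that respects
#' the dyadic dependence structure: instead of permuting cells
#' independently, whole node labels of one network are permuted (the same
#' permutation applied simultaneously to rows and columns), and the graph
#' correlation is recomputed for each of `n_permutations` uniform random
#' permutations. Applicable to valued and binary networks alike.
#'
#' P-values use the add-one convention `(1 + k) / (1 + M)` counting the
#' observed statistic among the permuted ones, so the smallest achievable
#' p is `1/(M + 1)`; ties at the observed statistic count toward
#' rejection. `p_greater` is the upper-tail p (permuted r at or above the
#' observed r); `p_two_sided` compares absolute values.
#'
#' @inheritParams graph_correlation
#' @param n_permutations number of random node permutations (default
#'   10,000).
#' @param seed optional integer seed for reproducibility.
#' @return a `"qap_result"`: `r_observed`, `p_greater`, `p_two_sided`,
#'   `n_permutations`, `null_summary` (mean, sd, 2.5th/97.5th quantiles of
#'   the permuted correlations), `seed`.
#' @seealso [qap_exact()] for exhaustive enumeration on tiny networks.
#' @export
qap_test <- function(a, b, n_permutations = 10000, seed = NULL) {
  A <- net_values(a)
  B <- net_values(b)
  check_comparable(A, B)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  n <- nrow(A)
  mask <- offdiag_mask(n)
  av <- A[mask]
  if (stats::sd(av) == 0 || stats::sd(B[mask]) == 0) {
    stop("QAP undefined: a network has no off-diagonal variance",
         call. = FALSE)
  }
  r_obs <- stats::cor(av, B[mask])
  if (!is.null(seed)) set.seed(seed)
  r_null <- vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    stats::cor(av, B[p, p][mask])
  }, numeric(1))
  eps <- 1e-12
  p_greater <- (1 + sum(r_null >= r_obs - eps)) / (1 + n_permutations)
  p_two <- (1 + sum(abs(r_null) >= abs(r_obs) - eps)) / (1 + n_permutations)
  qap_result(r_obs, r_null, p_greater, p_two, n_permutations,
             seed = seed %||% NA_integer_)
}

# all permutations of 1..n as an n!-row matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(rep(k, nrow(sub)),
                      matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Exhaustive QAP by full permutation enumeration
#'
#' Enumerates all `n!` node permutations (identity included) and reports
#' the exact permutation p-values, for networks of up to 8 nodes. Serves
#' as the deterministic reference for [qap_test()].
#'
#' @inheritParams graph_correlation
#' @return a `"qap_result"` with `exact = TRUE` and
#'   `n_permutations = n!`; p-values are exact proportions (no add-one
#'   adjustment).
#' @export
qap_exact <- function(a, b) {
  A <- net_values(a)
  B <- net_values(b)
  check_comparable(A, B)
  n <- nrow(A)
  if (n > 8) {
    stop("qap_exact enumerates n! permutations; n must be <= 8",
         call. = FALSE)
  }
  mask <- offdiag_mask(n)
  av <- A[mask]
  if (stats::sd(av) == 0 || stats::sd(B[mask]) == 0) {
    stop("QAP undefined: a network has no off-diagonal variance",
         call. = FALSE)
  }
  r_obs <- stats::cor(av, B[mask])
  perms <- all_permutations(n)
  r_all <- vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]
    stats::cor(av, B[p, p][mask])
  }, numeric(1))
  eps <- 1e-12
  p_greater <- mean(r_all >= r_obs - eps)
  p_two <- mean(abs(r_all) >= abs(r_obs) - eps)
  qap_result(r_obs, r_all, p_greater, p_two, nrow(perms), exact = TRUE)
}
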