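#' Bootstrap confidence interval for a correlation
#'
#' Pearson (or Spearman) correlation between two per-child vectors with a
#' 95% percentile-bootstrap confidence interval: children are resampled
#' with replacement as units, the correlation is recomputed on each of
#' `n_boot` resamples, and the 2.5th/97.5th percentiles of the resampled
#' correlations bound the interval. Pairs with a missing value in either
#' vector are dropped first. Resamples in which either vector is constant
#' (possible at small n) are redrawn; the number of redraws is reported in
#' the result.
#'
#' @param x,y paired numeric vectors (per-child measures); at least 3
#'   complete pairs required.
#' @param n_boot number of bootstrap resamples (default 1,000).
#' @param seed optional integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `"bootstrap_correlation"`: `r`, `ci_low`,
#'   `ci_high`, `n_boot`, `n_children`, `n_redraws`, `seed`, `method`.
#' @examples
#' set.seed(1)
#' x <- rnorm(16)
#' bootstrap_correlation(x, x + rnorm(16), seed = 1)
#' @export
bootstrap_correlation <- function(x, y, n_boot = 1000, seed = NULL,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  r <- stats::cor(x, y, method = method)
  if (!is.null(seed)) set.seed(seed)
  rs <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
      redraws <- redraws + 1L
    }
    rs[b] <- stats::cor(x[idx], y[idx], method = method)
  }
  ci <- unname(stats::quantile(rs, c(0.025, 0.975)))
  structure(
    list(r = r, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         n_children = n, n_redraws = redraws, seed = seed %||% NA_integer_,
         method = method),
    class = "bootstrap_correlation"
  )
}

#' @export
print.bootstrap_correlation <- function(x, ...) {
  cat(sprintf("r = %.2f, 95%% bootstrap CI [%.2f, %.2f] (n = %d, %s resamples)\n",
              x$r, x$ci_low, x$ci_high, x$n_children,
              format(x$n_boot, big.mark = ",")))
  invisible(x)
}

#' Validate informant networks against per-child outcomes
#'
#' Correlates one strength measure per informant network with each
#' outcome column, with bootstrap confidence intervals: the number of
#' nominations a child received (in-strength of the child network), the
#' child's total teacher-rating score, and the child's total observed
#' interaction count. Significance is read from whether the 95% CI
#' excludes 0.
#'
#' @param child a [binary_network()] of nominations.
#' @param teacher a [value_network()] of kind `"rating"`.
#' @param observed a [value_network()] of kind `"count"`.
#' @param outcomes data frame with a `child_id` column (ids on the shared
#'   roster) plus one numeric column per outcome score; missing values
#'   allowed.
#' @param n_boot bootstrap resamples per correlation (default 1,000).
#' @param seed integer seed; each cell's bootstrap derives its own
#'   sub-seed.
#' @param method correlation method, see [bootstrap_correlation()].
#' @return data frame with one row per (network measure, outcome) pair:
#'   `measure`, `outcome`, `r`, `ci_low`, `ci_high`, `n`, `significant`.
#' @export
validity_table <- function(child, teacher, observed, outcomes,
                           n_boot = 1000, seed = 1,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!"child_id" %in% names(outcomes)) {
    stop("outcomes must have a child_id column", call. = FALSE)
  }
  ids <- child$roster$child_ids
  if (!all(outcomes$child_id %in% ids)) {
    stop("outcomes contain child_ids not on the roster", call. = FALSE)
  }
  measures <- list(
    nomination_in_strength = node_strength(child, "in"),
    teacher_rating_total = node_strength(teacher, "total"),
    observed_count_total = node_strength(observed, "total")
  )
  score_cols <- setdiff(names(outcomes), "child_id")
  if (!length(score_cols)) stop("no outcome columns found", call. = FALSE)
  idx <- match(ids, outcomes$child_id)
  rows <- list()
  k <- 0L
  for (m in names(measures)) {
    for (sc in score_cols) {
      k <- k + 1L
      y <- outcomes[[sc]][idx]
      if (sum(stats::complete.cases(measures[[m]], y)) < 3) {
        warning("skipping ", m, " vs ", sc, ": fewer than 3 complete pairs",
                call. = FALSE)
        next
      }
      bc <- bootstrap_correlation(measures[[m]], y, n_boot,
                                  seed = derive_seed(seed, k),
                                  method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, outcome = sc, r = bc$r, ci_low = bc$ci_low,
        ci_high = bc$ci_high, n = bc$n_children,
        significant = bc$ci_low > 0 | bc$ci_high < 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an outcome-score table
#'
#' CSV with a `child_id` column and numeric score columns.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_outcomes <- function(path) {
  utils::read.csv(path, check.names = FALSE,
                  colClasses = c(child_id = "character"))
}
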