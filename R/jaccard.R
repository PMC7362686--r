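#' Jaccard overlap of two binary networks
#'
#' Decomposes the `n * (n - 1)` ordered off-diagonal dyads of two binary
#' networks on one roster into ties present in both (C), present only in
#' the first (A), present only in the second (B), and absent in both, and
#' returns `J = C / (A + B + C)`. Dyads absent in both networks are
#' excluded from numerator and denominator (this is the present-tie
#' Jaccard index, not the simple matching coefficient) but are reported.
#' `J` is defined as 0 when no tie is present in either network.
#'
#' Because absent-absent agreement is ignored, J rises mechanically with
#' network density: for independent random networks of matched density d
#' the expected components give `J ~ d / (2 - d)`, so J should be read
#' alongside the densities of the networks compared.
#'
#' @param a,b [binary_network()]s (or 0/1 matrices) on the same roster.
#' @return An object of class `"jaccard_result"`: counts `in_both`,
#'   `only_in_a`, `only_in_b`, `absent_in_both`, and the proportion
#'   `jaccard`.
#' @examples
#' m1 <- matrix(0, 3, 3); m1[1, 2] <- m1[2, 3] <- 1
#' m2 <- matrix(0, 3, 3); m2[2, 3] <- m2[3, 1] <- 1
#' jaccard(m1, m2)  # C=1, A=1, B=1 -> J = 1/3
#' @export
jaccard <- function(a, b) {
  A <- net_values(a)
  B <- net_values(b)
  if (!identical(dim(A), dim(B))) {
    stop("networks differ in size", call. = FALSE)
  }
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("networks are not on the same roster order", call. = FALSE)
  }
  mask <- offdiag_mask(nrow(A))
  av <- A[mask]
  bv <- B[mask]
  if (!all(av %in% c(0, 1)) || !all(bv %in% c(0, 1))) {
    stop("jaccard requires binary networks", call. = FALSE)
  }
  in_both <- sum(av == 1 & bv == 1)
  only_a <- sum(av == 1 & bv == 0)
  only_b <- sum(av == 0 & bv == 1)
  neither <- sum(av == 0 & bv == 0)
  denom <- in_both + only_a + only_b
  structure(
    list(in_both = in_both, only_in_a = only_a, only_in_b = only_b,
         absent_in_both = neither,
         jaccard = if (denom == 0) 0 else in_both / denom),
    class = "jaccard_result"
  )
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf("Jaccard J = %.3f (both %d, only-A %d, only-B %d, neither %d)\n",
              x$jaccard, x$in_both, x$only_in_a, x$only_in_b,
              x$absent_in_both))
  invisible(x)
}
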