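# internal helpers shared across modules

# logical mask selecting the n*(n-1) ordered off-diagonal cells
offdiag_mask <- function(n) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}

# off-diagonal cells of a square matrix, column-major order
offdiag_values <- function(m) m[offdiag_mask(nrow(m))]

# upper-triangle (unordered-pair) cells of a square matrix
pair_values <- function(m) m[upper.tri(m)]

# derive a reproducible 32-bit sub-seed from a top-level seed and an offset
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% .Machine$integer.max)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
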