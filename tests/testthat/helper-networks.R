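# fixture builders shared across test files

labeled <- function(m, ids = sprintf("c%02d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  m
}

# symmetric matrix from its upper-triangle values, column-major pair order
# (for n = 3: (1,2), (1,3), (2,3))
sym_from_pairs <- function(n, pairs) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- pairs
  m <- m + t(m)
  labeled(m)
}

rand_count_net <- function(n = 8, lambda = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- rpois(n * (n - 1) / 2, lambda)
  value_network(labeled(m + t(m)), "count")
}

rand_rating_net <- function(n = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- sample(0:4, n * (n - 1) / 2, replace = TRUE)
  value_network(labeled(m + t(m)), "rating")
}

rand_binary <- function(n = 8, d = 0.3, seed = 1, directed = TRUE) {
  set.seed(seed)
  m <- matrix(rbinom(n * n, 1, d), n, n)
  if (!directed) { m[lower.tri(m)] <- t(m)[lower.tri(m)] }
  diag(m) <- 0
  binary_network(labeled(m), directed = directed)
}

# apply the same node relabeling to a square matrix
relabel <- function(m, perm) {
  out <- m[perm, perm]
  dimnames(out) <- dimnames(m)
  out
}
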