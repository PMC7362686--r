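test_that("graph correlation matches a hand Pearson computation", {
  A <- labeled(matrix(c(0, 0, 1, 1, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE))
  B <- labeled(matrix(c(0, 0, 1, 1, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE))
  # off-diagonal cells paired in column-major order, Pearson by formula
  av <- A[row(A) != col(A)]
  bv <- B[row(B) != col(B)]
  r_hand <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(graph_correlation(A, B), r_hand)
})

test_that("graph correlation handles self, affine and degenerate cases", {
  A <- rand_count_net(6, seed = 4)
  expect_equal(graph_correlation(A, A), 1)
  m <- max(A$values) - A$values
  diag(m) <- 0
  expect_equal(graph_correlation(A, value_network(labeled(m), "count")), -1)
  flat <- labeled(matrix(1, 6, 6) - diag(6))
  expect_error(graph_correlation(A, flat), "variance")
})

test_that("exhaustive QAP agrees with direct 6-permutation enumeration", {
  set.seed(8)
  A <- labeled(matrix(runif(9), 3, 3)); diag(A) <- 0
  B <- labeled(matrix(runif(9), 3, 3)); diag(B) <- 0
  # independent oracle: enumerate the 6 permutations of 3 labels literally
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  mask <- row(A) != col(A)
  r_obs <- cor(A[mask], B[mask])
  r_all <- sapply(perms, function(p) cor(A[mask], B[p, p][mask]))
  ex <- qap_exact(A, B)
  expect_equal(ex$r_observed, r_obs)
  expect_equal(ex$p_greater, mean(r_all >= r_obs - 1e-12))
  expect_equal(ex$p_two_sided, mean(abs(r_all) >= abs(r_obs) - 1e-12))
  expect_equal(ex$n_permutations, 6)
})

test_that("self-comparison attains the maximum statistic", {
  A <- rand_count_net(5, seed = 12)
  ex <- qap_exact(A, A)
  expect_equal(ex$r_observed, 1)
  expect_true(ex$p_greater >= 1 / factorial(5))
  # a constant shift leaves the correlation, hence the p, unchanged
  B <- value_network(A$values + 2 - diag(2, 5), "count")
  ex2 <- qap_exact(A, B)
  expect_equal(ex2$r_observed, 1)
  expect_equal(ex2$p_greater, ex$p_greater)
})

test_that("Monte-Carlo QAP is reproducible and respects the add-one floor", {
  A <- rand_count_net(8, seed = 21)
  B <- rand_count_net(8, seed = 22)
  q1 <- qap_test(A, B, 499, seed = 5)
  q2 <- qap_test(A, B, 499, seed = 5)
  expect_identical(q1$p_greater, q2$p_greater)
  expect_identical(q1$null_summary, q2$null_summary)
  expect_gte(q1$p_greater, 1 / 500)

  self <- qap_test(A, A, 99, seed = 1)
  expect_equal(self$r_observed, 1)
})

test_that("Monte-Carlo p converges to the exact permutation p", {
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(rpois(25, 2), 5); diag(A) <- 0
    B <- matrix(rpois(25, 2), 5); diag(B) <- 0
    ex <- qap_exact(A, B)$p_greater
    mc <- qap_test(A, B, 1999, seed = i)$p_greater
    se <- sqrt(ex * (1 - ex) / 1999)
    expect_lt(abs(mc - ex), 3 * se + 2 / 2000)
  }
})

test_that("QAP is invariant under simultaneous relabeling of both networks", {
  A <- rand_count_net(7, seed = 41)
  B <- rand_rating_net(7, seed = 42)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(graph_correlation(relabel(A$values, perm),
                                 relabel(B$values, perm)),
               graph_correlation(A, B))
  expect_equal(qap_exact(relabel(A$values, perm),
                         relabel(B$values, perm))$p_greater,
               qap_exact(A$values, B$values)$p_greater)
})

test_that("jaccard decomposes the dyad universe and matches hand counts", {
  # ties(A) = {ab, bc}, ties(B) = {bc, ca} as unordered symmetric pairs
  A <- sym_from_pairs(3, c(1, 0, 1))
  B <- sym_from_pairs(3, c(0, 1, 1))
  j <- jaccard(A, B)
  expect_equal(j$in_both, 2)       # ordered dyads of the shared pair bc
  expect_equal(j$only_in_a, 2)
  expect_equal(j$only_in_b, 2)
  expect_equal(j$jaccard, 1 / 3)
  expect_equal(j$in_both + j$only_in_a + j$only_in_b + j$absent_in_both, 6)

  expect_equal(jaccard(A, A)$jaccard, 1)
  disjoint <- jaccard(sym_from_pairs(3, c(1, 0, 0)),
                      sym_from_pairs(3, c(0, 0, 1)))
  expect_equal(disjoint$jaccard, 0)
  empty <- matrix(0, 3, 3)
  expect_equal(jaccard(empty, empty)$jaccard, 0)
})

test_that("jaccard is symmetric and relabeling-invariant", {
  for (s in 1:5) {
    A <- rand_binary(8, d = 0.4, seed = s)
    B <- rand_binary(8, d = 0.4, seed = s + 100)
    expect_equal(jaccard(A, B)$jaccard, jaccard(B, A)$jaccard)
    perm <- sample(8)
    expect_equal(jaccard(relabel(A$ties, perm),
                         relabel(B$ties, perm))$jaccard,
                 jaccard(A, B)$jaccard)
  }
})

test_that("congruency grid matches direct component calls", {
  cls <- generate_classroom(synthetic_config(seed = 3))
  child <- binary_network(cls$nominations$values, cls$roster,
                          directed = TRUE)
  rep1 <- congruency_grid(child, cls$ratings, cls$counts,
                          teacher_cutoffs = 2,
                          researcher_schemes = list(
                            frequency_scheme("percentile", q = 75)),
                          n_permutations = 199, seed = 11)
  expect_equal(nrow(rep1$binary), 3)
  tb <- binarize_rating(cls$ratings, 2)
  rb <- binarize_frequency(cls$counts, "percentile", q = 75)
  row_tr <- rep1$binary[rep1$binary$pair == "teacher_vs_researcher", ]
  expect_equal(row_tr$r, graph_correlation(tb, rb))
  expect_equal(row_tr$jaccard, jaccard(tb, rb)$jaccard)
  row_ct <- rep1$binary[rep1$binary$pair == "child_vs_teacher", ]
  expect_equal(row_ct$r, graph_correlation(child, tb))

  # original-network QAP r's are plain graph correlations
  expect_equal(rep1$qap_original$r,
               c(graph_correlation(child, cls$ratings),
                 graph_correlation(child, cls$counts),
                 graph_correlation(cls$ratings, cls$counts)))
})

test_that("congruency grid has the expected shape and is deterministic", {
  cls <- generate_classroom(synthetic_config(seed = 5))
  child <- binary_network(cls$nominations$values, cls$roster,
                          directed = TRUE)
  rep1 <- congruency_grid(child, cls$ratings, cls$counts,
                          n_permutations = 99, seed = 2)
  expect_equal(nrow(rep1$qap_original), 3)
  # 3 child-teacher + 6 child-researcher + 18 teacher-researcher rows
  expect_equal(nrow(rep1$binary), 3 + 6 + 3 * 6)
  expect_equal(nrow(rep1$densities), 1 + 3 + 6)
  rep2 <- congruency_grid(child, cls$ratings, cls$counts,
                          n_permutations = 99, seed = 2)
  expect_identical(rep1$binary, rep2$binary)

  # identical informants give perfect congruency everywhere
  ties <- binarize_rating(cls$ratings, 2)
  same <- congruency_grid(
    binary_network(ties$ties, cls$roster, directed = FALSE),
    cls$ratings, value_network(ties$ties, "count", roster = cls$roster),
    teacher_cutoffs = 2,
    researcher_schemes = list(frequency_scheme("fixed", k = 1)),
    n_permutations = 99, seed = 1)
  expect_true(all(same$binary$r == 1))
  expect_true(all(same$binary$jaccard == 1))
})

test_that("mean jaccard of independent matched-density networks tracks d/(2-d)", {
  set.seed(606)
  mean_j <- sapply(c(0.1, 0.5, 0.9), function(d) {
    mean(replicate(12, {
      A <- matrix(rbinom(2500, 1, d), 50); diag(A) <- 0
      B <- matrix(rbinom(2500, 1, d), 50); diag(B) <- 0
      jaccard(A, B)$jaccard
    }))
  })
  expect_true(all(diff(mean_j) > 0))
  expect_equal(mean_j, c(0.1, 0.5, 0.9) / (2 - c(0.1, 0.5, 0.9)),
               tolerance = 0.05)
})
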