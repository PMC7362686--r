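test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_children = 1), ">= 2")
  expect_error(synthetic_config(within_group_affinity = 0.1,
                                between_group_affinity = 0.2), "affinity")
  expect_error(synthetic_config(rating_cutpoints = c(0.3, 0.2, 0.4, 0.5)),
               "increasing")
  expect_error(synthetic_config(availability_prob = 1.2), "availability")
})

test_that("latent affinity reflects the group structure and the seed", {
  cfg <- synthetic_config(n_groups = 2, affinity_jitter_sd = 0, seed = 1)
  lat <- generate_latent_affinity(cfg)
  expect_true(isSymmetric(unname(lat$affinity)))
  expect_equal(as.vector(table(lat$groups)), c(8, 8))
  same <- outer(lat$groups, lat$groups, "==")
  diag(same) <- NA
  expect_true(all(lat$affinity[which(same)] == cfg$within_group_affinity))
  expect_true(all(lat$affinity[which(!same)] == cfg$between_group_affinity))

  one <- generate_latent_affinity(synthetic_config(n_groups = 1,
                                                   affinity_jitter_sd = 0))
  expect_equal(length(unique(offdiag_vals <- one$affinity[row(one$affinity)
                                                          != col(one$affinity)])), 1)

  lat2 <- generate_latent_affinity(cfg)
  expect_identical(lat$affinity, lat2$affinity)
})

test_that("observation counts respect availability censoring", {
  cfg <- synthetic_config(seed = 2)
  lat <- generate_latent_affinity(cfg)
  obs <- simulate_observations(lat$affinity, cfg)
  counts <- obs$counts$values
  expect_true(isSymmetric(unname(counts)))
  # no pair can exceed the number of cycles both were available
  joint <- crossprod(obs$availability_log * 1)
  expect_true(all(counts <= joint))
  expect_equal(obs$counts$roster$available_cycles,
               unname(colSums(obs$availability_log)))

  # saturated classroom: every pair interacts in every cycle
  sat <- synthetic_config(availability_prob = 1, within_group_affinity = 1,
                          between_group_affinity = 1,
                          affinity_jitter_sd = 0, n_cycles = 10)
  asat <- generate_latent_affinity(sat)
  osat <- simulate_observations(asat$affinity, sat)
  expect_true(all(osat$counts$values[row(osat$counts$values) !=
                                     col(osat$counts$values)] == 10))

  # zero affinity: no interactions ever
  z <- synthetic_config(within_group_affinity = 0, between_group_affinity = 0,
                        affinity_jitter_sd = 0)
  az <- generate_latent_affinity(z)
  expect_equal(sum(simulate_observations(az$affinity, z)$counts$values), 0)
})

test_that("pair counts match the closed-form expectation", {
  cfg <- synthetic_config(n_children = 6, n_groups = 2, n_cycles = 30,
                          availability_prob = 0.8, affinity_jitter_sd = 0,
                          seed = 10)
  lat <- generate_latent_affinity(cfg)
  reps <- 200
  sums <- matrix(0, 6, 6)
  for (r in seq_len(reps)) {
    sums <- sums + simulate_observations(lat$affinity, cfg, seed = r)$counts$values
  }
  observed_mean <- sums / reps
  expected <- cfg$n_cycles * cfg$availability_prob^2 * lat$affinity
  # per-pair Monte-Carlo tolerance: 3 SE of a binomial count mean
  se <- sqrt(cfg$n_cycles * cfg$availability_prob^2 * lat$affinity *
             (1 - cfg$availability_prob^2 * lat$affinity) / reps)
  off <- row(expected) != col(expected)
  expect_true(all(abs(observed_mean[off] - expected[off]) <=
                  pmax(3 * se[off], 0.05)))
})

test_that("teacher ratings are a monotone step function of affinity", {
  cfg <- synthetic_config(rating_noise_sd = 0, seed = 3)
  lat <- generate_latent_affinity(cfg)
  ratings <- simulate_teacher_ratings(lat$affinity, cfg)
  expect_true(isSymmetric(unname(ratings$values)))
  off <- which(row(lat$affinity) != col(lat$affinity))
  ord <- order(lat$affinity[off])
  expect_true(all(diff(ratings$values[off][ord]) >= 0))

  # affinity entirely below the first cutpoint: all ratings zero
  low <- synthetic_config(within_group_affinity = 0.005,
                          between_group_affinity = 0.001,
                          affinity_jitter_sd = 0, rating_noise_sd = 0,
                          rating_cutpoints = c(0.5, 0.6, 0.7, 0.8))
  alow <- generate_latent_affinity(low)
  expect_equal(sum(simulate_teacher_ratings(alow$affinity, low)$values), 0)
})

test_that("nomination extremes match the logistic link", {
  cfg0 <- synthetic_config(nomination_slope = 0, nomination_intercept = -40)
  lat <- generate_latent_affinity(cfg0)
  expect_equal(sum(simulate_nominations(lat$affinity, cfg0)$values), 0)

  fair <- synthetic_config(nomination_slope = 0, nomination_intercept = 0)
  dens <- mean(sapply(1:30, function(s) {
    noms <- simulate_nominations(lat$affinity, fair, seed = s)
    mean(noms$values[row(noms$values) != col(noms$values)])
  }))
  expect_equal(dens, 0.5, tolerance = 0.05)
})

test_that("a classroom bundle is deterministic and internally consistent", {
  cfg <- synthetic_config(seed = 6)
  c1 <- generate_classroom(cfg)
  c2 <- generate_classroom(cfg)
  expect_identical(c1$counts$values, c2$counts$values)
  expect_identical(c1$nominations$values, c2$nominations$values)
  expect_identical(c1$ratings$values, c2$ratings$values)
  expect_true(c1$nominations$directed)
  expect_false(c1$ratings$directed)
  expect_identical(c1$roster$child_ids, rownames(c1$affinity))

  c3 <- generate_classroom(synthetic_config(seed = 7))
  expect_false(identical(c1$counts$values, c3$counts$values))
})

test_that("default calibration lands in the study-condition bands", {
  stats <- sapply(1:8, function(s) {
    cs <- calibration_summary(generate_classroom(synthetic_config(seed = s)))
    setNames(cs$value, cs$statistic)
  })
  expect_true(all(stats["nomination_density", ] >= 0.05 &
                  stats["nomination_density", ] <= 0.20))
  expect_true(all(stats["rating_mean", ] >= 1.0 &
                  stats["rating_mean", ] <= 1.7))
  expect_equal(mean(stats["count_mean", ]), 1.47, tolerance = 0.25)
  ref <- calibration_summary(generate_classroom(synthetic_config()))$reference
  expect_equal(ref[1:4], c(0.11, 1.35, 0.90, 1.47))
})

test_that("more informant noise lowers congruency with the other informants", {
  mean_r <- sapply(c(0.05, 0.4), function(ns) {
    mean(sapply(1:15, function(s) {
      d <- generate_classroom(synthetic_config(seed = s,
                                               rating_noise_sd = ns))
      child <- binary_network(d$nominations$values, d$roster,
                              directed = TRUE)
      (graph_correlation(child, d$ratings) +
        graph_correlation(d$ratings, d$counts)) / 2
    }))
  })
  expect_gt(mean_r[1], mean_r[2])
})

test_that("twice-chance binarized counts recover the latent tie structure", {
  js <- sapply(1:20, function(s) {
    d <- generate_classroom(synthetic_config(seed = s))
    b <- suppressMessages(binarize_ratio(d$counts, "twice_chance"))
    jaccard(b, latent_tie_network(d))$jaccard
  })
  expect_gte(mean(js), 0.6)
})
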