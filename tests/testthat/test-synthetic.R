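test_that("planted truths honor size schemes and seeds", {
  cfg <- generator_config(n_items = 80, k_true = 4, seed = 1)
  truth <- sample_truth(cfg)
  expect_equal(unname(table(as.integer(truth))), rep(20L, 4),
               ignore_attr = TRUE)
  expect_identical(as.integer(sample_truth(cfg)), as.integer(truth))
  # unequal division spreads the remainder
  cfg48 <- generator_config(n_items = 48, k_true = 5, seed = 2)
  expect_equal(sort(unname(table(as.integer(sample_truth(cfg48))))),
               c(9L, 9L, 10L, 10L, 10L), ignore_attr = TRUE)
  # random sizes never fall below the minimum
  sizes_ok <- vapply(1:200, function(s) {
    cfg_r <- generator_config(n_items = 20, k_true = 4,
                              size_scheme = "random", min_size = 2, seed = s)
    all(table(as.integer(sample_truth(cfg_r))) >= 2)
  }, logical(1))
  expect_true(all(sizes_ok))
  expect_error(generator_config(n_items = 5, k_true = 3, min_size = 2),
               "too small")
})

test_that("zero disagreement reproduces the truth exactly", {
  cfg <- generator_config(n_items = 24, k_true = 3, n_participants = 5,
                          disagreement = 0, seed = 7)
  truth <- sample_truth(cfg)
  sim <- simulate_sorts(truth, cfg)
  for (p in sim$partitions) {
    expect_equal(adjusted_rand_index(p, truth), 1)
  }
  v <- average_sorts(sim$sorts)$values
  expect_true(all(v[upper.tri(v)] %in% c(0, 1)))
})

test_that("the disagreement rate matches its nominal value", {
  cfg <- generator_config(n_items = 80, k_true = 4, n_participants = 20,
                          disagreement = 0.25, seed = 19)
  truth <- sample_truth(cfg)
  sim <- simulate_sorts(truth, cfg)
  off <- vapply(sim$partitions, function(p) {
    mean(as.integer(p) != as.integer(truth))
  }, numeric(1))
  # reassignment always moves to a different cluster, so each participant
  # is off-truth on exactly round(d * n) items
  expect_equal(mean(off), 0.25, tolerance = 1e-12)
})

test_that("full disagreement destroys the planted structure (k >= 3)", {
  cfg <- generator_config(n_items = 48, k_true = 3, n_participants = 10,
                          disagreement = 1, seed = 5)
  truth <- sample_truth(cfg)
  sim <- simulate_sorts(truth, cfg)
  aris <- vapply(sim$partitions, function(p) {
    adjusted_rand_index(p, truth)
  }, numeric(1))
  expect_lt(mean(aris), 0.5)
})

test_that("simulated labels come from the planted category pools", {
  cfg <- generator_config(n_items = 20, k_true = 2, n_participants = 4,
                          shared_labels = 2, seed = 3,
                          category_bounds = c(2L, 10L))
  sim <- simulate_sorts(sample_truth(cfg), cfg)
  expect_true(all(grepl("^(word0[12]|common)", sim$labels$label)))
  expect_true(all(c("participant", "cluster", "label") %in%
                    names(sim$labels)))
})

test_that("noiseless dense trials reproduce the planted co-membership", {
  cfg <- generator_config(n_items = 15, k_true = 3, density = 1,
                          flip_prob = 0, seed = 4)
  truth <- sample_truth(cfg)
  S <- accumulate_trials(simulate_trials(truth, cfg),
                         items = item_ids(truth))
  expect_equal(S$values[upper.tri(S$values)],
               comembership(truth)$values[upper.tri(S$values)])
})

test_that("pure flip noise drives similarities toward one half", {
  cfg <- generator_config(n_items = 12, k_true = 2, density = 1,
                          flip_prob = 0.5, trials_per_pair = 40L, seed = 8,
                          category_bounds = c(2L, 10L))
  truth <- sample_truth(cfg)
  S <- accumulate_trials(simulate_trials(truth, cfg),
                         items = item_ids(truth))
  expect_equal(mean(S$values[S$observed]), 0.5, tolerance = 0.05)
})

test_that("sampling density controls the observed-pair fraction", {
  cfg <- generator_config(n_items = 1000, k_true = 10, density = 0.0638,
                          seed = 21)
  truth <- sample_truth(cfg)
  trials <- simulate_trials(truth, cfg)
  S <- accumulate_trials(trials, items = item_ids(truth))
  n_pairs <- 1000 * 999 / 2
  expected <- n_pairs * 0.0638
  sd_binom <- sqrt(n_pairs * 0.0638 * (1 - 0.0638))
  expect_lt(abs(n_observed_pairs(S) - expected), 3 * sd_binom)
})

test_that("hub-biased sampling concentrates judgements on few items", {
  cfg_hub <- generator_config(n_items = 100, k_true = 4, density = 0.1,
                              pair_sampling = "hub", seed = 9)
  truth <- sample_truth(cfg_hub)
  S <- accumulate_trials(simulate_trials(truth, cfg_hub),
                         items = item_ids(truth))
  deg <- rowSums(S$observed)
  # low-index items are the hubs by construction
  expect_gt(mean(deg[1:10]), mean(deg[91:100]))
})

test_that("the zero-noise round trip recovers truth and k exactly", {
  cfg <- generator_config(n_items = 24, k_true = 3, n_participants = 6,
                          disagreement = 0, density = 1, flip_prob = 0,
                          seed = 13)
  truth <- sample_truth(cfg)
  S_sorts <- average_sorts(simulate_sorts(truth, cfg)$sorts)
  fit <- circa_fit(S_sorts, k = 3, n_restarts = 30, seed = 1)
  expect_equal(fit$alpha, 1)
  expect_equal(adjusted_rand_index(fit$best, truth), 1)
  S_trials <- accumulate_trials(simulate_trials(truth, cfg),
                                items = item_ids(truth))
  fit2 <- circa_fit(S_trials, k = 3, n_restarts = 30, seed = 2)
  expect_equal(adjusted_rand_index(fit2$best, truth), 1)
})
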