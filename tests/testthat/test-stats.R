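# independent enumeration oracle over all sign assignments, via expand.grid
oracle_exact_p <- function(diffs, sidedness = "one_greater") {
  n <- length(diffs)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- as.vector(grid %*% diffs) / n
  obs <- mean(diffs)
  eps <- 1e-8 * max(1, abs(obs)) # ties count as extreme, robust to rounding
  switch(sidedness,
    one_greater = mean(null >= obs - eps),
    one_less = mean(null <= obs + eps),
    two = mean(abs(null) >= abs(obs) - eps)
  )
}

test_that("the observed statistic is the mean difference over non-excluded cages", {
  d <- paired_design(c("a", "b"), c(100, 100), c(110, 130))
  expect_equal(paired_mean_difference(d), 20)
  expect_equal(paired_mean_difference(paired_design("a", 5, 5)), 0)

  d8 <- paired_design(paste0("cage", 1:8), rep(100, 8), 100 + (1:8) * 10)
  d7 <- paired_design(paste0("cage", 1:8), rep(100, 8), 100 + (1:8) * 10,
                      excluded = "cage5")
  expect_equal(paired_mean_difference(d7), mean(((1:8) * 10)[-5]))
  expect_false(paired_mean_difference(d7) == paired_mean_difference(d8))
  all_out <- paired_design("a", 1, 2, excluded = "a")
  expect_error(paired_mean_difference(all_out), class = "wheeltracker_validation_error")
})

test_that("exact enumeration matches brute-force expand.grid on small designs", {
  expect_equal(as.numeric(exact_sign_flip_test(paired_design("a", 0, 5))), 0.5)

  d <- paired_design(c("a", "b"), c(10, 10), c(20, 0)) # diffs +10, -10
  expect_equal(as.numeric(exact_sign_flip_test(d, "two")), 1)

  d3 <- paired_design(paste0("c", 1:3), c(0, 0, 0), c(1, 2, 3))
  expect_equal(as.numeric(exact_sign_flip_test(d3)), 1 / 8)

  set.seed(12)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    diffs <- round(rnorm(n, 0.3, 1), 3)
    d <- paired_design(paste0("c", 1:n), pmax(-diffs, 0), pmax(diffs, 0))
    for (side in c("one_greater", "one_less", "two")) {
      expect_equal(as.numeric(exact_sign_flip_test(d, side)),
                   oracle_exact_p(diffs, side))
    }
  }
  big <- paired_design(paste0("c", 1:21), rep(0, 21), rep(1, 21))
  expect_error(exact_sign_flip_test(big), regexp = "permutation_test",
               class = "wheeltracker_validation_error")
})

test_that("cage order does not change the observed statistic or exact p", {
  diffs <- c(3, -1, 4, 1, -5)
  d <- paired_design(paste0("c", 1:5), pmax(-diffs, 0), pmax(diffs, 0))
  perm <- d[c(4, 2, 5, 1, 3), ]
  expect_equal(paired_mean_difference(perm), paired_mean_difference(d))
  expect_equal(as.numeric(exact_sign_flip_test(perm)),
               as.numeric(exact_sign_flip_test(d)))
})

test_that("negating all differences swaps the one-sided exact p-values", {
  set.seed(5)
  for (i in 1:5) {
    diffs <- rnorm(6)
    d <- paired_design(paste0("c", 1:6), pmax(-diffs, 0), pmax(diffs, 0))
    neg <- paired_design(paste0("c", 1:6), pmax(diffs, 0), pmax(-diffs, 0))
    expect_equal(as.numeric(exact_sign_flip_test(d, "one_greater")),
                 as.numeric(exact_sign_flip_test(neg, "one_less")))
    expect_equal(as.numeric(exact_sign_flip_test(d, "two")),
                 as.numeric(exact_sign_flip_test(neg, "two")))
  }
})

test_that("a degenerate all-zero design gives p = 1", {
  d <- paired_design(paste0("c", 1:4), rep(7, 4), rep(7, 4))
  res <- permutation_test(d, 100, seed = 1)
  expect_true(all(res$null_stats == 0))
  expect_equal(res$p_empirical_add_one, 1)
  expect_equal(res$p_empirical, 1)
  expect_equal(res$p_density_auc, 1)
})

test_that("Monte-Carlo p is reproducible and respects the estimator ordering", {
  d <- paired_design(paste0("c", 1:6), rep(100, 6), c(120, 130, 90, 140, 150, 110))
  a <- permutation_test(d, 1000, seed = 9)
  b <- permutation_test(d, 1000, seed = 9)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(a$p_value, b$p_value)
  expect_equal(length(a$null_stats), 1000)
  expect_gte(a$p_empirical_add_one, a$p_empirical * 1000 / 1001)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
})

test_that("density-AUC p tracks the empirical tail on Gaussian designs", {
  set.seed(17)
  for (i in 1:5) {
    diffs <- rnorm(8, 0.4, 1)
    d <- paired_design(paste0("c", 1:8), pmax(-diffs, 0), pmax(diffs, 0))
    res <- permutation_test(d, 2000, seed = i)
    expect_lt(abs(res$p_density_auc - res$p_empirical), 0.02)
  }
})

test_that("Monte-Carlo p agrees with enumeration within 3 binomial SEs", {
  set.seed(23)
  for (i in 1:4) {
    n <- sample(5:12, 1)
    diffs <- rnorm(n, 0.5, 1.2)
    d <- paired_design(paste0("c", 1:n), pmax(-diffs, 0), pmax(diffs, 0))
    p_exact <- as.numeric(exact_sign_flip_test(d))
    res <- permutation_test(d, 1e5, seed = 1000 + i, estimator = "empirical")
    se <- sqrt(p_exact * (1 - p_exact) / 1e5)
    expect_lt(abs(res$p_empirical - p_exact), 3 * se + 1e-12)
  }
})

test_that("tidy and glance expose all estimators and the run metadata", {
  d <- paired_design(paste0("c", 1:6), rep(100, 6), c(120, 130, 90, 140, 150, 110))
  res <- permutation_test(d, 500, seed = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 3)
  expect_setequal(td$estimator, c("empirical", "empirical_add_one", "density_auc"))
  expect_true(all(td$estimate == res$observed_stat))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$p.value, res$p_value)
  expect_equal(gl$seed, 3L)
})

test_that("near-noiseless positive effects are always detected at n = 8", {
  # with all differences equal and positive the exact one-sided p is 2^-n
  d <- paired_design(paste0("c", 1:8), rep(0, 8), rep(10, 8))
  expect_equal(as.numeric(exact_sign_flip_test(d)), 2^-8)
  oc <- simulate_operating_characteristics(
    n_cages = 8, effect_cm = 10, noise_sd_cm = 1e-9, n_reps = 20,
    n_permutations = 500, seed = 2
  )
  expect_equal(oc$rejection_rate, 1)
})

test_that("a single replicate returns a 0/1 rejection indicator", {
  oc <- simulate_operating_characteristics(
    n_cages = 6, effect_cm = 0, noise_sd_cm = 1, n_reps = 1,
    n_permutations = 200, seed = 4
  )
  expect_true(oc$rejection_rate %in% c(0, 1))
})

test_that("paired designs round-trip through CSV with exclusions", {
  d <- paired_design(paste0("cage", 1:8), rep(1e5, 8), 1e5 + (1:8) * 1000,
                     excluded = "cage5")
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_design(d, path)
  back <- read_paired_design(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(d))
  more <- read_paired_design(path, excluded = "cage1")
  expect_setequal(more$cage[more$excluded], c("cage1", "cage5"))
})
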