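test_that("perfect predictions give the identity statistics", {
  obs <- c(5.1, 6.2, 7.3, 8.4)
  s <- regression_validation_stats(obs, obs)
  expect_equal(s$r2, 1); expect_equal(s$r0_2, 1); expect_equal(s$rm_2, 1)
  expect_equal(s$k, 1); expect_equal(s$k_prime, 1); expect_equal(s$rmse, 0)
})

test_that("constant predictions hit the error branch", {
  expect_error(regression_validation_stats(rep(6, 4), c(5, 6, 7, 8)),
               "constant")
  expect_error(regression_validation_stats(c(1, 2), c(1, 2)))
  expect_error(regression_validation_stats(c(1, 2, 3), c(5, 5, 5)))
})

test_that("statistics equal a spreadsheet-style manual evaluation", {
  pred <- c(6.1, 7.0, 8.2); obs <- c(6.0, 7.1, 8.0)
  s <- regression_validation_stats(pred, obs)
  # manual arithmetic on the defining formulas
  r_manual <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    (sqrt(sum((pred - mean(pred))^2)) * sqrt(sum((obs - mean(obs))^2)))
  expect_equal(s$pearson_r, r_manual, tolerance = 1e-12)
  expect_equal(s$r2, r_manual^2, tolerance = 1e-12)
  r0_manual <- 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
  expect_equal(s$r0_2, r0_manual, tolerance = 1e-12)
  r0p_manual <- 1 - sum((obs - pred)^2) / sum((pred - mean(pred))^2)
  expect_equal(s$r0p_2, r0p_manual, tolerance = 1e-12)
  expect_equal(s$k, sum(pred * obs) / sum(pred^2), tolerance = 1e-12)
  expect_equal(s$rm_2, s$r2 * (1 - sqrt(abs(s$r2 - s$r0_2))),
               tolerance = 1e-12)
  expect_equal(s$rmse, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  # the printed-formula variant of k is preserved behind the flag
  s_legacy <- regression_validation_stats(pred, obs, legacy_k = TRUE)
  expect_equal(s_legacy$k, sum(pred * obs) / sum(pred), tolerance = 1e-12)
})

test_that("F statistics reproduce the printed model table at df 30", {
  f1 <- f_statistic(0.8514, m = 1, n = 32)
  expect_lt(abs(f1$F - 171.8), 0.5)
  f2 <- f_statistic(0.8614, m = 1, n = 32)
  expect_lt(abs(f2$F - 186.5), 0.5)
  expect_equal(f_statistic(0, 1, 32)$F, 0)
  expect_equal(f_statistic(1, 1, 32)$F, Inf)
  expect_error(f_statistic(0.5, 5, 6))
})

test_that("the seven df-30 table rows are F-consistent with their printed r2", {
  printed <- rbind(
    c(0.8514, 171.8), c(0.8488, 168.4), c(0.8488, 168.4), c(0.8368, 153.9),
    c(0.8368, 153.9), c(0.8471, 166.3), c(0.8614, 186.5))
  for (i in seq_len(nrow(printed))) {
    expect_lt(abs(f_statistic(printed[i, 1], 1, 32)$F - printed[i, 2]), 0.5)
  }
})

test_that("F is monotone in r2 and in n", {
  r2s <- seq(0.1, 0.9, by = 0.1)
  Fs <- vapply(r2s, function(r) f_statistic(r, 1, 32)$F, numeric(1))
  expect_true(all(diff(Fs) > 0))
  ns <- seq(10, 60, by = 10)
  Fn <- vapply(ns, function(n) f_statistic(0.7, 1, n)$F, numeric(1))
  expect_true(all(diff(Fn) > 0))
})

test_that("k times k_prime bounds the squared Pearson correlation", {
  set.seed(77)
  for (i in 1:20) {
    pred <- runif(10, 4, 9); obs <- pred + rnorm(10, 0, runif(1, 0.1, 2))
    s <- regression_validation_stats(pred, obs)
    expect_gte(s$k * s$k_prime + 1e-12, s$r2)
    expect_lte(s$rm_2, s$r2 + 1e-12)
    expect_lte(s$r0_2, 1)
  }
})

test_that("external q2 hits its anchor cases", {
  obs <- c(5, 6, 7, 8)
  expect_equal(external_q2(obs, obs), 1)
  expect_equal(external_q2(rep(mean(obs), 4), obs), 0)
  expect_error(external_q2(numeric(0), numeric(0)))
})

test_that("acceptance rule set reports verbatim failures", {
  good <- list(q2 = 1, r2 = 1, r0_2 = 1, r0p_2 = 1, k = 1, rm_2 = 1)
  expect_true(accept_model(good)$accepted)
  bad <- good; bad$q2 <- 0.49
  res <- accept_model(bad)
  expect_false(res$accepted)
  expect_equal(res$failed_criteria, "q2 > 0.5")
  # the printed r2/q2 of the best published model pass their criteria
  tab1 <- list(q2 = 0.6789, r2 = 0.8514, r0_2 = 0.8514, r0p_2 = 0.8514,
               k = 1, rm_2 = 0.8514)
  expect_true(accept_model(tab1)$accepted)
  expect_error(accept_model(list(q2 = 1)), "lacks")
})

test_that("LOO stability is high for clean linear data and bounded", {
  set.seed(30)
  n <- 20; p <- 5
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  y <- 5 + as.numeric(X %*% runif(p, 0.3, 1))
  s <- loo_stability(X, y, n_factors = p)
  expect_gt(s, 0.99)
  # minimal n = 5 stays within [0, 1]
  s5 <- loo_stability(X[1:5, ], y[1:5], n_factors = 1)
  expect_gte(s5, 0); expect_lte(s5, 1)
  # duplicating every row must not destabilize
  s_dup <- loo_stability(rbind(X, X), c(y, y), n_factors = p)
  expect_lt(abs(s_dup - s), 0.01)
})
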