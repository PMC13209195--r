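test_that("one-column PLS equals simple least squares", {
  set.seed(3)
  x <- matrix(rbinom(40, 1, 0.5), 40, 1)
  y <- 5 + 0.8 * x[, 1] + rnorm(40, 0, 0.1)
  f <- qsarphore:::pls1_fit(x, y, 1)
  ols <- lm(y ~ x)
  expect_equal(f$coef, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("PLS agrees with an independent implementation (mixOmics)", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, paste0("b", 1:8)))
  y <- X %*% rnorm(8) + rnorm(30, 0, 0.2)
  for (m in c(1, 3)) {
    ours <- qsarphore:::pls1_fit(X, as.numeric(y), m)
    ref <- mixOmics::pls(X, y, ncomp = m, mode = "regression",
                         scale = FALSE)
    pred_ref <- predict(ref, X)$predict[, 1, m]
    pred_ours <- qsarphore:::pls1_predict(ours, X)
    expect_equal(pred_ours, unname(pred_ref), tolerance = 1e-6)
  }
})

test_that("noiseless planted-linear data is fitted exactly", {
  set.seed(4)
  n <- 30; p <- 6
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  beta <- runif(p, 0.2, 1)
  y <- 5 + as.numeric(X %*% beta)
  model <- fit_qsar_pls(X, y, max_factors = p, t_cutoff = 0,
                        min_support = 0)
  expect_gt(cor(model$fitted, y)^2, 1 - 1e-6)
})

test_that("training predictions reproduce stored fitted values", {
  ds <- small_synthetic(seed = 5, n_act = 10, n_inact = 10)
  h <- planted_hypothesis(ds)
  occ <- build_occupancy_matrix(ds$molecules, h)
  y <- vapply(ds$molecules, `[[`, numeric(1), "pIC50")
  model <- fit_qsar_pls(occ$X, y, grid = occ$grid, hypothesis = h,
                        ids = occ$ids)
  pred <- vapply(ds$molecules[1:5], function(m) predict_molecule(model, m),
                 numeric(1))
  expect_equal(pred, model$fitted[1:5], tolerance = 1e-8)
})

test_that("predictions are invariant to rigid motion of the input", {
  ds <- small_synthetic(seed = 5, n_act = 10, n_inact = 10)
  h <- planted_hypothesis(ds)
  occ <- build_occupancy_matrix(ds$molecules, h)
  y <- vapply(ds$molecules, `[[`, numeric(1), "pIC50")
  model <- fit_qsar_pls(occ$X, y, grid = occ$grid, hypothesis = h,
                        ids = occ$ids)
  conf <- ds$molecules[[1]]$conformers[[1]]
  p0 <- predict_activity(model, conf)
  moved <- rigid_transform_conformer(conf, rotmat_z(0.9), c(7, -1, 3))
  expect_equal(predict_activity(model, moved), p0, tolerance = 1e-6)
})

test_that("prediction is absent for non-matching conformers", {
  ds <- small_synthetic(seed = 5, n_act = 10, n_inact = 10)
  h <- planted_hypothesis(ds)
  occ <- build_occupancy_matrix(ds$molecules, h)
  y <- vapply(ds$molecules, `[[`, numeric(1), "pIC50")
  model <- fit_qsar_pls(occ$X, y, grid = occ$grid, hypothesis = h,
                        ids = occ$ids)
  conf <- conformer(matrix(0, 1, 3), "C")
  conf$features <- feature_sites("H", matrix(0, 1, 3))
  expect_true(is.na(predict_activity(model, conf)))
})

test_that("fit is invariant to training-row permutation", {
  set.seed(12)
  n <- 25; p <- 10
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  y <- 5 + X %*% runif(p, 0, 0.5) + rnorm(n, 0, 0.2)
  m1 <- fit_qsar_pls(X, as.numeric(y), min_support = 0)
  perm <- sample(n)
  m2 <- fit_qsar_pls(X[perm, ], as.numeric(y)[perm], min_support = 0)
  expect_equal(m2$coefficients, m1$coefficients, tolerance = 1e-8)
  expect_equal(m2$intercept, m1$intercept, tolerance = 1e-8)
})

test_that("degenerate inputs error", {
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  expect_error(fit_qsar_pls(X, rep(5, 10)), "constant")
  expect_error(fit_qsar_pls(matrix(1, 10, 3), rnorm(10)), "columns")
})
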