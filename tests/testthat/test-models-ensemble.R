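test_that("constant-learner boosting follows the geometric residual form", {
  y <- rep(2, 12)
  X <- random_coded(12, 5, seed = 81)
  fit <- fit_boosting(y, X, learning_rate = 0.5, n_rounds = 2,
                      max_depth = 0)
  # 2 * (1 - (1 - v)^M) = 1.5
  expect_equal(unname(unique(round(fit$gebv, 12))), 1.5)
  zero <- fit_boosting(y + rnorm(12), X, learning_rate = 0, n_rounds = 10,
                       max_depth = 1)
  expect_true(all(zero$gebv == 0))
})

test_that("training MSE never increases along boosting rounds", {
  set.seed(82)
  pop <- small_population(n = 60, m = 100, seed = 82)
  y <- level_trait(pop)
  fit <- fit_boosting(y, pop$coded, learning_rate = 0.1, n_rounds = 200,
                      max_depth = 2)
  expect_true(all(diff(fit$training_meta$mse_trace) <= 1e-9))
})

test_that("schedule mode applies the decaying learning-rate trace", {
  y <- rnorm(20)
  X <- random_coded(20, 10, seed = 83)
  fit <- fit_boosting(y, X, n_rounds = 5, max_depth = 1, schedule = TRUE,
                      alpha0 = 1)
  expect_equal(fit$training_meta$rates, 100 / (100 + 0:4))
})

test_that("marker-tree splits agree with the rpart oracle", {
  skip_if_not_installed("rpart")
  for (s in 1:3) {
    X <- random_coded(70, 30, seed = 90 + s)
    set.seed(90 + s)
    y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(70)
    mine <- gsnue:::fit_marker_tree(X, y, max_depth = 1)
    df <- as.data.frame(X)
    names(df) <- paste0("m", seq_len(ncol(X)))
    df$.r <- y
    ref <- rpart::rpart(.r ~ ., df, method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = 0, minsplit = 5,
                          minbucket = 2, xval = 0, maxcompete = 0,
                          maxsurrogate = 0))
    expect_equal(gsnue:::predict_marker_tree(mine, X),
                 unname(predict(ref, df)), tolerance = 1e-10)
  }
})

test_that("bagging with the constant learner averages resample means", {
  set.seed(84)
  y <- rnorm(50, mean = 3)
  X <- random_coded(50, 20, seed = 84)
  fit <- fit_bagging(y, X, n_bags = 200, max_depth = 0, seed = 7)
  se <- sd(y) / sqrt(50)
  expect_lt(abs(mean(fit$gebv) - mean(y)), 2 * se)
  expect_equal(length(unique(round(fit$gebv, 12))), 1L)
})

test_that("bagging is reproducible and averages more trees more stably", {
  pop <- small_population(n = 40, m = 60, seed = 85)
  y <- level_trait(pop)
  f1 <- fit_bagging(y, pop$coded, n_bags = 30, seed = 4)
  f2 <- fit_bagging(y, pop$coded, n_bags = 30, seed = 4)
  expect_identical(f1$gebv, f2$gebv)
  expect_true(is.finite(f1$training_meta$oob_mse))

  # variance of the bagged prediction at a fixed genotype is
  # non-increasing in the number of bags (one Monte-Carlo violation allowed)
  vars <- sapply(c(1, 10, 50), function(B) {
    preds <- sapply(1:30, function(s)
      fit_bagging(y, pop$coded, n_bags = B, seed = 100 + s)$gebv[1])
    var(preds)
  })
  expect_lte(sum(diff(vars) > 0), 1)
})

test_that("stacking recovers an oracle base model", {
  set.seed(86)
  n <- 300
  truth <- rnorm(n)
  y <- truth
  oof <- cbind(oracle = truth + rnorm(n) * 0.01,
               noise1 = rnorm(n), noise2 = rnorm(n))
  fit <- fit_stacking(y, oof)
  w <- fit$training_meta$weights
  expect_gte(w["oracle"] / sum(w), 0.9)
})

test_that("identical bases collapse to the common prediction", {
  set.seed(87)
  n <- 80
  base <- rnorm(n)
  y <- base + rnorm(n) * 0.1
  oof <- cbind(a = base, b = base, c = base)
  fit <- fit_stacking(y, oof)
  manual <- fit$intercept + base * sum(fit$training_meta$weights)
  expect_equal(unname(fit$gebv + fit$intercept), manual, tolerance = 1e-8)
})

test_that("epsilon-insensitive stacking loss vanishes inside the tube", {
  set.seed(88)
  n <- 60
  base <- rnorm(n)
  y <- base + rnorm(n) * 0.05
  oof <- cbind(a = base, b = base + rnorm(n) * 0.05)
  fit <- fit_stacking(y, oof, epsilon = 10)
  expect_equal(fit$training_meta$meta_loss, 0)
  expect_error(fit_stacking(y, oof[, 1, drop = FALSE]), "at least 2")
})

test_that("non-negative least squares matches lm on a positive problem", {
  set.seed(89)
  A <- cbind(1, matrix(runif(60), 20, 3))
  b <- drop(A %*% c(-1, 2, 0.5, 1)) + rnorm(20) * 0.01
  w <- gsnue:::nnls_fit(A, b, free = 1L)
  ref <- lm.fit(A, b)$coefficients
  expect_equal(unname(w), unname(ref), tolerance = 1e-6)
  # negative true weight gets clipped to the boundary
  b2 <- drop(A %*% c(0, -2, 1, 1))
  w2 <- gsnue:::nnls_fit(A, b2, free = 1L)
  expect_true(all(w2[-1] >= 0))
  expect_equal(unname(w2[2]), 0)
})
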