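#' K-nearest-neighbour regression
#'
#' Predicts each test point as the mean response of its k nearest training
#' points under Euclidean distance on the coded marker rows (or any
#' supplied feature matrix). Distance ties are broken by the lowest
#' training index, so predictions are deterministic.
#'
#' @param train_x,train_y Training features (matrix) and responses.
#' @param test_x Test feature matrix.
#' @param k Neighbour count, 1 <= k <= nrow(train_x).
#' @return Numeric predictions, one per test row.
#' @export
knn_predict <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  n <- nrow(train_x)
  assert_that(is_count(k) && k <= n, "k must lie in [1, n_train]")
  assert_that(length(train_y) == n, "train_y must match train_x")
  d2 <- outer(rowSums(test_x^2), rep(1, n)) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  apply(d2, 1, function(di) {
    nb <- order(di, seq_len(n))[seq_len(k)] # ties: lowest index first
    mean(train_y[nb])
  })
}

#' Bias-variance decomposition over a complexity grid
#'
#' For each complexity value, the predictor is fitted on `B` resampled
#' training sets and evaluated at a fixed set of test points:
#' bias^2 = mean over test points of (mean prediction - true target)^2,
#' variance = mean over test points of the across-resample prediction
#' variance, expected loss = mean squared error against the (noisy) test
#' responses. In synthetic mode the data source draws a fresh training set
#' per resample and the truth and noise floor are known; on a fixed dataset
#' training rows are bootstrapped and the held-out phenotype serves as the
#' target.
#'
#' @param predictor `function(train_x, train_y, test_x, complexity)`
#'   returning test predictions; see [knn_bias_variance()] for the KNN
#'   reference family.
#' @param data_source Either a function `function(b)` returning
#'   `list(train_x, train_y)` for resample b (synthetic mode; supply
#'   `test_x`, `test_truth`, `sigma2_e`), or a
#'   `list(x, y)` fixed dataset to bootstrap.
#' @param complexity_grid Numeric complexity values (for KNN: k).
#' @param B Resamples (>= 10).
#' @param test_x,test_truth,sigma2_e Fixed test points, their true targets
#'   and the irreducible noise variance (synthetic mode).
#' @param holdout Fraction of a fixed dataset reserved as test points.
#' @param seed Resampling seed.
#' @return Tibble of class `bias_variance` with one row per complexity:
#'   `bias2`, `variance`, `expected_loss`, `irreducible_error`,
#'   `n_resamples` and Monte-Carlo standard errors.
#' @export
decompose_bias_variance <- function(predictor, data_source,
                                    complexity_grid, B = 200,
                                    test_x = NULL, test_truth = NULL,
                                    sigma2_e = NULL, holdout = 0.25,
                                    seed = 1) {
  assert_that(is_count(B) && B >= 10, "B must be a count >= 10")
  synthetic <- is.function(data_source)
  if (synthetic) {
    assert_that(!is.null(test_x) && !is.null(test_truth),
                "synthetic mode needs test_x and test_truth")
  } else {
    assert_that(is.list(data_source) &&
                  all(c("x", "y") %in% names(data_source)),
                "fixed mode needs list(x, y)")
  }
  local_rng(seed_stream(seed, "bias-variance"), {
    if (!synthetic) {
      n <- length(data_source$y)
      te <- sample.int(n, max(2, floor(holdout * n)))
      tr_pool <- setdiff(seq_len(n), te)
      test_x <- data_source$x[te, , drop = FALSE]
      test_obs <- data_source$y[te]
      test_truth <- test_obs # observed phenotype stands in for the target
    }
    n_test <- nrow(as.matrix(test_x))
    rows <- list()
    for (cx in sort(complexity_grid)) {
      preds <- matrix(NA_real_, n_test, B)
      sq_loss <- matrix(NA_real_, n_test, B)
      for (b in seq_len(B)) {
        if (synthetic) {
          ds <- data_source(b)
          target <- test_truth +
            if (!is.null(sigma2_e) && sigma2_e > 0)
              rnorm(n_test, 0, sqrt(sigma2_e)) else 0
        } else {
          idx <- sample(tr_pool, length(tr_pool), replace = TRUE)
          ds <- list(train_x = data_source$x[idx, , drop = FALSE],
                     train_y = data_source$y[idx])
          target <- test_obs
        }
        preds[, b] <- predictor(ds$train_x, ds$train_y, test_x, cx)
        sq_loss[, b] <- (preds[, b] - target)^2
      }
      mean_pred <- rowMeans(preds)
      bias2_pt <- (mean_pred - test_truth)^2
      var_pt <- apply(preds, 1, stats::var)
      loss_pt <- rowMeans(sq_loss)
      ie <- if (synthetic) (sigma2_e %||% 0) else
        max(mean(loss_pt) - mean(bias2_pt) - mean(var_pt), 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        complexity = cx,
        bias2 = mean(bias2_pt),
        variance = mean(var_pt),
        expected_loss = mean(loss_pt),
        irreducible_error = ie,
        n_resamples = B,
        se_loss = sd(colMeans(sq_loss)) / sqrt(B),
        se_variance = sd(var_pt) / sqrt(n_test)
      )
    }
    out <- dplyr::bind_rows(rows)
    structure(out, synthetic = synthetic,
              class = c("bias_variance", class(out)))
  })
}

#' KNN bias-variance sweep on a synthetic population
#'
#' Convenience wrapper running [decompose_bias_variance()] with the KNN
#' reference family over a grid of neighbour counts. One superpopulation
#' is simulated (so the genetic architecture -- the true genotype-to-trait
#' function -- is fixed); `n_test` genotypes are held out as fixed test
#' points with known true genetic values, and each resample draws a fresh
#' training set (new genotype sample from the pool, fresh phenotype
#' noise). This is the classical complexity sweep: prediction variance
#' falls with k while squared bias rises towards the population variance
#' of the true genetic values as predictions collapse to the mean.
#'
#' @param config A [population_config()]; its trait model defines truth
#'   and noise. The config's `n_genotypes` is the training-set size per
#'   resample; the superpopulation pool holds `pool_factor` times that.
#' @param k_grid Neighbour counts to sweep.
#' @param n_test Held-fixed test genotypes.
#' @param B Resamples.
#' @param n_level `"LN"` or `"HN"`.
#' @param pool_factor Superpopulation size multiplier (default 3).
#' @param seed Seed.
#' @return A `bias_variance` tibble (see [decompose_bias_variance()]).
#' @export
knn_bias_variance <- function(config, k_grid = c(1, 5, 25, 100),
                              n_test = 40, B = 200, n_level = "LN",
                              pool_factor = 3, seed = 1) {
  cfg <- config
  n_train <- cfg$n_genotypes
  cfg$n_genotypes <- as.integer(pool_factor * n_train + n_test)
  cfg$missing_rate <- 0
  cfg$seed <- seed_stream(seed, "bv-pop")
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  truth_all <- sim$architecture$true_gebv[, n_level] +
    sim$architecture$mu[[n_level]]
  s2e <- sim$architecture$sigma2_e[[n_level]]
  x_all <- impute_marker_mean(G) - 1
  te <- seq_len(n_test)
  pool <- setdiff(seq_len(nrow(G)), te)
  draws <- local_rng(seed_stream(seed, "bv-draws"), lapply(seq_len(B),
    function(b) {
      idx <- sample(pool, n_train)
      noise <- if (s2e > 0) rnorm(n_train, 0, sqrt(s2e)) else 0
      list(train_x = x_all[idx, , drop = FALSE],
           train_y = truth_all[idx] + noise)
    }))
  decompose_bias_variance(
    predictor = function(tx, ty, sx, k) knn_predict(tx, ty, sx, k),
    data_source = function(b) draws[[b]],
    complexity_grid = pmin(k_grid, n_train),
    B = B,
    test_x = x_all[te, , drop = FALSE],
    test_truth = truth_all[te],
    sigma2_e = s2e,
    seed = seed
  )
}

#' Irreducible error of a prediction problem
#'
#' Synthetic mode returns the generator's true residual variance; replicate
#' mode the within-genotype variance of replicated observations; residual
#' mode (fixed data, no replicates) the expected loss minus bias^2 and
#' variance from a stored decomposition row, floored at zero with a
#' warning.
#'
#' @param mode One of `"synthetic"`, `"replicate"`, `"residual"`.
#' @param sigma2_e True noise variance (synthetic mode).
#' @param replicates Data frame with `genotype_id` and `value` columns
#'   (replicate mode).
#' @param row One row of a [decompose_bias_variance()] table (residual
#'   mode).
#' @return Irreducible error (trait units squared).
#' @export
estimate_irreducible_error <- function(mode = c("synthetic", "replicate",
                                                "residual"),
                                       sigma2_e = NULL, replicates = NULL,
                                       row = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    synthetic = {
      assert_that(is.numeric(sigma2_e) && sigma2_e >= 0,
                  "synthetic mode needs the true sigma2_e")
      sigma2_e
    },
    replicate = {
      assert_that(is.data.frame(replicates) &&
                    all(c("genotype_id", "value") %in% names(replicates)),
                  "replicate mode needs genotype_id/value records")
      reps <- dplyr::filter(
        dplyr::summarise(dplyr::group_by(replicates, .data$genotype_id),
                         v = stats::var(.data$value), n = dplyr::n()),
        .data$n >= 2)
      assert_that(nrow(reps) > 0, "no genotype has replicate observations")
      mean(reps$v)
    },
    residual = {
      assert_that(is.list(row) &&
                    all(c("expected_loss", "bias2", "variance") %in% names(row)),
                  "residual mode needs a decomposition row")
      ie <- row$expected_loss - row$bias2 - row$variance
      if (ie < 0) {
        warn("residual-mode irreducible error was negative; floored at 0")
        ie <- 0
      }
      ie
    }
  )
}
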