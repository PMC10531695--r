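#' Stage-wise gradient boosting on marker columns
#'
#' Squared-loss gradient boosting with depth-limited regression-tree weak
#' learners grown on the coded marker columns (exhaustive
#' variance-reduction splits over the dosage thresholds; see the methods
#' vignette). Starts from F0 = 0 (the
#' intercept is absorbed by the first rounds) and adds `learning_rate`
#' times each tree's fit to the current residuals. `max_depth = 0` uses the
#' constant (mean-of-residuals) weak learner. With `schedule = TRUE` the
#' per-round rate follows the epoch schedule alpha_j = 100 alpha0 / (100 +
#' j) instead of the constant `learning_rate`; the trace actually applied
#' is recorded either way.
#'
#' @param y Phenotype vector.
#' @param X Complete coded marker matrix.
#' @param learning_rate Constant shrinkage v in [0, 1].
#' @param n_rounds Number of boosting rounds M (>= 1).
#' @param max_depth Tree depth (0 = constant learner).
#' @param schedule Use the decaying learning-rate schedule.
#' @param alpha0 Initial rate of the schedule.
#' @return A `gs_fit`; `training_meta` holds the trees, applied rate trace
#'   and training-MSE trace.
#' @export
fit_boosting <- function(y, X, learning_rate = 0.1, n_rounds = 100,
                         max_depth = 2, schedule = FALSE, alpha0 = 1) {
  assert_that(is.matrix(X) && !anyNA(X) && nrow(X) == length(y),
              "X must be complete and match y")
  assert_that(is.numeric(learning_rate) && learning_rate >= 0 &&
                learning_rate <= 1, "learning_rate must lie in [0, 1]")
  assert_that(is_count(n_rounds), "n_rounds must be a positive count")
  assert_that(is.numeric(max_depth) && max_depth >= 0,
              "max_depth must be >= 0")
  rates <- if (schedule)
    learning_rate_schedule(alpha0, n_rounds - 1)$alpha
  else rep(learning_rate, n_rounds)
  Fhat <- numeric(length(y))
  trees <- vector("list", n_rounds)
  mse_trace <- numeric(n_rounds)
  for (m in seq_len(n_rounds)) {
    resid <- y - Fhat
    if (max_depth == 0) {
      trees[[m]] <- mean(resid)
      pred <- rep(mean(resid), length(y))
    } else {
      tr <- fit_marker_tree(X, resid, max_depth)
      trees[[m]] <- tr
      pred <- predict_marker_tree(tr, X)
    }
    Fhat <- Fhat + rates[m] * pred
    mse_trace[m] <- mean((y - Fhat)^2)
  }
  names(Fhat) <- rownames(X)
  new_gs_fit("boost", y, Fhat, 0,
             regularization = list(v = learning_rate,
                                   n_rounds = n_rounds,
                                   max_depth = max_depth),
             training_meta = list(trees = trees, rates = rates,
                                  mse_trace = mse_trace,
                                  schedule = schedule))
}

#' Bootstrap-aggregated regression trees (bagging)
#'
#' B bootstrap resamples of genotypes, one regression tree per resample;
#' the GEBV is the mean of the tree predictions. The out-of-bag (OOB) mean
#' squared error and the bootstrap mean of the ensemble prediction (the
#' bagged estimator's own bias diagnostic) are reported.
#'
#' @param y Phenotype vector.
#' @param X Complete coded marker matrix.
#' @param n_bags Number of bootstrap resamples B (>= 1).
#' @param max_depth Tree depth (0 = constant learner, for which the bagged
#'   prediction is the average of resample means).
#' @param seed Resampling seed; fixed seed gives identical GEBVs.
#' @return A `gs_fit`; `training_meta` holds the trees, bag indices, OOB
#'   error and bootstrap mean.
#' @export
fit_bagging <- function(y, X, n_bags = 50, max_depth = 3, seed = 1) {
  assert_that(is.matrix(X) && !anyNA(X) && nrow(X) == length(y),
              "X must be complete and match y")
  assert_that(is_count(n_bags), "n_bags must be a positive count")
  n <- length(y)
  local_rng(seed_stream(seed, "bagging"), {
    preds <- matrix(0, n, n_bags)
    inbag <- matrix(FALSE, n, n_bags)
    trees <- vector("list", n_bags)
    for (b in seq_len(n_bags)) {
      idx <- sample.int(n, n, replace = TRUE)
      inbag[unique(idx), b] <- TRUE
      if (max_depth == 0) {
        trees[[b]] <- mean(y[idx])
        preds[, b] <- mean(y[idx])
      } else {
        tr <- fit_marker_tree(X[idx, , drop = FALSE], y[idx], max_depth)
        trees[[b]] <- tr
        preds[, b] <- predict_marker_tree(tr, X)
      }
    }
    gebv <- rowMeans(preds)
    names(gebv) <- rownames(X)
    oob_pred <- vapply(seq_len(n), function(i) {
      out <- !inbag[i, ]
      if (any(out)) mean(preds[i, out]) else NA_real_
    }, numeric(1))
    oob_mse <- mean((y - oob_pred)^2, na.rm = TRUE)
    new_gs_fit("bagg", y, gebv, 0,
               regularization = list(n_bags = n_bags,
                                     max_depth = max_depth),
               training_meta = list(trees = trees, seed = seed,
                                    oob_mse = oob_mse,
                                    bootstrap_mean = mean(colMeans(preds)),
                                    max_depth = max_depth))
  })
}

#' Stacking meta-learner over base GS models
#'
#' Combines base models through meta-learning: a non-negative least squares
#' fit (with free intercept) of the phenotype on the base models'
#' out-of-fold predictions, so the meta-weights are learned without
#' leakage and stay interpretable as a convex-like mixture. An optional
#' epsilon-insensitive variant re-fits ignoring observations whose current
#' meta-residual is inside the epsilon tube, mirroring the stacking loss
#' that charges nothing below epsilon; the reported `meta_loss` is the mean
#' epsilon-insensitive residual magnitude.
#'
#' @param y Phenotype vector.
#' @param oof n x B matrix of out-of-fold base predictions (columns named
#'   by base model), aligned to `y`.
#' @param base_gebv Optional n x B matrix of the base models' full-data
#'   GEBVs; when given, the stacked GEBV is the weighted combination of
#'   these (otherwise of the out-of-fold predictions).
#' @param epsilon Tube half-width of the insensitive variant (0 disables).
#' @param nonneg Constrain weights to be non-negative (default TRUE).
#' @return A `gs_fit`; `training_meta$weights` holds the named meta-weights.
#' @export
fit_stacking <- function(y, oof, base_gebv = NULL, epsilon = 0,
                         nonneg = TRUE) {
  oof <- as.matrix(oof)
  assert_that(ncol(oof) >= 2, "stacking needs at least 2 base models")
  assert_that(nrow(oof) == length(y), "out-of-fold predictions must align to y")
  if (is.null(colnames(oof))) colnames(oof) <- paste0("base", seq_len(ncol(oof)))
  fit_w <- function(rows) {
    A <- cbind(`(Intercept)` = 1, oof[rows, , drop = FALSE])
    free <- 1L # intercept unconstrained
    if (nonneg) nnls_fit(A, y[rows], free = free)
    else drop(stats::lm.fit(A, y[rows])$coefficients)
  }
  active <- rep(TRUE, length(y))
  coefs <- fit_w(active)
  if (epsilon > 0) {
    for (it in 1:20) {
      r <- y - drop(cbind(1, oof) %*% coefs)
      new_active <- abs(r) >= epsilon
      if (!any(new_active)) break
      if (identical(new_active, active)) break
      active <- new_active
      coefs <- fit_w(active)
    }
  }
  w <- coefs[-1]
  intercept <- coefs[1]
  resid <- y - drop(cbind(1, oof) %*% coefs)
  meta_loss <- mean(pmax(abs(resid) - epsilon, 0))
  comb <- if (!is.null(base_gebv)) as.matrix(base_gebv) else oof
  gebv <- drop(comb %*% w)
  names(gebv) <- rownames(oof)
  new_gs_fit("stack", y, gebv, intercept,
             regularization = list(epsilon = epsilon, nonneg = nonneg),
             training_meta = list(weights = setNames(w, colnames(oof)),
                                  meta_loss = meta_loss))
}

# Lawson-Hanson style active-set non-negative least squares;
# the first `free` columns are unconstrained.
nnls_fit <- function(A, b, free = 0L, tol = 1e-10) {
  p <- ncol(A)
  passive <- c(rep(TRUE, free), rep(FALSE, p - free))
  x <- numeric(p)
  for (outer in seq_len(10 * p + 10)) {
    wgrad <- drop(crossprod(A, b - A %*% x))
    cand <- which(!passive & wgrad > tol)
    if (!length(cand)) break
    passive[cand[which.max(wgrad[cand])]] <- TRUE
    repeat {
      z <- numeric(p)
      z[passive] <- drop(stats::lm.fit(A[, passive, drop = FALSE],
                                       b)$coefficients)
      z[is.na(z)] <- 0
      neg <- passive & z < -tol & seq_len(p) > free
      if (!any(neg)) {
        x <- z
        break
      }
      idx <- which(neg)
      alpha <- min(x[idx] / (x[idx] - z[idx]))
      x <- x + alpha * (z - x)
      passive[seq_len(p) > free & passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  setNames(x, colnames(A))
}
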