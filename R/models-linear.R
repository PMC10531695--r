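# Solvers for the intercept-augmented mixed-model / kernel-ridge systems.
# For lambda > 0 the joint MME solution with an unpenalized intercept is
# equivalent to solving [[M, 1], [1', 0]] [a; mu] = [y; 0] with M the n x n
# dual matrix; the constraint 1'a = 0 falls out of the intercept equation.
solve_augmented <- function(M, y) {
  n <- length(y)
  # rescale the dual block so the bordered system stays well conditioned
  # even under extreme shrinkage (M ~ lambda I with huge lambda)
  s <- max(mean(abs(diag(M))), .Machine$double.xmin)
  jitter <- 0
  for (esc in 0:6) {
    A <- rbind(cbind(M / s + diag(jitter, n), 1), c(rep(1, n), 0))
    sol <- tryCatch(solve(A, c(y, 0)), error = function(e) NULL)
    if (!is.null(sol) && all(is.finite(sol)))
      return(list(a = sol[seq_len(n)] / s, mu = sol[n + 1],
                  jitter = jitter * s))
    jitter <- if (jitter == 0) 1e-10 else jitter * 100
  }
  abort("singular mixed-model system after regularization")
}

#' Ridge-regression BLUP of marker effects (rrBLUP)
#'
#' Solves the intercept-augmented mixed-model equations
#' \deqn{[[1'1, 1'X], [X'1, X'X + \lambda I]] [\mu; g] = [1'y; X'y]}
#' with shrinkage \eqn{\lambda = \sigma_e^2/\sigma_g^2}. When `lambda` is
#' not supplied it is estimated by spectral REML on the marker-derived
#' relationship matrix and mapped back to the marker scale. The system is
#' solved in its n x n dual form, so panels with many more markers than
#' genotypes cost only one n x n solve. GEBV = X g-hat.
#'
#' @param y Phenotype vector.
#' @param X Complete coded marker matrix (n x p), (-1, 0, 1) scale.
#' @param lambda Optional positive shrinkage on the marker scale.
#' @param intercept Estimate mu jointly (default) or fix it at 0.
#' @return A `gs_fit` with marker effects, GEBVs and variance components
#'   (when REML ran).
#' @export
fit_rrblup <- function(y, X, lambda = NULL, intercept = TRUE) {
  assert_that(is.matrix(X) && !anyNA(X) && nrow(X) == length(y),
              "X must be complete and match y")
  vc <- NULL
  XXt <- tcrossprod(X)
  if (is.null(lambda)) {
    cscale <- mean(diag(XXt))
    vc <- estimate_variance_components(y, XXt / cscale)
    lambda <- cscale * vc$lambda
  }
  assert_that(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  if (intercept) {
    sol <- solve_augmented(XXt + diag(lambda, nrow(XXt)), y)
    a <- sol$a
    mu <- sol$mu
  } else {
    a <- tryCatch(solve(XXt + diag(lambda, nrow(XXt)), y),
                  error = function(e)
                    abort("singular mixed-model system after regularization"))
    mu <- 0
  }
  g <- drop(crossprod(X, a))
  names(g) <- colnames(X)
  gebv <- drop(X %*% g)
  names(gebv) <- rownames(X)
  new_gs_fit("rrblup", y, gebv, mu,
             marker_effects = g, vc = vc,
             regularization = list(lambda = lambda),
             training_meta = list(dual = TRUE))
}

#' Genomic BLUP of genotype values (gBLUP)
#'
#' Best linear unbiased prediction of genetic values u with Var(u) =
#' G sigma2_u: u-hat = sigma2_u G V^-1 (y - 1 mu-hat), V = G sigma2_u +
#' I sigma2_e, with mu-hat the GLS mean. Variance components come from
#' spectral REML on G unless the ratio `lambda` = sigma2_e / sigma2_u is
#' supplied. GEBV = u-hat.
#'
#' @param y Phenotype vector.
#' @param G Genomic relationship matrix (PSD) from [build_grm()].
#' @param lambda Optional ratio sigma2_e / sigma2_u.
#' @return A `gs_fit`; `training_meta$dual_coef` holds V^-1 residuals scaled
#'   for prediction of new genotypes from their relationship rows.
#' @export
fit_gblup <- function(y, G, lambda = NULL) {
  assert_that(is.matrix(G) && nrow(G) == length(y), "G must match y")
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(abs(G))) abort("G is not positive semidefinite")
  vc <- NULL
  if (is.null(lambda)) {
    vc <- estimate_variance_components(y, G)
    lambda <- vc$lambda
  }
  assert_that(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  sol <- solve_augmented(G + diag(lambda, nrow(G)), y)
  u <- drop(G %*% sol$a)
  names(u) <- rownames(G)
  new_gs_fit("gblup", y, u, sol$mu,
             vc = vc, regularization = list(lambda = lambda),
             training_meta = list(dual_coef = sol$a))
}

#' Kernel ridge regression in an RKHS
#'
#' alpha-hat = (K + lambda I)^-1 (y - 1 mu-hat) with the Gaussian (or any
#' PSD) kernel K; GEBV = K alpha-hat. lambda is estimated by REML on K
#' (the RKHS/gBLUP duality) unless supplied. lambda trades goodness of fit
#' against model complexity: small values interpolate, large values shrink
#' to the mean.
#'
#' @param y Phenotype vector.
#' @param K Kernel matrix from [build_gaussian_kernel()] (or a GRM).
#' @param lambda Optional positive regularization.
#' @return A `gs_fit`; `training_meta$alpha` holds the kernel expansion
#'   coefficients used for prediction.
#' @export
fit_rkhs <- function(y, K, lambda = NULL) {
  assert_that(is.matrix(K) && nrow(K) == length(y), "K must match y")
  vc <- NULL
  if (is.null(lambda)) {
    vc <- estimate_variance_components(y, K)
    lambda <- vc$lambda
  }
  assert_that(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  sol <- solve_augmented(K + diag(lambda, nrow(K)), y)
  gebv <- drop(K %*% sol$a)
  names(gebv) <- rownames(K)
  new_gs_fit("rkhs", y, gebv, sol$mu,
             vc = vc, regularization = list(lambda = lambda),
             training_meta = list(alpha = sol$a))
}

#' L1-penalized marker regression (LASSO)
#'
#' Minimizes (1/2n) ||y - mu - X beta||^2 + lambda ||beta||_1 by cyclic
#' coordinate descent with soft-thresholding, the standard solver for the
#' L1 objective. Columns are centered internally (mu = mean y). When
#' `lambda` is not supplied, a log-spaced path from lambda_max =
#' max |X'(y - ybar)| / n downwards is fitted with warm starts and the
#' value minimizing inner cross-validated MSE is chosen.
#'
#' @param y Phenotype vector.
#' @param X Complete coded marker matrix.
#' @param lambda Optional penalty; 0 gives the unpenalized least-squares
#'   limit (only sensible for n > p).
#' @param cv_folds Inner CV folds for the path search (default 10).
#' @param n_lambda,lambda_min_ratio Path resolution and lower end relative
#'   to lambda_max.
#' @param tol,max_sweeps Convergence tolerance (largest weighted squared
#'   coefficient move per sweep, relative to the phenotypic variance --
#'   the glmnet criterion) and the sweep cap (exceeding it is an error
#'   with diagnostics).
#' @param seed Seed for the CV fold assignment.
#' @return A `gs_fit` with sparse marker effects; `training_meta` records
#'   the path, CV curve and sweep counts.
#' @export
fit_lasso <- function(y, X, lambda = NULL, cv_folds = 10, n_lambda = 20,
                      lambda_min_ratio = 0.05, tol = 1e-7,
                      max_sweeps = 20000, seed = 1) {
  assert_that(is.matrix(X) && !anyNA(X) && nrow(X) == length(y),
              "X must be complete and match y")
  n <- nrow(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  mu <- mean(y)
  yc <- y - mu
  cv_mse <- NULL
  path <- NULL
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(Xc, yc))) / n
    path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = n_lambda))
    folds <- local_rng(seed_stream(seed, "lasso-cv"),
                       sample(rep_len(seq_len(cv_folds), n)))
    err <- matrix(NA_real_, cv_folds, n_lambda)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      # the path search stops once the active set saturates (the CV curve
      # is already rising there)
      fitp <- lasso_path(yc[tr], Xc[tr, , drop = FALSE], path,
                         tol = tol, max_sweeps = max_sweeps,
                         dfmax = sum(tr) - 1)
      pred <- Xc[!tr, , drop = FALSE] %*% fitp$beta
      err[f, ] <- colMeans((yc[!tr] - pred)^2)
    }
    cv_mse <- colMeans(err)
    lambda <- path[which.min(cv_mse)]
  }
  assert_that(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  fit <- lasso_path(yc, Xc, lambda, tol, max_sweeps)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  gebv <- drop(Xc %*% beta)
  names(gebv) <- rownames(X)
  new_gs_fit("lasso", y, gebv, mu,
             marker_effects = beta,
             regularization = list(lambda = lambda),
             training_meta = list(path = path, cv_mse = cv_mse,
                                  sweeps = fit$sweeps,
                                  x_center = xbar))
}

# Cyclic coordinate descent over a decreasing lambda sequence with warm
# starts and an active-set strategy: converge on the working set, then one
# vectorized KKT pass over all predictors recruits violators. Inputs are
# centered; returns p x length(lambdas) coefficient matrix.
lasso_path <- function(yc, Xc, lambdas, tol, max_sweeps, dfmax = Inf) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  ssq <- colSums(Xc^2) / n
  thresh <- tol * max(stats::var(yc), .Machine$double.eps)
  beta <- numeric(p)
  out <- matrix(0, p, length(lambdas))
  sweeps_used <- integer(length(lambdas))
  r <- yc
  active <- integer(0)
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    sweeps <- 0L
    repeat {
      # converge cyclic descent on the working set
      repeat {
        sweeps <- sweeps + 1L
        if (sweeps > max_sweeps)
          abort(sprintf(
            "LASSO coordinate descent did not converge at lambda = %.4g within %d sweeps",
            lam, max_sweeps))
        delta_max <- 0
        for (j in active) {
          if (ssq[j] == 0) next
          bj <- beta[j]
          rho <- sum(Xc[, j] * r) / n + ssq[j] * bj
          bnew <- sign(rho) * max(abs(rho) - lam, 0) / ssq[j]
          if (bnew != bj) {
            r <- r - Xc[, j] * (bnew - bj)
            delta_max <- max(delta_max, ssq[j] * (bnew - bj)^2)
            beta[j] <- bnew
          }
        }
        if (delta_max < thresh) break
      }
      # vectorized KKT check over all predictors
      grad <- drop(crossprod(Xc, r)) / n
      viol <- which(beta == 0 & abs(grad) > lam + 1e-12 & ssq > 0)
      viol <- setdiff(viol, active)
      if (!length(viol)) break
      active <- union(active, viol)
    }
    active <- which(beta != 0) # shrink working set for the next lambda
    out[, li] <- beta
    sweeps_used[li] <- sweeps
    if (length(active) >= dfmax && li < length(lambdas)) {
      # saturated: carry the current solution through the remaining path
      out[, (li + 1):length(lambdas)] <- beta
      break
    }
  }
  list(beta = out, sweeps = sweeps_used)
}
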