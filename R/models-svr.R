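#' Epsilon-insensitive support vector regression in the dual
#'
#' Kernel SVR with the epsilon-insensitive loss: residuals smaller than
#' epsilon cost nothing, larger ones cost linearly, capped by the box
#' constraint C. Solved in the dual over beta_i = alpha_i - alpha_i* in
#' [-C, C] with sum(beta) = 0: maximize
#' -1/2 beta' K beta + beta' y - epsilon ||beta||_1, by pairwise analytic
#' coordinate ascent (an SMO-style solver: each step optimizes one pair
#' exactly along the equality constraint, handling the three smooth
#' segments of the L1 term). Genotypes with |beta_i| > 0 are the support
#' vectors; prediction is the kernel expansion over them plus a bias. When
#' the tube leaves the bias non-unique (no free support vectors), the bias
#' is the midrange of y, a deterministic tie rule.
#'
#' @param y Phenotype vector.
#' @param K PSD kernel matrix.
#' @param epsilon Tube half-width (>= 0); default 0.1 sd(y), keeping the
#'   tube proportionate to the trait scale.
#' @param C Box constraint (> 0); default sd(y).
#' @param tol Minimum objective improvement per pass; below it the solver
#'   stops.
#' @param max_passes Pass cap; exceeding it without converging is an error.
#' @param seed Seed for the pair sweep order.
#' @return A `gs_fit`; `training_meta` holds `beta` (dual coefficients),
#'   `n_support` and the final dual objective.
#' @export
fit_svr <- function(y, K, epsilon = NULL, C = NULL, tol = 1e-8,
                    max_passes = 2000, seed = 1) {
  assert_that(is.matrix(K) && nrow(K) == length(y), "K must match y")
  if (is.null(epsilon)) epsilon <- 0.1 * sd(y)
  if (is.null(C)) C <- sd(y)
  assert_that(is.numeric(epsilon) && epsilon >= 0, "epsilon must be >= 0")
  assert_that(is.numeric(C) && C > 0, "C must be > 0")
  n <- length(y)
  beta <- numeric(n)
  Kbeta <- numeric(n)
  obj <- function() -0.5 * sum(beta * Kbeta) + sum(beta * y) -
    epsilon * sum(abs(beta))
  # exact maximizer for the pair (i, j) with beta_i + beta_j fixed at s
  pair_update <- function(i, j) {
    s <- beta[i] + beta[j]
    qi <- Kbeta[i] - K[i, i] * beta[i] - K[i, j] * beta[j]
    qj <- Kbeta[j] - K[i, j] * beta[i] - K[j, j] * beta[j]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    lo <- max(-C, s - C)
    hi <- min(C, s + C)
    if (lo > hi) return(FALSE)
    # d/dt of smooth part: -(eta t - K[j,j] s + K[i,j] s) + (y_i - y_j) - qi + qj
    base <- (K[j, j] - K[i, j]) * s + (y[i] - y[j]) - qi + qj
    w <- function(t) {
      -0.5 * (K[i, i] * t^2 + K[j, j] * (s - t)^2 + 2 * K[i, j] * t * (s - t)) +
        t * y[i] + (s - t) * y[j] - t * qi - (s - t) * qj -
        epsilon * (abs(t) + abs(s - t))
    }
    cands <- c(lo, hi, 0, s)
    for (sg_t in c(-1, 1)) for (sg_u in c(-1, 1)) {
      # segment where sign(t) = sg_t, sign(s - t) = sg_u
      grad0 <- base - epsilon * sg_t + epsilon * sg_u
      t_star <- if (eta > 1e-12) grad0 / eta else NA_real_
      if (is.finite(t_star)) cands <- c(cands, t_star)
    }
    cands <- unique(pmin(pmax(cands, lo), hi))
    vals <- vapply(cands, w, numeric(1))
    t_new <- cands[which.max(vals)]
    if (abs(t_new - beta[i]) < 1e-14) return(FALSE)
    db_i <- t_new - beta[i]
    db_j <- (s - t_new) - beta[j]
    Kbeta <<- Kbeta + K[, i] * db_i + K[, j] * db_j
    beta[i] <<- t_new
    beta[j] <<- s - t_new
    TRUE
  }
  local_rng(seed_stream(seed, "svr"), {
    prev <- obj()
    converged <- FALSE
    for (pass in seq_len(max_passes)) {
      ord <- sample.int(n)
      for (k in seq_len(n)) {
        i <- ord[k]
        j <- ord[if (k == n) 1 else k + 1]
        if (i != j) pair_update(i, j)
      }
      cur <- obj()
      if (cur - prev < tol) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    if (!converged)
      abort("SVR dual solver stagnated beyond the pass cap")
  })
  sv <- abs(beta) > 1e-8
  free <- sv & abs(beta) < C - 1e-8
  bias <- if (any(free)) {
    mean(ifelse(beta[free] > 0,
                y[free] - Kbeta[free] - epsilon,
                y[free] - Kbeta[free] + epsilon))
  } else {
    (max(y) + min(y)) / 2 # tube tie rule
  }
  gebv <- Kbeta # kernel expansion; bias kept as the fit intercept
  names(gebv) <- rownames(K)
  names(beta) <- rownames(K)
  new_gs_fit("svm", y, gebv, bias,
             regularization = list(epsilon = epsilon, C = C),
             training_meta = list(beta = beta, n_support = sum(sv),
                                  dual_objective = -0.5 * sum(beta * Kbeta) +
                                    sum(beta * y) - epsilon * sum(abs(beta))))
}
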