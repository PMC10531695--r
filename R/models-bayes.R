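#' Bayesian ridge regression of marker effects (Gibbs sampler)
#'
#' Whole-genome regression y = 1 mu + X alpha + e with a Gaussian prior
#' alpha_j ~ N(0, sigma2_alpha) and scaled-inverse-chi-square priors on both
#' variances -- the ridge-type Bayesian shrinkage model that spreads small
#' effects over all SNPs. The sampler works in the eigenbasis of the
#' centered marker matrix (one thin SVD up front): the rotated effect
#' coordinates are conditionally independent Gaussians, the null-space norm
#' is drawn as a chi-square, and every sweep costs O(n), so long chains are
#' cheap and exactly reproducible under the seed.
#'
#' Per-marker summaries include the posterior mean effect and a posterior
#' sign probability P(alpha_j > 0 | y) (normal approximation from the
#' posterior mean and variance), the package's summary of the per-marker
#' null hypothesis test alpha_j = 0.
#'
#' @param y Phenotype vector.
#' @param X Complete coded marker matrix.
#' @param n_iter,burn_in Chain length and discarded prefix.
#' @param seed Chain seed.
#' @param priors List with `nu_e`, `s2_e`, `nu_a`, `s2_a` (degrees of
#'   freedom and scale of the two scaled-inv-chi-square priors); defaults
#'   split the phenotypic variance evenly between signal and noise.
#' @param fixed_variances Optional list(sigma2_e =, sigma2_alpha =) to run
#'   the conjugate fixed-variance chain (used for validation against the
#'   closed-form ridge posterior).
#' @return A `gs_fit` with posterior-mean marker effects, GEBVs, posterior
#'   sign probabilities (`training_meta$sign_prob`) and variance-component
#'   posterior means.
#' @export
fit_bayesian_ridge <- function(y, X, n_iter = 3000, burn_in = 1000,
                               seed = 1, priors = NULL,
                               fixed_variances = NULL) {
  assert_that(is.matrix(X) && !anyNA(X) && nrow(X) == length(y),
              "X must be complete and match y")
  assert_that(n_iter > burn_in, "n_iter must exceed burn_in")
  n <- nrow(X)
  p <- ncol(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  sv <- svd(Xc, nu = min(n, p), nv = min(n, p))
  pos <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  r <- length(d)
  uy <- drop(crossprod(U, y)) # U'1 = 0 (columns of Xc are centered)
  if (is.null(priors)) {
    vy <- stats::var(y)
    msx <- sum(apply(Xc, 2, stats::var))
    priors <- list(nu_e = 4, s2_e = 0.5 * vy,
                   nu_a = 4, s2_a = 0.5 * vy / max(msx, 1e-8))
  }
  fixed <- !is.null(fixed_variances)
  s2e <- if (fixed) fixed_variances$sigma2_e else stats::var(y) / 2
  s2a <- if (fixed) fixed_variances$sigma2_alpha else
    stats::var(y) / (2 * max(sum(d^2) / n, 1e-8))
  keep <- n_iter - burn_in
  local_rng(seed_stream(seed, "gibbs"), {
    beta <- numeric(r)
    gamma2 <- 0
    sum_beta <- numeric(r)
    sum_bb <- matrix(0, r, r)
    sum_s2e <- sum_s2a <- sum_mu <- 0
    for (it in seq_len(n_iter)) {
      lam <- s2e / s2a
      denom <- d^2 + lam
      beta <- rnorm(r, d * uy / denom, sqrt(s2e / denom))
      gamma2 <- if (p > r) s2a * rchisq(1, p - r) else 0
      mu <- rnorm(1, mean(y), sqrt(s2e / n))
      if (!fixed) {
        resid <- y - mu - drop(U %*% (d * beta))
        ssr <- sum(resid^2)
        s2e <- (ssr + priors$nu_e * priors$s2_e) /
          rchisq(1, n + priors$nu_e)
        ssa <- sum(beta^2) + gamma2
        s2a <- (ssa + priors$nu_a * priors$s2_a) /
          rchisq(1, p + priors$nu_a)
        if (!is.finite(s2e) || !is.finite(s2a))
          abort("divergent chain: non-finite variance draw")
      }
      if (it > burn_in) {
        sum_beta <- sum_beta + beta
        sum_bb <- sum_bb + tcrossprod(beta)
        sum_s2e <- sum_s2e + s2e
        sum_s2a <- sum_s2a + s2a
        sum_mu <- sum_mu + mu
      }
    }
    beta_mean <- sum_beta / keep
    beta_cov <- sum_bb / keep - tcrossprod(beta_mean)
    mu_mean <- sum_mu / keep
    s2e_mean <- if (fixed) s2e else sum_s2e / keep
    s2a_mean <- if (fixed) s2a else sum_s2a / keep
    alpha <- drop(V %*% beta_mean)
    names(alpha) <- colnames(X)
    # posterior sd of alpha_j: rotated part plus prior-only null-space part
    v_norm2 <- rowSums(V^2)
    var_alpha <- rowSums((V %*% beta_cov) * V) +
      s2a_mean * pmax(1 - v_norm2, 0)
    sign_prob <- pnorm(alpha / sqrt(pmax(var_alpha, 1e-300)))
    gebv <- drop(Xc %*% alpha)
    names(gebv) <- rownames(X)
    s2a_genic <- s2a_mean * sum(d^2) / n # marker variance to genomic scale
    vc <- structure(list(sigma2_a = s2a_genic, sigma2_e = s2e_mean,
                         h2 = s2a_genic / (s2a_genic + s2e_mean),
                         lambda = s2e_mean / s2a_genic),
                    class = "variance_components")
    new_gs_fit("bglr", y, gebv, mu_mean,
               marker_effects = alpha, vc = vc,
               regularization = list(sigma2_alpha = s2a_mean,
                                     lambda = s2e_mean / s2a_mean),
               training_meta = list(n_iter = n_iter, burn_in = burn_in,
                                    seed = seed, sign_prob = sign_prob,
                                    x_center = xbar,
                                    fixed_variances = fixed))
  })
}
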