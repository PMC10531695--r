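#' REML variance components for a single-kinship mixed model
#'
#' Fits y = 1 mu + g + e with g ~ N(0, K sigma2_a), e ~ N(0, I sigma2_e) by
#' restricted maximum likelihood. A single eigendecomposition of K turns the
#' restricted likelihood into a cheap one-dimensional profile over the ratio
#' lambda = sigma2_e / sigma2_a, maximized on a log-spaced grid and refined
#' by golden-section search. SNP heritability h2 = sigma2_a / (sigma2_a +
#' sigma2_e) = 1 / (1 + lambda) follows directly.
#'
#' @param y Phenotype vector with positive variance.
#' @param K Symmetric PSD kinship/kernel matrix matching `y`.
#' @param lambda_grid Log10 bounds and resolution of the profile grid.
#' @return List of class `variance_components`: `sigma2_a`, `sigma2_e`,
#'   `h2`, `lambda`, `loglik`, `boundary` (TRUE when the optimum sits on the
#'   grid edge) and `identifiable` (FALSE when K is essentially the
#'   identity, where the two components cannot be separated).
#' @export
estimate_variance_components <- function(y, K,
                                         lambda_grid = c(-6, 6, 121)) {
  assert_that(is.numeric(y) && length(y) == nrow(K),
              "y length must match K")
  assert_that(max(abs(K - t(K))) < 1e-6, "K must be symmetric")
  if (stats::var(y) <= 0) abort("y has zero variance")
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  if (diff(range(evals)) < 1e-8 * max(1, max(evals)))
    warn("K has (near-)equal eigenvalues: sigma2_a and sigma2_e are not separately identifiable; boundary estimate returned")
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  restr_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (evals + lam)
    xhx <- sum(w * xt^2)
    xhy <- sum(w * xt * yt)
    yhy <- sum(w * yt^2)
    ypy <- yhy - xhy^2 / xhx
    if (ypy <= 0) return(-Inf)
    s2a <- ypy / (n - 1)
    -0.5 * ((n - 1) * log(s2a) + sum(log(evals + lam)) + log(xhx) + (n - 1))
  }
  grid <- seq(lambda_grid[1] * log(10), lambda_grid[2] * log(10),
              length.out = lambda_grid[3])
  ll <- vapply(grid, restr_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(restr_ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  lam <- exp(opt$maximum)
  w <- 1 / (evals + lam)
  xhx <- sum(w * xt^2)
  xhy <- sum(w * xt * yt)
  ypy <- sum(w * yt^2) - xhy^2 / xhx
  s2a <- ypy / (n - 1)
  structure(list(
    sigma2_a = s2a,
    sigma2_e = lam * s2a,
    h2 = 1 / (1 + lam),
    lambda = lam,
    loglik = opt$objective,
    boundary = i %in% c(1L, length(grid)),
    identifiable = diff(range(evals)) >= 1e-8 * max(1, max(evals))
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML variance components: sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f (lambda = %.4g)\n",
              x$sigma2_a, x$sigma2_e, x$h2, x$lambda))
  invisible(x)
}

#' SNP heritability from variance components
#'
#' h2 = sigma2_a / (sigma2_a + sigma2_e), the ratio of additive genomic to
#' total (genomic + residual) variance.
#'
#' @param vc A `variance_components` object, or a list/vector with elements
#'   `sigma2_a` and `sigma2_e`.
#' @return Heritability in [0, 1].
#' @export
#' @examples
#' snp_heritability(list(sigma2_a = 57.11, sigma2_e = 69.81))
snp_heritability <- function(vc) {
  s2a <- vc[["sigma2_a"]]
  s2e <- vc[["sigma2_e"]]
  assert_that(is.numeric(s2a) && is.numeric(s2e) && s2a >= 0 && s2e >= 0,
              "variance components must be nonnegative numbers")
  if (s2a + s2e <= 0) abort("both variance components are zero")
  s2a / (s2a + s2e)
}
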