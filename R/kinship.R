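#' Genomic relationship matrix (GRM)
#'
#' Allele-frequency-scaled cross-product G = W W' / (2 * sum p_k (1 - p_k)),
#' with W the dosage matrix column-centered at 2 p_k and p_k the
#' alternate-allele frequency of marker k. Accepts either raw dosages
#' (0..2) or the centered (-1, 0, 1) coding; the centering makes the two
#' equivalent. Symmetric and positive semidefinite by construction; under
#' Hardy-Weinberg proportions the diagonal averages about 1.
#'
#' @param M Complete genotype matrix: dosages in [0, 2] or coded in [-1, 1].
#' @return Symmetric n x n matrix with genotype ids as dimnames and
#'   attributes `construction = "GRM"` and `scaling` (the denominator).
#' @export
build_grm <- function(M) {
  assert_that(is.matrix(M) && !anyNA(M), "M must be a complete matrix")
  assert_that(ncol(M) >= 2, "need at least two markers")
  # detect coding: coded matrices live in [-1, 1], dosages in [0, 2]
  p <- if (min(M) < 0) (colMeans(M) + 1) / 2 else colMeans(M) / 2
  W <- sweep(M, 2, colMeans(M))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= .Machine$double.eps * ncol(M))
    abort("all markers are monomorphic; GRM scaling denominator is zero")
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(G, construction = "GRM", scaling = denom)
}

#' Gaussian kernel matrix on marker profiles
#'
#' K_ij = exp(-d_ij^2 / (2 theta^2)) with d the Euclidean distance between
#' the column-centered coded rows of two genotypes. The default bandwidth is
#' the median heuristic: theta = median off-diagonal distance. Entries lie
#' in (0, 1] with a unit diagonal.
#'
#' @param M Complete coded (or dosage) matrix; columns are centered before
#'   distances are taken so kernel and GRM share inputs.
#' @param bandwidth Positive scalar theta, or `"median"` for the heuristic.
#' @return Symmetric kernel matrix with attributes `construction =
#'   "gaussian_kernel"` and `bandwidth`.
#' @export
build_gaussian_kernel <- function(M, bandwidth = "median") {
  assert_that(is.matrix(M) && !anyNA(M), "M must be a complete matrix")
  W <- sweep(M, 2, colMeans(M))
  D <- as.matrix(stats::dist(W))
  if (identical(bandwidth, "median")) {
    bandwidth <- median(D[upper.tri(D)])
    if (!is.finite(bandwidth) || bandwidth <= 0)
      bandwidth <- 1 # degenerate: all rows identical
  }
  assert_that(is.numeric(bandwidth) && bandwidth > 0,
              "bandwidth must be positive or \"median\"")
  K <- exp(-D^2 / (2 * bandwidth^2))
  dimnames(K) <- list(rownames(M), rownames(M))
  structure(K, construction = "gaussian_kernel", bandwidth = bandwidth)
}

#' Jitter-regularized matrix inverse
#'
#' Inverts K + jitter * I, escalating the jitter tenfold (up to
#' `max_escalations` times) until the Cholesky factorization succeeds.
#' Every escalation is recorded on the result so downstream reports can log
#' that the relationship matrix needed regularization.
#'
#' @param K Square symmetric matrix.
#' @param jitter Initial ridge added to the diagonal (default 1e-6; 0 tries
#'   a plain inverse first).
#' @param max_escalations Maximum number of tenfold escalations.
#' @return The inverse matrix with attributes `jitter_used` and
#'   `escalations`.
#' @export
regularized_inverse <- function(K, jitter = 1e-6, max_escalations = 10L) {
  assert_that(is.matrix(K) && nrow(K) == ncol(K), "K must be square")
  assert_that(max(abs(K - t(K))) < 1e-8, "K must be symmetric")
  j <- jitter
  for (esc in 0:max_escalations) {
    Kj <- K + diag(j, nrow(K))
    inv <- tryCatch(chol2inv(chol(Kj)), error = function(e) NULL)
    if (!is.null(inv) && all(is.finite(inv))) {
      dimnames(inv) <- dimnames(K)
      return(structure(inv, jitter_used = j, escalations = esc))
    }
    j <- if (j == 0) 1e-8 else j * 10
  }
  abort("matrix not invertible after jitter escalation")
}
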