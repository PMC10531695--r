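test_that("GRM matches the hand-computed single-marker case", {
  # dosages (0, 2) at one informative marker (p = 0.5): W = (-1, +1),
  # denominator 2 * 0.25 = 0.5 -> G = [[2, -2], [-2, 2]]; the second,
  # monomorphic marker contributes nothing to W or the denominator
  M1 <- cbind(m1 = c(0, 2), m2 = c(0, 0))
  G1 <- build_grm(M1)
  expect_equal(unname(G1[, ]), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # two copies of the marker double numerator and denominator alike
  M2 <- cbind(m1 = c(0, 2), m2 = c(0, 2))
  expect_equal(unname(build_grm(M2)[, ]), unname(G1[, ]), tolerance = 1e-12)
})

test_that("duplicate genotypes have identical GRM rows", {
  M <- random_coded(6, 40, seed = 3) + 1
  M[2, ] <- M[1, ]
  G <- build_grm(M)
  expect_equal(G[1, ], G[2, ])
  expect_equal(G[1, 2], G[1, 1])
})

test_that("GRM diagonal averages near 1 under Hardy-Weinberg sampling", {
  set.seed(10)
  p <- runif(2000, 0.1, 0.5)
  M <- sapply(p, function(pk) rbinom(300, 2, pk))
  G <- build_grm(M)
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("GRM is the same on dosage and centered coding and permutes", {
  pop <- small_population(n = 30, m = 80, seed = 12)
  G1 <- build_grm(pop$genotypes)
  G2 <- build_grm(pop$coded)
  expect_equal(G1[, ], G2[, ], tolerance = 1e-10)
  perm <- sample(nrow(pop$coded))
  Gp <- build_grm(pop$coded[perm, ])
  expect_equal(Gp[, ], G1[perm, perm], tolerance = 1e-10)
  expect_error(build_grm(matrix(0, 4, 3)), "monomorphic")
})

test_that("Gaussian kernel matches plug-in values and bounds", {
  # rows at Euclidean distance 2: d^2 = 4, theta^2 = 2 -> exp(-1)
  M <- rbind(a = c(0, 0), b = c(2, 0))
  K <- build_gaussian_kernel(M, bandwidth = sqrt(2))
  expect_equal(K["a", "b"], exp(-1), tolerance = 1e-12)
  expect_equal(diag(K), c(a = 1, b = 1))
  # identical rows -> kernel 1
  M2 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, -1, 1))
  K2 <- build_gaussian_kernel(M2, bandwidth = 1)
  expect_equal(K2["a", "b"], 1)
  expect_true(all(K2 > 0 & K2 <= 1))
  # flat-kernel limit at enormous bandwidth
  pop <- small_population(n = 20, m = 50, seed = 13)
  D <- as.matrix(dist(sweep(pop$coded, 2, colMeans(pop$coded))))
  K3 <- build_gaussian_kernel(pop$coded, bandwidth = 1e6 * max(D))
  expect_true(all(abs(K3 - 1) < 1e-6))
  expect_error(build_gaussian_kernel(pop$coded, bandwidth = -1),
               "bandwidth")
})

test_that("median-heuristic bandwidth is the median off-diagonal distance", {
  pop <- small_population(n = 25, m = 60, seed = 14)
  K <- build_gaussian_kernel(pop$coded)
  W <- sweep(pop$coded, 2, colMeans(pop$coded))
  D <- as.matrix(dist(W))
  expect_equal(attr(K, "bandwidth"), median(D[upper.tri(D)]))
})

test_that("regularized inverse handles identity, PSD and singular input", {
  I5 <- diag(5)
  inv <- regularized_inverse(I5, jitter = 0)
  expect_equal(inv[, ], I5)
  expect_equal(attr(inv, "escalations"), 0)

  set.seed(3)
  A <- crossprod(matrix(rnorm(100), 20, 5)) + diag(0.5, 5)
  invA <- regularized_inverse(A, jitter = 0)
  expect_true(max(abs(A %*% invA - diag(5))) < 1e-8)

  # four copies of one genotype: the relationship matrix is exactly
  # rank one, the plain Cholesky fails, and inversion succeeds only after
  # jitter escalation, which is recorded
  G <- tcrossprod(rep(1, 4))
  invG <- regularized_inverse(G, jitter = 0)
  expect_gt(attr(invG, "escalations"), 0)
  expect_error(regularized_inverse(matrix(1:6, 2, 3)), "square")
})
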