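test_that("rrBLUP reproduces the worked mixed-model fixture", {
  X <- matrix(c(1, 0, 0, 1, -1, 1), 3, 2, byrow = TRUE)
  y <- c(1, 0, -1)
  fit <- fit_rrblup(y, X, lambda = 1, intercept = FALSE)
  # independent dense-solve oracle
  oracle <- solve(crossprod(X) + diag(2), crossprod(X, y))
  expect_equal(unname(fit$marker_effects), drop(oracle), tolerance = 1e-10)
  expect_equal(unname(fit$marker_effects), c(0.625, -0.125),
               tolerance = 1e-10)
  expect_equal(unname(fit$gebv), c(0.625, -0.125, -0.75), tolerance = 1e-10)
})

test_that("rrBLUP shrinkage limits behave", {
  set.seed(41)
  X <- random_coded(30, 20, seed = 41)
  y <- rnorm(30)
  heavy <- fit_rrblup(y, X, lambda = 1e8)
  expect_lte(max(abs(heavy$marker_effects)), 1e-6)
  # square invertible X, lambda -> 0: fit interpolates the phenotype
  Xs <- matrix(rnorm(64), 8, 8)
  ys <- rnorm(8)
  lo <- fit_rrblup(ys, Xs, lambda = 1e-10)
  expect_equal(unname(lo$gebv + lo$intercept), ys, tolerance = 1e-6)
})

test_that("rrBLUP effect norms shrink monotonically in lambda", {
  set.seed(42)
  X <- random_coded(40, 60, seed = 42)
  y <- rnorm(40) + X[, 1]
  norms <- sapply(c(0.1, 1, 10, 100), function(l)
    sum(fit_rrblup(y, X, lambda = l)$marker_effects^2))
  expect_true(all(diff(norms) < 0))
})

test_that("rrBLUP and gBLUP are duals under the GRM mapping", {
  set.seed(43)
  X <- random_coded(50, 200, seed = 43)
  y <- rnorm(50) + drop(X[, 1:10] %*% rnorm(10)) * 0.4
  cscale <- mean(diag(tcrossprod(X)))
  G <- tcrossprod(X) / cscale
  lamK <- 1.7
  rr <- fit_rrblup(y, X, lambda = cscale * lamK)
  gb <- fit_gblup(y, G, lambda = lamK)
  expect_lt(max(abs(rr$gebv - gb$gebv)), 1e-8)
  expect_equal(rr$intercept, gb$intercept, tolerance = 1e-8)
  # RKHS with the linear kernel reproduces gBLUP on the same G
  rk <- fit_rkhs(y, G, lambda = lamK)
  expect_lt(max(abs(rk$gebv - gb$gebv)), 1e-8)
})

test_that("gBLUP collapses to the mean when genetic variance vanishes", {
  set.seed(44)
  pop <- small_population(n = 40, m = 80, seed = 44)
  y <- level_trait(pop)
  G <- build_grm(pop$coded)
  fit <- fit_gblup(y, G[, ], lambda = 1e8) # sigma_u^2 -> 0 relative to noise
  expect_lt(max(abs(fit$gebv)), 1e-4 * sd(y))
})

test_that("duplicate individuals receive identical gBLUP GEBVs", {
  M <- random_coded(8, 50, seed = 45)
  M[2, ] <- M[1, ]
  G <- build_grm(M)
  set.seed(45)
  y <- rnorm(8)
  y[2] <- y[1]
  fit <- fit_gblup(y, G[, ], lambda = 0.5)
  expect_equal(fit$gebv[1], fit$gebv[2], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("RKHS solves the decoupled and 2x2 hand cases", {
  set.seed(46)
  y <- rnorm(10)
  fit <- fit_rkhs(y, diag(10), lambda = 2)
  expect_equal(unname(fit$gebv), (y - mean(y)) / 3, tolerance = 1e-10)

  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  yc <- c(1, -1)
  fit2 <- fit_rkhs(yc, K, lambda = 1)
  expect_equal(unname(fit2$training_meta$alpha), c(2 / 3, -2 / 3),
               tolerance = 1e-10)
  expect_equal(unname(fit2$gebv), c(1 / 3, -1 / 3), tolerance = 1e-10)

  # strictly PD kernel, lambda -> 0 interpolates centered y
  pop <- small_population(n = 25, m = 60, seed = 46)
  Kg <- build_gaussian_kernel(pop$coded)
  yy <- level_trait(pop)
  lo <- fit_rkhs(yy, Kg[, ], lambda = 1e-10)
  expect_equal(unname(lo$gebv + lo$intercept), unname(yy),
               tolerance = 1e-5)
})

test_that("deterministic fits are invariant to genotype permutation", {
  pop <- small_population(n = 30, m = 60, seed = 47)
  y <- level_trait(pop)
  X <- pop$coded
  fit <- fit_rrblup(y, X, lambda = 3)
  perm <- sample(nrow(X))
  fitp <- fit_rrblup(y[perm], X[perm, ], lambda = 3)
  expect_equal(unname(fitp$gebv), unname(fit$gebv[perm]), tolerance = 1e-8)
})

test_that("rrBLUP estimates its shrinkage by REML when not supplied", {
  cfg <- population_config(n_genotypes = 150, n_markers = 400, n_qtl = 80,
                           h2_low_n = 0.7, missing_rate = 0, seed = 48)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  y <- level_trait(list(genotypes = G, phenotypes = sim$phenotypes))
  fit <- fit_rrblup(y, G - 1)
  expect_false(is.null(fit$vc))
  expect_gt(fit$vc$h2, 0.3)
  expect_gt(cor(fit$gebv, sim$architecture$true_gebv[, "LN"]), 0.5)
})
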