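test_that("accuracy is the Pearson correlation with guards", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(1:5, -(1:5)), -1)
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_error(accuracy(1:5, rep(1, 5)), "zero variance")
  expect_error(accuracy(1:2, 1:2), "at least 3")
  # invariance to positive affine transforms
  set.seed(1)
  a <- rnorm(20)
  b <- rnorm(20)
  expect_equal(accuracy(a, b), accuracy(2 * a + 5, 0.1 * b - 3),
               tolerance = 1e-12)
})

test_that("learning-rate schedule hits its printed minimum", {
  s <- learning_rate_schedule(1, 9900)
  expect_equal(s$minimum, 0.01)
  expect_equal(s$alpha[1], 1) # j = 0 returns alpha0
  expect_true(all(diff(s$alpha) < 0))
  # alpha_j * (100 + j) is constant along the trace
  expect_equal(unique(round(s$alpha * (100 + s$j), 10)), 100)
  expect_error(learning_rate_schedule(0, 10), "alpha0")
})

test_that("bootstrap of the GEBV mean behaves like the CLT says", {
  const <- bootstrap_gebv_mean(rep(2, 30), n_boot = 200, seed = 1)
  expect_equal(const$upper - const$lower, 0)
  set.seed(2)
  x <- rnorm(400)
  bt <- bootstrap_gebv_mean(x, n_boot = 2000, seed = 3)
  expect_true(bt$lower <= mean(x) && mean(x) <= bt$upper)
  half <- (bt$upper - bt$lower) / 2
  expect_lt(abs(half - 1.96 / sqrt(400)), 0.3 * 1.96 / sqrt(400))
  expect_error(bootstrap_gebv_mean(x, n_boot = 50), "n_boot")
})

test_that("train-vs-test comparison reproduces the Welch statistic", {
  same <- compare_train_test_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(4)
  a <- rnorm(100)
  b <- rnorm(100) + 10
  expect_lt(compare_train_test_means(a, b)$p_value, 1e-6)
  # from-scratch Welch computation on the hand case
  g1 <- c(1, 2, 3)
  g2 <- c(1, 2, 3, 4)
  got <- compare_train_test_means(g1, g2)
  se <- sqrt(var(g1) / 3 + var(g2) / 4)
  expect_equal(got$t, (mean(g1) - mean(g2)) / se, tolerance = 1e-10)
})

test_that("cross-validation plans partition the genotypes", {
  ids <- sprintf("G%03d", 1:53)
  plan <- cv_plan(ids, outer_folds = 5, inner_folds = 10, seed = 2)
  expect_setequal(plan$assignment$genotype_id, ids)
  expect_equal(nrow(plan$assignment), length(ids)) # each id exactly once
  expect_true(all(table(plan$assignment$outer_fold) >= 10))
  expect_error(cv_plan(ids[1:5], outer_folds = 5), "too few")
})

test_that("noise-free phenotypes give near-perfect test accuracy", {
  # noise-free trait on a strongly linked causal-only panel: haplotype
  # sharing makes the genotype-to-value map low-dimensional, so rrBLUP
  # can recover it from the training folds
  cfg <- population_config(n_genotypes = 300, n_markers = 1000,
                           n_qtl = 1000, h2_low_n = 1, missing_rate = 0,
                           ld_block_len = 100, n_founders = 8,
                           n_subpops = 1, mutation_rate = 0.005,
                           seed = 101)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  plan <- cv_plan(rownames(G), outer_folds = 5, inner_folds = 5, seed = 3)
  rep <- run_nested_cv(sim$phenotypes, G * 1.0, "rrblup", plan)
  acc <- rep$accuracy_test[rep$n_level == "LN"]
  expect_gte(acc, 0.95)
})

test_that("permuted phenotypes have no predictive accuracy", {
  pop <- small_population(n = 80, m = 150, seed = 102, missing_rate = 0)
  plan <- cv_plan(rownames(pop$genotypes), outer_folds = 4,
                  inner_folds = 4, seed = 5)
  ph <- pop$phenotypes
  set.seed(6)
  accs <- replicate(20, {
    shuffled <- ph
    for (lev in c("LN", "HN")) {
      i <- shuffled$n_level == lev
      shuffled$NUE[i] <- sample(shuffled$NUE[i])
    }
    r <- run_nested_cv(shuffled, pop$genotypes, "rrblup", plan)
    mean(r$accuracy_test)
  })
  expect_lt(abs(mean(accs)), 0.1)
})

test_that("nested CV reports the Table-style columns per model and level", {
  pop <- small_population(n = 60, m = 120, seed = 103)
  plan <- cv_plan(rownames(pop$genotypes), outer_folds = 3,
                  inner_folds = 3, seed = 7)
  rep <- run_nested_cv(pop$phenotypes, pop$genotypes,
                       c("rrblup", "gblup", "rkhs"), plan)
  expect_equal(nrow(rep), 6L)
  expect_true(all(c("snp_h2", "vg", "ve", "gebv_mean_train",
                    "gebv_mean_test", "boot_gebv_mean", "accuracy_train",
                    "accuracy_test", "p_value", "signif") %in% names(rep)))
  expect_true(all(rep$snp_h2 >= 0 & rep$snp_h2 <= 1))
  expect_true(all(rep$boot_lower <= rep$boot_gebv_mean &
                    rep$boot_gebv_mean <= rep$boot_upper))
  expect_true(all(abs(rep$accuracy_test) <= 1, na.rm = TRUE))
  # deterministic under the same plan
  rep2 <- run_nested_cv(pop$phenotypes, pop$genotypes,
                        c("rrblup", "gblup", "rkhs"), plan)
  expect_equal(as.data.frame(rep), as.data.frame(rep2))
})

test_that("the literal two-CV mode runs behind the switch", {
  pop <- small_population(n = 60, m = 100, seed = 104)
  plan <- cv_plan(rownames(pop$genotypes), outer_folds = 3,
                  inner_folds = 4, seed = 8)
  rep <- run_nested_cv(pop$phenotypes, pop$genotypes, "rrblup", plan,
                       mode = "independent")
  expect_equal(nrow(rep), 2L)
  expect_true(all(is.finite(rep$accuracy_train)))
})
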