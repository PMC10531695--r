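test_that("config validation rejects impossible settings", {
  expect_error(population_config(maf_low = 0.4, maf_high = 0.2), "maf_low")
  expect_error(population_config(n_qtl = 100, n_markers = 50), "n_qtl")
  expect_error(population_config(h2_low_n = 1.2), "h2_low_n")
  expect_error(population_config(missing_rate = 1), "missing_rate")
  expect_error(population_config(genetic_corr_n_levels = -2), "genetic_corr")
})

test_that("genotype simulation is deterministic under the seed", {
  cfg <- population_config(n_genotypes = 40, n_markers = 100, seed = 7)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  cfg2 <- population_config(n_genotypes = 40, n_markers = 100, seed = 8)
  expect_false(identical(simulate_genotypes(cfg)[, ],
                         simulate_genotypes(cfg2)[, ]))
})

test_that("unlinked markers are uncorrelated (block length 1)", {
  cfg <- population_config(n_genotypes = 250, n_markers = 120,
                           n_subpops = 1, ld_block_len = 1,
                           missing_rate = 0, seed = 3)
  G <- simulate_genotypes(cfg)
  set.seed(1)
  pairs <- replicate(100, sample.int(ncol(G), 2))
  cors <- apply(pairs, 2, function(p) {
    a <- G[, p[1]]
    b <- G[, p[2]]
    if (sd(a) == 0 || sd(b) == 0) 0 else abs(cor(a, b))
  })
  expect_lte(mean(cors), 0.1)
})

test_that("markers within an LD block are positively correlated", {
  cfg <- population_config(n_genotypes = 250, n_markers = 100,
                           n_subpops = 1, ld_block_len = 10,
                           n_founders = 10, mutation_rate = 0,
                           missing_rate = 0, seed = 3)
  G <- simulate_genotypes(cfg)
  within <- sapply(seq(1, 91, by = 10), function(j) {
    a <- G[, j]; b <- G[, j + 1]
    if (sd(a) == 0 || sd(b) == 0) NA else cor(a, b)
  })
  expect_gt(mean(within, na.rm = TRUE), 0.2)
})

test_that("realized MAF matches an independent allele re-tally", {
  # a large founder pool keeps realized frequencies at the target up to
  # sampling noise only
  cfg <- population_config(n_genotypes = 200, n_markers = 300,
                           maf_low = 0.5, maf_high = 0.5, n_subpops = 1,
                           n_founders = 200, missing_rate = 0, seed = 5)
  G <- simulate_genotypes(cfg)
  # brute-force oracle: count alternate alleles column by column
  tally <- apply(G, 2, function(g) {
    f <- sum(g) / (2 * length(g))
    min(f, 1 - f)
  })
  expect_equal(unname(attr(G, "realized_maf")), unname(tally))
  expect_lt(abs(mean(tally) - 0.5), 0.05)
})

test_that("missingness is injected at the configured rate", {
  cfg <- population_config(n_genotypes = 200, n_markers = 200,
                           missing_rate = 0.1, seed = 2)
  G <- simulate_genotypes(cfg)
  expect_lt(abs(mean(is.na(G)) - 0.1), 0.01)
  expect_true(all(G[!is.na(G)] %in% 0:2))
})

test_that("phenotype heritability limits behave (h2 = 1 and h2 = 0)", {
  cfg1 <- population_config(n_genotypes = 100, n_markers = 200,
                            h2_low_n = 1, missing_rate = 0, seed = 9)
  G <- simulate_genotypes(cfg1)
  sim <- simulate_phenotypes(G, cfg1)
  y <- level_trait(list(genotypes = G, phenotypes = sim$phenotypes), "LN")
  expect_gt(cor(y, sim$architecture$true_gebv[, "LN"]), 1 - 1e-10)

  cfg0 <- population_config(n_genotypes = 500, n_markers = 200,
                            h2_low_n = 0, missing_rate = 0, seed = 9)
  G0 <- simulate_genotypes(cfg0)
  sim0 <- simulate_phenotypes(G0, cfg0)
  y0 <- level_trait(list(genotypes = G0, phenotypes = sim0$phenotypes), "LN")
  expect_lte(cor(y0, sim0$architecture$true_gebv[, "LN"])^2, 0.05)
})

test_that("variance ratio of genetic to total matches the h2 target", {
  cfg <- population_config(n_genotypes = 400, n_markers = 400, n_qtl = 200,
                           h2_low_n = 0.5, missing_rate = 0, seed = 13)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  y <- level_trait(list(genotypes = G, phenotypes = sim$phenotypes), "LN")
  # independent variance tally from the raw vectors
  ratio <- var(sim$architecture$true_gebv[, "LN"]) / var(y)
  expect_lt(abs(ratio - 0.5), 0.08)
  # construction-level ratio is exact
  s2a <- sim$architecture$sigma2_a[["LN"]]
  s2e <- sim$architecture$sigma2_e[["LN"]]
  expect_equal(s2a / (s2a + s2e), 0.5, tolerance = 1e-12)
})

test_that("sample heritability converges to the target at large n", {
  cfg <- population_config(n_genotypes = 1000, n_markers = 300,
                           n_qtl = 150, h2_low_n = 0.45, h2_high_n = 0.6,
                           missing_rate = 0, seed = 21)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  for (lev in c("LN", "HN")) {
    y <- level_trait(list(genotypes = G, phenotypes = sim$phenotypes), lev)
    ratio <- var(sim$architecture$true_gebv[, lev]) / var(y)
    target <- if (lev == "LN") 0.45 else 0.6
    expect_lt(abs(ratio - target), 0.05)
  }
})

test_that("QTL effects across N levels carry the configured correlation", {
  cfg <- population_config(n_genotypes = 50, n_markers = 3000,
                           n_qtl = 2500, genetic_corr_n_levels = 0.8,
                           seed = 4)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  r <- cor(sim$architecture$effects_low_n, sim$architecture$effects_high_n)
  expect_lt(abs(r - 0.8), 0.05)
})

test_that("subpopulation structure is visible on the leading PCs", {
  cfg <- population_config(n_genotypes = 150, n_markers = 1000,
                           n_subpops = 3, subpop_divergence = 0.1,
                           missing_rate = 0, seed = 17)
  G <- simulate_genotypes(cfg)
  pcs <- prcomp(sweep(G, 2, colMeans(G)), rank. = 2)$x
  set.seed(1)
  cl <- kmeans(pcs, centers = 3, nstart = 20)$cluster
  purity <- mean(apply(table(cl, attr(G, "subpop")), 1, max) /
                   table(cl))
  expect_gte(purity, 0.9)
})

test_that("NUE is the yield-to-nitrogen ratio with the factored identity", {
  expect_equal(compute_nue(GY = 500, Ns = 100), 5)
  expect_equal(compute_nue(GY = 500, Ns = 100, Nt = 250), 5)
  expect_error(compute_nue(GY = 500, Ns = 0), "Ns")
  expect_error(compute_nue(GY = 500, Ns = 100, Nt = -1), "Nt")
})

test_that("phenotype table satisfies the NUE invariant", {
  pop <- small_population(n = 40, m = 100, seed = 2)
  ph <- pop$phenotypes
  expect_setequal(unique(ph$n_level), c("LN", "HN"))
  expect_equal(ph$NUE, ph$GY / ph$Ns)
  expect_true(all(ph$Nt > 0))
})
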