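test_that("Henderson-matrix power matches the block-determinant fixture", {
  bp <- mme_power(matrix(1, 3, 1), diag(3), diag(3), sigma2_e = 1,
                  sigma2_u = 1)
  # det C = det(2 I3) * (3 - 1'(2I)^-1 1) = 8 * 1.5 = 12
  expect_equal(as.numeric(bp), log(12) / 4, tolerance = 1e-12)
  expect_error(mme_power(matrix(1, 3, 1), matrix(0, 3, 3), diag(3), 1, 1),
               "degenerate Z")
})

test_that("model power grows with added genotypes", {
  set.seed(131)
  grows <- replicate(10, {
    n <- 20
    M <- random_coded(2 * n, 100, seed = sample.int(1e6, 1)) + 1
    G1 <- build_grm(M[1:n, ])
    G2 <- build_grm(M)
    b1 <- mme_power(matrix(1, n, 1), diag(n),
                    regularized_inverse(G1)[, ], 1, 1)
    b2 <- mme_power(matrix(1, 2 * n, 1), diag(2 * n),
                    regularized_inverse(G2)[, ], 1, 1)
    attr(b2, "logdet") > attr(b1, "logdet")
  })
  expect_true(all(grows))
})

test_that("gain formulas are literal products and exactly linear", {
  expect_equal(genetic_gain(0, 0.9, 2, 0.5, 1)$R, 0)
  expect_equal(genetic_gain(1.4, 1, 1, 1, 1)$R, 1.4)
  g <- genetic_gain(2.06, 0.9, 1, 0.62, 1.5)
  expect_equal(round(g$R, 4), 1.1495)
  expect_equal(g$delta_g, 2.06 * 0.62 * 1.5)
  # factor doubling doubles both outputs
  g2 <- genetic_gain(2 * 2.06, 0.9, 1, 0.62, 1.5)
  expect_equal(g2$R, 2 * g$R)
  expect_equal(g2$delta_g, 2 * g$delta_g)
  # per-year variant divides by y
  expect_equal(genetic_gain(1, 0.5, 4, 1, 1, per_year = TRUE)$R,
               genetic_gain(1, 0.5, 4, 1, 1)$R / 4)
})

test_that("relative efficiency is r over R squared", {
  expect_equal(relative_efficiency(1, 1), 1)
  expect_equal(relative_efficiency(0.8, 2), 0.2)
  res <- sapply(c(0.5, 1, 2, 4), function(R) relative_efficiency(0.6, R))
  expect_true(all(diff(res) < 0))
  expect_error(relative_efficiency(0.5, 0), "R = 0")
})

test_that("selection intensity follows the normal truncation relation", {
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5, tolerance = 1e-12)
  expect_gt(selection_intensity(0.05), selection_intensity(0.5))
})

test_that("top-genotype ranking handles ties, overlap and completeness", {
  gebvs <- tibble::tibble(
    genotype_id = rep(sprintf("g%d", 1:5), 2),
    n_level = rep(c("LN", "HN"), each = 5),
    gebv = c(3, 1, 4, 1, 5, 3, 1, 4, 1, 5))
  rk <- rank_top_genotypes(gebvs, k = 2)
  expect_setequal(rk$top$genotype_id[rk$top$n_level == "LN"],
                  c("g5", "g3")) # values 5 and 4
  expect_equal(length(rk$overlap), 2L) # identical levels -> full overlap
  # disjoint rankings
  gebvs$gebv[gebvs$n_level == "HN"] <- c(5, 4, 1, 1, 1)
  rk2 <- rank_top_genotypes(gebvs, k = 2)
  expect_equal(length(rk2$overlap), 0L)
  # tie at the boundary broken by genotype id
  g3 <- tibble::tibble(genotype_id = c("a", "b", "c"), n_level = "LN",
                       gebv = c(1, 1, 0))
  expect_equal(rank_top_genotypes(g3, k = 1)$top$genotype_id, "a")
  expect_error(rank_top_genotypes(g3, k = 10), "population size")
  # full ranking is a permutation
  rk_full <- rank_top_genotypes(gebvs, k = 5)
  expect_setequal(rk_full$top$genotype_id[rk_full$top$n_level == "LN"],
                  sprintf("g%d", 1:5))
})

test_that("allele contents are complementary and contrasts detect enrichment", {
  pop <- small_population(n = 100, m = 200, seed = 132)
  G <- pop$genotypes
  res <- allele_content_contrast(G, rownames(G)) # top = whole population
  expect_equal(res$contrast$difference, c(0, 0))
  expect_equal(res$contrast$p_value, c(1, 1))
  expect_equal(res$per_genotype$mean_minor + res$per_genotype$mean_major,
               rep(2, nrow(G)))
  # constructed enrichment: top genotypes loaded with minor alleles
  set.seed(133)
  n <- 200
  p <- 500
  freq <- runif(p, 0.1, 0.3)
  base <- sapply(freq, function(f) rbinom(n, 2, f))
  rownames(base) <- sprintf("G%03d", 1:n)
  top <- rownames(base)[1:10]
  extra <- sapply(freq, function(f) rbinom(10, 2, pmin(f * 1.6, 1)))
  base[1:10, ] <- pmax(base[1:10, ], extra)
  res2 <- allele_content_contrast(base, top)
  minor_row <- res2$contrast[res2$contrast$content == "minor", ]
  expect_lt(minor_row$p_value, 0.01)
  expect_gt(minor_row$difference, 0)
  expect_error(allele_content_contrast(base, character(0)), "empty")
})

test_that("75/25 splitting uses floor rounding and is seeded", {
  ids <- sprintf("G%03d", 1:221)
  sp <- split_train_test(ids, 0.75, seed = 3)
  expect_equal(length(sp$train), floor(0.75 * 221))
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- split_train_test(ids, 0.75, seed = 3)
  expect_identical(sp, sp2)
})

test_that("the gain report assembles accuracy, power, gain and top lists", {
  pop <- small_population(n = 70, m = 150, seed = 134, h2_ln = 0.7,
                          h2_hn = 0.7)
  gr <- gain_report(pop$phenotypes, pop$genotypes, model = "rrblup",
                    k = 8, seed = 11)
  expect_s3_class(gr$summary, "tbl_df")
  expect_equal(nrow(gr$summary), 2L)
  expect_true(all(abs(gr$summary$accuracy) <= 1))
  expect_true(all(gr$summary$beta_power > 0))
  expect_equal(gr$summary$expected_gain,
               gr$summary$selection_intensity * gr$summary$accuracy *
                 gr$summary$years * gr$summary$beta_power)
  expect_equal(nrow(gr$top), 16L)
  expect_true(all(gr$top$genotype_id %in% rownames(pop$genotypes)))
  # top lists are sorted descending within level
  for (lev in c("LN", "HN")) {
    gl <- gr$top$gebv[gr$top$n_level == lev]
    expect_true(all(diff(gl) <= 0))
  }
})
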