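test_that("MAF follows the allele-count definition and folds at 0.5", {
  # 10 genotypes, dosages summing to 8 -> f = 8/20 = 0.4
  G <- cbind(m1 = c(2, 2, 2, 2, 0, 0, 0, 0, 0, 0),
             m2 = rep(0, 10),       # fixed reference
             m3 = rep(2, 10))       # fixed alternate, folds to 0
  expect_equal(unname(compute_maf(G)), c(0.4, 0, 0))
  # missing entries drop out of numerator and denominator
  G2 <- cbind(m = c(2, 2, NA, NA, 0))
  expect_equal(unname(compute_maf(G2)), min(4 / 6, 1 - 4 / 6))
  # all-missing marker is flagged undefined
  expect_true(is.na(compute_maf(cbind(m = rep(NA_real_, 4)))))
})

test_that("MAF is invariant to swapping reference and alternate alleles", {
  pop <- small_population(n = 60, m = 120, seed = 4)
  G <- pop$G_raw
  expect_equal(compute_maf(G), compute_maf(2 - G))
})

test_that("HWE chi-square matches hand computations", {
  counts_to_marker <- function(n0, n1, n2)
    c(rep(0, n0), rep(1, n1), rep(2, n2))
  G <- cbind(hwe = counts_to_marker(25, 50, 25),
             dev = counts_to_marker(30, 40, 30),
             het0 = counts_to_marker(50, 0, 50))
  h <- hwe_chisq(G)
  expect_equal(h$chisq[1], 0)
  expect_equal(h$chisq[2], 4)   # (5^2/25) + (10^2/50) + (5^2/25)
  expect_equal(h$chisq[3], 100) # complete heterozygote deficit at p = 0.5
  # monomorphic marker: expectation zero in a cell, reported undefined
  Gm <- cbind(mono = rep(0, 50))
  expect_true(is.na(hwe_chisq(Gm)$chisq))
  # chi-square is never negative on random panels
  pop <- small_population(n = 60, m = 100, seed = 5)
  expect_true(all(hwe_chisq(pop$G_raw)$chisq >= 0, na.rm = TRUE))
})

test_that("inclusive MAF threshold removes boundary markers", {
  # markers engineered to exact MAFs {0.01, 0.05, 0.2, 0.5, 0.04}
  n <- 100
  make <- function(k) c(rep(1, k), rep(0, 2 * n / 2 - k))[1:n] # k hets
  G <- sapply(c(2, 10, 40, 100, 8), function(k) make(k))
  colnames(G) <- paste0("m", 1:5)
  expect_equal(unname(compute_maf(G)), c(0.01, 0.05, 0.2, 0.5, 0.04))
  qc <- apply_qc(G, maf_threshold = 0.05, hwe_alpha = 0, min_call_rate = 0)
  expect_equal(ncol(qc$genotypes), 2L)
  expect_equal(qc$report$n_removed_maf, 3L)
  expect_setequal(colnames(qc$genotypes), c("m3", "m4"))
})

test_that("no-op thresholds leave a polymorphic panel unchanged", {
  pop <- small_population(n = 50, m = 80, seed = 6, missing_rate = 0)
  G <- pop$G_raw
  poly <- G[, compute_maf(G) > 0, drop = FALSE]
  qc <- apply_qc(poly, maf_threshold = 0, hwe_alpha = 0, min_call_rate = 0)
  expect_equal(qc$genotypes, poly * 1.0)
})

test_that("QC report counts are conserved and reasons are exclusive", {
  pop <- small_population(n = 80, m = 300, seed = 7, missing_rate = 0.1)
  qc <- apply_qc(pop$G_raw)
  r <- qc$report
  expect_equal(r$n_markers_in,
               r$n_markers_out + r$n_removed_maf + r$n_removed_hwe +
                 r$n_removed_callrate)
  tab <- table(r$per_marker$removed_by, useNA = "ifany")
  expect_equal(sum(tab), r$n_markers_in)
  expect_false(anyNA(qc$genotypes))
})

test_that("raising the MAF threshold never retains more markers", {
  pop <- small_population(n = 60, m = 200, seed = 8)
  kept <- sapply(c(0, 0.02, 0.05, 0.1, 0.2), function(thr)
    ncol(apply_qc(pop$G_raw, maf_threshold = thr, hwe_alpha = 0,
                  min_call_rate = 0.5)$genotypes))
  expect_true(all(diff(kept) <= 0))
})

test_that("all-missing markers fall to the call-rate rule", {
  G <- cbind(ok = c(0, 1, 2, 1), gone = rep(NA_real_, 4))
  qc <- apply_qc(G, maf_threshold = 0, hwe_alpha = 0, min_call_rate = 0.5)
  expect_equal(colnames(qc$genotypes), "ok")
  expect_equal(qc$report$n_removed_callrate, 1L)
})

test_that("centered recoding maps dosages to (-1, 0, 1) and inverts", {
  expect_equal(unname(recode_centered(rbind(c(0, 1, 2)))),
               rbind(c(-1, 0, 1)))
  pop <- small_population(n = 30, m = 50, seed = 9)
  coded <- recode_centered(pop$genotypes)
  expect_equal(coded + 1, pop$genotypes)
  het <- matrix(1, 5, 2)
  expect_true(all(recode_centered(het) == 0))
  expect_error(recode_centered(cbind(c(0, NA, 2))), "missing")
})

test_that("empty panel after QC is an explicit error", {
  G <- cbind(m1 = rep(0, 20), m2 = rep(2, 20)) # both monomorphic
  expect_error(apply_qc(G), "empty panel")
})
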