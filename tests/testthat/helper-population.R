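# Small simulated populations shared across test files. Sizes are kept
# modest so the whole suite stays fast; statistical checks use tolerances
# sized to these n.

small_population <- function(n = 80, m = 300, seed = 11, h2_ln = 0.45,
                             h2_hn = 0.6, missing_rate = 0.02, ...) {
  cfg <- population_config(n_genotypes = n, n_markers = m,
                           h2_low_n = h2_ln, h2_high_n = h2_hn,
                           n_qtl = min(60L, m),
                           missing_rate = missing_rate, seed = seed, ...)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, cfg)
  qc <- apply_qc(G)
  genotypes <- qc$genotypes
  attr(genotypes, "subpop") <- attr(G, "subpop")
  list(config = cfg, G_raw = G, genotypes = genotypes,
       coded = recode_centered(genotypes),
       phenotypes = sim$phenotypes, architecture = sim$architecture,
       qc_report = qc$report)
}

# phenotype vector for one N level aligned to a genotype matrix
level_trait <- function(pop, level = "LN", trait = "NUE") {
  ph <- pop$phenotypes[pop$phenotypes$n_level == level, ]
  ph[[trait]][match(rownames(pop$genotypes), ph$genotype_id)]
}

# random coded marker matrix without population structure
random_coded <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(sample(c(-1, 0, 1), n * p, replace = TRUE), n, p,
         dimnames = list(sprintf("G%03d", 1:n), sprintf("M%05d", 1:p)))
}
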