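#' Configuration for the synthetic wheat-like population
#'
#' Bundles every knob of the simulated study population: 221 genotypes in
#' three subpopulation clusters genotyped at a panel of biallelic SNPs, with a
#' quantitative nitrogen-use-efficiency (NUE) trait measured under a low-N
#' (LN) and a high-N (HN) environment. Defaults are the package's study
#' conditions (see the methods vignette for the rationale behind each one).
#'
#' @param n_genotypes Number of genotypes (default 221).
#' @param n_markers Number of biallelic SNP markers.
#' @param n_subpops Number of subpopulation clusters (default 3).
#' @param subpop_divergence Drift parameter (Fst-like, >= 0) separating
#'   subpopulation allele frequencies from the shared ancestral frequency
#'   under a Balding-Nichols model. 0 gives a panmictic population.
#' @param maf_low,maf_high Bounds in (0, 0.5] for ancestral minor allele
#'   frequencies.
#' @param ld_block_len Markers per LD block (>= 1). Within a block each
#'   gamete copies a single founder haplotype, which induces positive
#'   correlation between adjacent markers; 1 gives independent markers.
#' @param n_founders Founder haplotypes per subpopulation feeding the
#'   copying model (default 100, a broad diversity-panel base). Within-block
#'   LD comes from the shared latent factor of the founder haplotypes;
#'   shrinking the pool additionally creates genome-wide relatedness.
#' @param mutation_rate Per-marker flip probability applied after copying.
#' @param n_qtl Number of causal markers for the trait (<= n_markers;
#'   default 200, capped at n_markers).
#' @param h2_low_n,h2_high_n Narrow-sense heritability targets in [0, 1] for
#'   the LN and HN environments.
#' @param genetic_corr_n_levels Correlation in [-1, 1] between QTL effects at
#'   the two N levels (genotype-by-nitrogen interaction strength).
#' @param missing_rate Fraction of genotype calls set missing completely at
#'   random, in [0, 1).
#' @param seed Integer seed; the whole population is deterministic given the
#'   config.
#'
#' @return A validated list of class `population_config`.
#' @export
#' @examples
#' cfg <- population_config(n_genotypes = 50, n_markers = 200, seed = 7)
#' G <- simulate_genotypes(cfg)
#' dim(G)
population_config <- function(n_genotypes = 221,
                              n_markers = 5000,
                              n_subpops = 3,
                              subpop_divergence = 0.1,
                              maf_low = 0.05,
                              maf_high = 0.5,
                              ld_block_len = 10,
                              n_founders = 100,
                              mutation_rate = 0.01,
                              n_qtl = NULL,
                              h2_low_n = 0.45,
                              h2_high_n = 0.60,
                              genetic_corr_n_levels = 0.8,
                              missing_rate = 0.02,
                              seed = 1L) {
  assert_that(is_count(n_genotypes), "n_genotypes must be a positive count")
  assert_that(is_count(n_markers), "n_markers must be a positive count")
  assert_that(is_count(n_subpops), "n_subpops must be a positive count")
  assert_that(is.numeric(subpop_divergence) && subpop_divergence >= 0,
              "subpop_divergence must be >= 0")
  assert_that(is_prob(maf_low) && maf_low > 0 && maf_low <= 0.5,
              "maf_low must lie in (0, 0.5]")
  assert_that(is_prob(maf_high) && maf_high > 0 && maf_high <= 0.5,
              "maf_high must lie in (0, 0.5]")
  assert_that(maf_low <= maf_high, "maf_low must not exceed maf_high")
  assert_that(is_count(ld_block_len), "ld_block_len must be a positive count")
  if (is.null(n_qtl)) n_qtl <- min(200L, n_markers)
  assert_that(is_count(n_founders) && n_founders >= 2,
              "n_founders must be a count >= 2")
  assert_that(is_prob(mutation_rate), "mutation_rate must lie in [0, 1]")
  assert_that(is_count(n_qtl) && n_qtl <= n_markers,
              "n_qtl must be a count <= n_markers")
  assert_that(is_prob(h2_low_n), "h2_low_n must lie in [0, 1]")
  assert_that(is_prob(h2_high_n), "h2_high_n must lie in [0, 1]")
  assert_that(is.numeric(genetic_corr_n_levels) &&
                abs(genetic_corr_n_levels) <= 1,
              "genetic_corr_n_levels must lie in [-1, 1]")
  assert_that(is_prob(missing_rate) && missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  assert_that(length(seed) == 1 && is.finite(seed), "seed must be an integer")
  structure(list(
    n_genotypes = as.integer(n_genotypes), n_markers = as.integer(n_markers),
    n_subpops = as.integer(n_subpops), subpop_divergence = subpop_divergence,
    maf_low = maf_low, maf_high = maf_high,
    ld_block_len = as.integer(ld_block_len),
    n_founders = as.integer(n_founders), mutation_rate = mutation_rate,
    n_qtl = as.integer(n_qtl), h2_low_n = h2_low_n, h2_high_n = h2_high_n,
    genetic_corr_n_levels = genetic_corr_n_levels,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "population_config")
}

#' Simulate a structured SNP dosage matrix
#'
#' Draws a genotypes-by-markers dosage matrix (counts of the alternate
#' allele, 0/1/2, `NA` for missing) with subpopulation structure and
#' blockwise linkage disequilibrium. Ancestral allele frequencies are uniform
#' on `[maf_low, maf_high]`; subpopulation frequencies drift from them under
#' a Balding-Nichols model with parameter `subpop_divergence`. Each gamete is
#' built by copying one founder haplotype of its subpopulation per LD block
#' and flipping alleles at `mutation_rate`, so markers within a block are
#' positively correlated through shared founders. Missing calls are injected
#' completely at random.
#'
#' @param config A [population_config()].
#' @return Integer matrix of dosages with genotype ids as row names and
#'   marker ids as column names. Attributes: `subpop` (integer cluster label
#'   per genotype), `marker_meta` (tibble with chromosome/position/ancestral
#'   frequency per marker), `realized_maf` (per-marker minor allele frequency
#'   after simulation, missing calls excluded).
#' @export
simulate_genotypes <- function(config) {
  assert_that(inherits(config, "population_config"),
              "config must be a population_config")
  n <- config$n_genotypes
  m <- config$n_markers
  local_rng(seed_stream(config$seed, "genotypes"), {
    p_anc <- runif(m, config$maf_low, config$maf_high)
    subpop <- rep_len(seq_len(config$n_subpops), n)
    blocks <- ceiling(seq_len(m) / config$ld_block_len)
    n_blocks <- max(blocks)
    dosage <- matrix(0L, n, m)
    for (s in seq_len(config$n_subpops)) {
      rows <- which(subpop == s)
      if (!length(rows)) next
      F <- config$subpop_divergence
      p_s <- if (F > 0 && config$n_subpops > 1) {
        shape <- (1 - F) / F
        pmin(pmax(rbeta(m, p_anc * shape, (1 - p_anc) * shape), 1e-6), 1 - 1e-6)
      } else p_anc
      # founder haplotypes: markers of a block share a latent Gaussian
      # factor (the "latent haplotype"), so within-block alleles are
      # positively associated while marginals stay Bernoulli(p_s)
      rho <- 0.7
      z_block <- matrix(rnorm(config$n_founders * n_blocks),
                        config$n_founders, n_blocks)
      eps <- matrix(rnorm(config$n_founders * m), config$n_founders, m)
      latent <- sqrt(rho) * z_block[, blocks, drop = FALSE] +
        sqrt(1 - rho) * eps
      founders <- matrix(0L, config$n_founders, m)
      founders[latent < rep(qnorm(p_s), each = config$n_founders)] <- 1L
      for (gam in 1:2) {
        fid <- matrix(sample.int(config$n_founders, length(rows) * n_blocks,
                                 replace = TRUE),
                      length(rows), n_blocks)
        alleles <- matrix(
          founders[cbind(as.vector(fid[, blocks]), rep(seq_len(m), each = length(rows)))],
          length(rows), m
        )
        if (config$mutation_rate > 0) {
          flip <- matrix(runif(length(rows) * m) < config$mutation_rate,
                         length(rows), m)
          alleles[flip] <- 1L - alleles[flip]
        }
        dosage[rows, ] <- dosage[rows, ] + alleles
      }
    }
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n * m) < config$missing_rate, n, m)
      dosage[miss] <- NA_integer_
    }
    dimnames(dosage) <- list(genotype_ids(n), marker_ids(m))
    meta <- tibble::tibble(
      marker_id = marker_ids(m),
      chrom = ((blocks - 1L) %% 21L) + 1L,
      pos = seq_len(m),
      ancestral_freq = p_anc
    )
    structure(dosage,
              subpop = subpop,
              marker_meta = meta,
              realized_maf = compute_maf(dosage))
  })
}

#' Simulate NUE phenotypes on top of a genotype matrix
#'
#' Additive QTL model per N environment: a set of causal markers receives
#' effects drawn from a bivariate normal across the LN/HN environments with
#' correlation `genetic_corr_n_levels`; genetic values are scaled to
#' Table-1-like genetic variances and residual noise is scaled so the
#' population-level variance ratio equals the target heritability exactly
#' (`sigma2_e = sigma2_a (1 - h2) / h2`). The NUE value is built first and
#' grain yield (GY), nitrogen supplied (Ns) and total plant nitrogen (Nt)
#' are derived consistently with NUE = GY / Ns.
#'
#' @param G Dosage matrix from [simulate_genotypes()] (missing entries are
#'   mean-imputed internally when computing genetic values).
#' @param config The same [population_config()].
#' @return A list with `phenotypes` (tibble: genotype_id, n_level, GY, Ns,
#'   Nt, NUE) and `architecture` (class `true_architecture`: qtl indices and
#'   ids, per-level effects, variance components and true genomic values).
#' @export
simulate_phenotypes <- function(G, config) {
  assert_that(inherits(config, "population_config"),
              "config must be a population_config")
  assert_that(is.matrix(G), "G must be a dosage matrix")
  assert_that(!any(colSums(!is.na(G)) == 0), "G has all-missing markers")
  assert_that(config$n_qtl <= ncol(G), "n_qtl exceeds available markers")
  n <- nrow(G)
  local_rng(seed_stream(config$seed, "phenotypes"), {
    W <- impute_marker_mean(G)
    W <- sweep(W, 2, colMeans(W))
    qtl <- sort(sample.int(ncol(G), config$n_qtl))
    z1 <- rnorm(config$n_qtl)
    z2 <- rnorm(config$n_qtl)
    rho <- config$genetic_corr_n_levels
    eff <- list(LN = z1, HN = rho * z1 + sqrt(1 - rho^2) * z2)
    # Table-1-like genetic variances and NUE scales (g grain per g N supplied)
    target_vg <- c(LN = 30, HN = 15)
    mu <- c(LN = 45, HN = 25)
    ns <- c(LN = 10, HN = 22)
    h2 <- c(LN = config$h2_low_n, HN = config$h2_high_n)
    true_gebv <- matrix(0, n, 2, dimnames = list(rownames(G), c("LN", "HN")))
    sigma2_a <- sigma2_e <- c(LN = 0, HN = 0)
    pheno <- vector("list", 2)
    for (lev in c("LN", "HN")) {
      g_raw <- drop(W[, qtl, drop = FALSE] %*% eff[[lev]])
      s_raw <- stats::var(g_raw)
      scale_fac <- if (s_raw > 0) sqrt(target_vg[[lev]] / s_raw) else 0
      g <- g_raw * scale_fac
      eff[[lev]] <- eff[[lev]] * scale_fac
      true_gebv[, lev] <- g
      if (h2[[lev]] > 0) {
        sigma2_a[[lev]] <- stats::var(g)
        sigma2_e[[lev]] <- if (h2[[lev]] < 1)
          sigma2_a[[lev]] * (1 - h2[[lev]]) / h2[[lev]] else 0
        e <- if (sigma2_e[[lev]] > 0) rnorm(n, 0, sqrt(sigma2_e[[lev]])) else 0
        nue <- mu[[lev]] + g + e
      } else {
        # no heritable signal: phenotype is pure noise at the genetic scale
        sigma2_a[[lev]] <- 0
        sigma2_e[[lev]] <- target_vg[[lev]]
        nue <- mu[[lev]] + rnorm(n, 0, sqrt(sigma2_e[[lev]]))
      }
      gy <- nue * ns[[lev]]
      nt <- 0.6 * ns[[lev]] + 0.012 * gy
      pheno[[lev]] <- tibble::tibble(
        genotype_id = rownames(G), n_level = lev,
        GY = unname(gy), Ns = ns[[lev]], Nt = unname(nt),
        NUE = unname(nue)
      )
    }
    arch <- structure(list(
      qtl_indices = qtl, qtl_ids = colnames(G)[qtl],
      effects_low_n = eff$LN, effects_high_n = eff$HN,
      sigma2_a = sigma2_a, sigma2_e = sigma2_e,
      h2_target = h2, mu = mu, true_gebv = true_gebv
    ), class = "true_architecture")
    list(phenotypes = dplyr::bind_rows(pheno), architecture = arch)
  })
}

#' Nitrogen use efficiency
#'
#' NUE = GY / Ns, grain yield per unit nitrogen supplied; the factored form
#' (Nt/Ns)(GY/Nt) through total plant nitrogen Nt is algebraically identical
#' and is used when `Nt` is supplied (after validating Nt > 0).
#'
#' @param GY Grain yield (g/m^2).
#' @param Ns Nutrient (N) supplied; must be positive.
#' @param Nt Optional total above-ground plant N at maturity; must be
#'   positive when given.
#' @return Numeric NUE value(s), unitless ratio.
#' @export
#' @examples
#' compute_nue(GY = 500, Ns = 100)
compute_nue <- function(GY, Ns, Nt = NULL) {
  assert_that(all(is.finite(Ns)) && all(Ns > 0), "Ns must be positive")
  if (!is.null(Nt)) {
    assert_that(all(is.finite(Nt)) && all(Nt > 0), "Nt must be positive")
    return((Nt / Ns) * (GY / Nt))
  }
  GY / Ns
}

#' Mean-impute missing dosages per marker
#'
#' Replaces missing calls with the marker's mean non-missing dosage; the
#' completion step used after QC filtering so the matrix algebra downstream
#' has no gaps.
#'
#' @param G Dosage matrix with possible `NA` entries.
#' @return Numeric matrix without missing values.
#' @export
impute_marker_mean <- function(G) {
  if (!anyNA(G)) return(G * 1.0)
  mns <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G <- G * 1.0
  G[idx] <- mns[idx[, 2]]
  G
}
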