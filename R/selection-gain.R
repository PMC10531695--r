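#' Model power from the Henderson coefficient matrix
#'
#' Assembles the mixed-model-equation coefficient matrix
#' C = [[X'X, X'Z], [Z'X, Z'Z + G^-1 sigma2_e / sigma2_u]] and returns the
#' information-content reading of the model-power term: beta_power =
#' logdet(C) / dim(C). More genotypes or a denser design add information
#' and raise the log-determinant.
#'
#' @param X Fixed-effect incidence matrix (n x f), e.g. population
#'   structure proportions or an intercept column.
#' @param Z Random-effect design matrix (n x q); no all-zero columns.
#' @param Ginv Inverted genomic relationship matrix (q x q), e.g. from
#'   [regularized_inverse()].
#' @param sigma2_e,sigma2_u Residual and additive variance scalars.
#' @return `beta_power` (scalar) with attribute `logdet`.
#' @export
mme_power <- function(X, Z, Ginv, sigma2_e, sigma2_u = 1) {
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  assert_that(nrow(X) == nrow(Z), "X and Z must have matching rows")
  assert_that(nrow(Ginv) == ncol(Z) && ncol(Ginv) == ncol(Z),
              "Ginv must be q x q with q = ncol(Z)")
  assert_that(sigma2_e > 0 && sigma2_u > 0, "variances must be positive")
  if (any(colSums(abs(Z)) == 0))
    abort("degenerate Z: a random effect has no incidence (singular system)")
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + Ginv * (sigma2_e / sigma2_u))
  )
  ld <- determinant(C, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    abort("singular Henderson coefficient matrix")
  q <- nrow(C)
  structure(as.numeric(ld$modulus) / q, logdet = as.numeric(ld$modulus))
}

#' Selection intensity from the selected fraction
#'
#' Standardized mean of the selected tail under a normal truncation model:
#' i = dnorm(qnorm(1 - p)) / p for selected fraction p.
#'
#' @param fraction Selected fraction in (0, 1).
#' @return Selection intensity (unitless).
#' @export
selection_intensity <- function(fraction) {
  assert_that(is.numeric(fraction) && all(fraction > 0 & fraction < 1),
              "fraction must lie in (0, 1)")
  dnorm(qnorm(1 - fraction)) / fraction
}

#' Genetic gain and expected selection gain
#'
#' Literal products of the gain formulas: delta_g = i * beta_power *
#' sigma_e (marker-based genetic gain) and R = i * r * y * beta_power
#' (expected genetic selection gain), with i the selection intensity (or
#' genetic selection density), r the selection accuracy, y the number of
#' years and beta_power the model power from [mme_power()]. Both are
#' exactly linear in each factor. `per_year = TRUE` divides R by y, the
#' conventional per-year variant.
#'
#' @param i Selection intensity / genetic selection density.
#' @param r Accuracy in [-1, 1].
#' @param y_years Breeding-cycle years (>= 1).
#' @param beta_power Model power.
#' @param sigma_e Residual standard error of the model.
#' @param per_year Divide R by y (default FALSE: literal product).
#' @return List: `delta_g`, `R`.
#' @export
genetic_gain <- function(i, r, y_years, beta_power, sigma_e,
                         per_year = FALSE) {
  assert_that(is.numeric(y_years) && y_years >= 1, "y_years must be >= 1")
  assert_that(is.numeric(r) && abs(r) <= 1, "r must lie in [-1, 1]")
  R <- i * r * y_years * beta_power
  if (per_year) R <- R / y_years
  list(delta_g = i * beta_power * sigma_e, R = R)
}

#' Relative efficiency of genomic over phenotypic selection
#'
#' RE = r / R^2, relating selection accuracy to the squared expected gain;
#' reported per N level, and as a percentage when multiplied by 100.
#'
#' @param r Selection accuracy.
#' @param R Expected genetic selection gain (nonzero).
#' @return RE (unitless).
#' @export
relative_efficiency <- function(r, R) {
  assert_that(is.numeric(R) && all(R != 0), "RE undefined for R = 0")
  r / R^2
}

#' Top genotypes by GEBV per N level
#'
#' Ranks genotypes by GEBV within each N level (ties broken by genotype
#' id), returns the top k per level and the overlap set of ids appearing
#' in both levels' top lists.
#'
#' @param gebvs Tibble with `genotype_id`, `n_level`, `gebv`.
#' @param k Top-list size (default 10).
#' @return List: `top` (tibble with rank per level), `overlap` (character
#'   ids in both top lists).
#' @export
rank_top_genotypes <- function(gebvs, k = 10) {
  assert_that(all(c("genotype_id", "n_level", "gebv") %in% names(gebvs)),
              "gebvs needs genotype_id, n_level, gebv")
  n_per <- min(table(gebvs$n_level))
  assert_that(k <= n_per, "k exceeds the population size")
  top <- gebvs |>
    dplyr::group_by(.data$n_level) |>
    dplyr::arrange(dplyr::desc(.data$gebv), .data$genotype_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  levels_present <- unique(top$n_level)
  overlap <- if (length(levels_present) >= 2) {
    Reduce(intersect, split(top$genotype_id, top$n_level))
  } else character(0)
  list(top = top, overlap = overlap)
}

#' Allele-content contrast of top genotypes against the population
#'
#' Per genotype, the mean count of minor and of major alleles across the
#' QC'd markers (folded at the population alternate-allele frequency;
#' minor + major counts sum to 2 per marker). The selected top set is
#' compared to the whole population by a Welch t-test for each content
#' type.
#'
#' @param G Complete dosage matrix after QC.
#' @param top_ids Non-empty character vector of selected genotype ids.
#' @return List: `per_genotype` tibble (mean minor/major counts, top-set
#'   flag) and `contrast` tibble (means, mean difference, t, p per content
#'   type).
#' @export
allele_content_contrast <- function(G, top_ids) {
  assert_that(length(top_ids) > 0, "top set is empty")
  assert_that(all(top_ids %in% rownames(G)),
              "top_ids must be present in G")
  f <- colMeans(G) / 2 # alternate-allele frequency
  minor_is_alt <- f <= 0.5
  minor <- sweep(G, 2, ifelse(minor_is_alt, 0, 2), function(g, o)
    abs(g - o))
  mean_minor <- rowMeans(minor)
  mean_major <- 2 - mean_minor
  per_genotype <- tibble::tibble(
    genotype_id = rownames(G),
    mean_minor = unname(mean_minor), mean_major = unname(mean_major),
    in_top = rownames(G) %in% top_ids
  )
  contrast <- purrr::map_dfr(c(minor = "mean_minor", major = "mean_major"),
    function(col) {
      top <- per_genotype[[col]][per_genotype$in_top]
      pop <- per_genotype[[col]]
      if (isTRUE(all.equal(mean(top), mean(pop))) &&
          length(top) == length(pop)) {
        tibble::tibble(mean_top = mean(top), mean_population = mean(pop),
                       difference = 0, t = 0, p_value = 1)
      } else {
        tt <- t.test(top, pop, var.equal = FALSE)
        tibble::tibble(mean_top = mean(top), mean_population = mean(pop),
                       difference = mean(top) - mean(pop),
                       t = unname(tt$statistic), p_value = tt$p.value)
      }
    }, .id = "content")
  list(per_genotype = per_genotype, contrast = contrast)
}

#' Split genotypes into 75% training and 25% testing
#'
#' Seeded shuffle with floor rounding of the training fraction.
#'
#' @param ids Genotype ids.
#' @param fraction Training fraction (default 0.75).
#' @param seed Shuffle seed.
#' @return List: `train`, `test` id vectors.
#' @export
split_train_test <- function(ids, fraction = 0.75, seed = 1) {
  assert_that(is_prob(fraction) && fraction > 0 && fraction < 1,
              "fraction must lie in (0, 1)")
  n_train <- floor(fraction * length(ids))
  assert_that(n_train >= 1 && n_train < length(ids),
              "split leaves an empty set")
  shuffled <- local_rng(seed_stream(seed, "split"), sample(ids))
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Selection-gain report for a chosen GS model
#'
#' The end-stage analysis: split the population 75/25, fit the chosen
#' model per N level, measure test accuracy, assemble the Henderson-matrix
#' model power, convert the selected fraction to an intensity, and report
#' expected gain R, relative efficiency RE, the top-k genotypes per level
#' with their RE percentages (each top genotype's share of the top-set
#' GEBV total scaled by the population RE -- a display convention), the
#' cross-level overlap, and the allele-content contrast of the overlap
#' set (falling back to the union of top lists when fewer than 2 overlap).
#'
#' @param phenotypes Phenotype tibble (genotype_id, n_level, trait).
#' @param genotypes QC'd complete dosage matrix.
#' @param model Model name (default "stack"; any of [gs_model_names()]).
#' @param k Top-list size.
#' @param y_years Breeding-cycle years.
#' @param settings [model_settings()].
#' @param trait Trait column (default "NUE").
#' @param seed Seed for the split and stochastic fits.
#' @return A `gain_report` list: `summary` tibble per N level, `top`,
#'   `overlap`, `allele_contrast`, `beta_power`, split sizes.
#' @export
gain_report <- function(phenotypes, genotypes, model = "stack", k = 10,
                        y_years = 1, settings = model_settings(),
                        trait = "NUE", seed = 1) {
  model <- match.arg(model, gs_model_names())
  ids <- rownames(genotypes)
  split <- split_train_test(ids, 0.75, seed)
  coded <- recode_centered(genotypes)
  G <- build_grm(coded)
  K <- build_gaussian_kernel(coded, settings$kernel_bandwidth)
  tr <- match(split$train, ids)
  te <- match(split$test, ids)
  models_needed <- if (model == "stack")
    c(settings$stack_bases %||% setdiff(gs_model_names(), "stack"), "stack")
  else model
  subpop <- attr(genotypes, "subpop")
  Xfix <- if (!is.null(subpop))
    stats::model.matrix(~ 0 + factor(subpop)) else matrix(1, nrow(G), 1)
  rows <- list()
  gebv_all <- list()
  for (lev in unique(phenotypes$n_level)) {
    ph <- phenotypes[phenotypes$n_level == lev, ]
    y <- ph[[trait]][match(ids, ph$genotype_id)]
    fits <- fit_gs_models(y[tr], coded[tr, , drop = FALSE],
                          G = G[tr, tr], K = K[tr, tr],
                          models = models_needed, settings = settings,
                          inner_folds = 5,
                          seed = seed_stream(seed, paste0("gain", lev)))
    fit <- fits[[model]]
    pred_te <- predict_gs(fit, model, coded[te, , drop = FALSE],
                          G[te, tr, drop = FALSE], K[te, tr, drop = FALSE],
                          fits = fits)
    r_acc <- if (stats::var(pred_te) > 0) accuracy(y[te], pred_te) else {
      warn(paste0("constant ", model, " predictions at ", lev,
                  "; selection accuracy set to 0"))
      0
    }
    vc <- fit$vc %||% empirical_vc(fit)
    Ginv <- regularized_inverse(G)
    bp <- mme_power(Xfix, diag(nrow(G)), Ginv,
                    sigma2_e = max(vc$sigma2_e, 1e-8),
                    sigma2_u = max(vc$sigma2_a, 1e-8))
    i <- selection_intensity(k / length(ids))
    gain <- genetic_gain(i, r_acc, y_years, bp, sqrt(max(vc$sigma2_e, 0)))
    re <- if (gain$R != 0) relative_efficiency(r_acc, gain$R) else NA_real_
    pred_all <- c(setNames(fit$gebv, split$train), setNames(pred_te, split$test))
    gebv_all[[lev]] <- tibble::tibble(genotype_id = names(pred_all),
                                      n_level = lev,
                                      gebv = unname(pred_all))
    rows[[lev]] <- tibble::tibble(
      n_level = lev, model = model, accuracy = r_acc,
      beta_power = as.numeric(bp), selection_intensity = i,
      years = y_years, sigma_e = sqrt(max(vc$sigma2_e, 0)),
      delta_g = gain$delta_g, expected_gain = gain$R,
      relative_efficiency = re, re_pct = 100 * re
    )
  }
  gebvs <- dplyr::bind_rows(gebv_all)
  ranking <- rank_top_genotypes(gebvs, k = k)
  summary <- dplyr::bind_rows(rows)
  top <- ranking$top |>
    dplyr::left_join(summary[, c("n_level", "relative_efficiency")],
                     by = "n_level") |>
    dplyr::group_by(.data$n_level) |>
    dplyr::mutate(re_pct = 100 * .data$relative_efficiency *
                    .data$gebv / sum(.data$gebv)) |>
    dplyr::ungroup() |>
    dplyr::select(-"relative_efficiency")
  contrast_ids <- if (length(ranking$overlap) >= 2) ranking$overlap else
    unique(ranking$top$genotype_id)
  contrast <- allele_content_contrast(genotypes, contrast_ids)
  structure(list(summary = summary, top = top,
                 overlap = ranking$overlap,
                 allele_contrast = contrast,
                 split = vapply(split, length, 1L),
                 model = model, k = k),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat("Selection gain report (", x$model, ", top ", x$k, ")\n", sep = "")
  print(x$summary)
  cat("Top-list overlap across N levels:",
      if (length(x$overlap)) paste(x$overlap, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
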