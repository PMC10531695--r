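#' Pipeline configuration
#'
#' One object holding every stage's settings for [run_pipeline()]: either
#' file inputs (genotype VCF/TSV plus phenotype CSV) or a synthetic
#' [population_config()], the QC thresholds, model list, cross-validation
#' plan, bias-variance sweep, comparison and gain settings, and the single
#' global seed from which every stochastic stage derives its substream.
#'
#' @param synthetic A [population_config()], or NULL when reading files.
#' @param genotype_file,phenotype_file Input paths (exactly one of file
#'   inputs or `synthetic` must be given).
#' @param models Models to run (default all nine).
#' @param maf_threshold,hwe_alpha,min_call_rate QC thresholds.
#' @param outer_folds,inner_folds CV design (testing / training folds).
#' @param cv_mode `"nested"` or `"independent"`.
#' @param settings [model_settings()].
#' @param bv_k_grid,bv_B,bv_n_test KNN bias-variance sweep: neighbour
#'   grid, resamples, fixed test genotypes.
#' @param cmp_n_resamples,cmp_fdr Comparison-stage resamples and FDR.
#' @param gain_model,gain_k,gain_years Gain stage: model, top-list size,
#'   years.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = population_config(),
                       genotype_file = NULL, phenotype_file = NULL,
                       models = gs_model_names(),
                       maf_threshold = 0.05, hwe_alpha = 1e-4,
                       min_call_rate = 0.95,
                       outer_folds = 5, inner_folds = 10,
                       cv_mode = "nested",
                       settings = model_settings(),
                       bv_k_grid = c(1, 5, 25, 100), bv_B = 100,
                       bv_n_test = 40,
                       cmp_n_resamples = 2000, cmp_fdr = 0.05,
                       gain_model = "stack", gain_k = 10, gain_years = 1,
                       seed = 1) {
  from_files <- !is.null(genotype_file) || !is.null(phenotype_file)
  assert_that(xor(from_files, !is.null(synthetic)),
              "give exactly one of file inputs or a synthetic config")
  if (from_files)
    assert_that(!is.null(genotype_file) && !is.null(phenotype_file),
                "file input needs both genotype_file and phenotype_file")
  structure(list(
    synthetic = synthetic, genotype_file = genotype_file,
    phenotype_file = phenotype_file, models = models,
    maf_threshold = maf_threshold, hwe_alpha = hwe_alpha,
    min_call_rate = min_call_rate, outer_folds = outer_folds,
    inner_folds = inner_folds, cv_mode = cv_mode, settings = settings,
    bv_k_grid = bv_k_grid, bv_B = bv_B, bv_n_test = bv_n_test,
    cmp_n_resamples = cmp_n_resamples, cmp_fdr = cmp_fdr,
    gain_model = gain_model, gain_k = gain_k, gain_years = gain_years,
    seed = seed
  ), class = "run_config")
}

#' Run the full GS comparison pipeline
#'
#' Executes, in order: data acquisition (synthetic simulation or file
#' ingestion), marker QC, kinship construction (GRM + Gaussian kernel),
#' model fitting and evaluation under cross-validation, the KNN
#' bias-variance sweep, the adaptive-SE pairwise model comparison on a
#' 75/25 split, and the selection-gain analysis. Every artifact is
#' written under `out_dir` (TSV/CSV/JSON) and a manifest records the
#' config, seed and an md5 checksum per file, so two runs with the same
#' config and seed produce identical manifests.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e))))
  }
  # -- data
  res <- list()
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- seed_stream(config$seed, "population")
    G_raw <- stage("simulate", simulate_genotypes(cfg))
    sim <- stage("simulate", simulate_phenotypes(G_raw, cfg))
    phenotypes <- sim$phenotypes
    res$architecture <- sim$architecture
    write_genotype_tsv(G_raw, file.path(out_dir, "genotypes.tsv"))
    write_genotype_vcf(G_raw, file.path(out_dir, "genotypes.vcf"))
    write_json_report(list(
      qtl_ids = sim$architecture$qtl_ids,
      effects_low_n = sim$architecture$effects_low_n,
      effects_high_n = sim$architecture$effects_high_n,
      sigma2_a = as.list(sim$architecture$sigma2_a),
      sigma2_e = as.list(sim$architecture$sigma2_e)
    ), file.path(out_dir, "architecture.json"))
  } else {
    G_raw <- stage("read", read_genotypes(config$genotype_file))
    phenotypes <- stage("read", read_phenotypes(config$phenotype_file))
  }
  write_phenotypes(phenotypes, file.path(out_dir, "phenotypes.csv"))
  # -- QC
  qc <- stage("qc", apply_qc(G_raw, config$maf_threshold,
                             config$hwe_alpha, config$min_call_rate))
  genotypes <- qc$genotypes
  attr(genotypes, "subpop") <- attr(G_raw, "subpop")
  write.table(qc$report$per_marker, file.path(out_dir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_report(qc$report[c("n_markers_in", "n_removed_maf",
                                "n_removed_hwe", "n_removed_callrate",
                                "n_markers_out")],
                    file.path(out_dir, "qc_report.json"))
  # -- kinship
  coded <- recode_centered(genotypes)
  grm <- stage("kinship", build_grm(coded))
  kernel <- stage("kinship", build_gaussian_kernel(coded))
  write_kinship_tsv(grm, file.path(out_dir, "grm.tsv"))
  write_kinship_tsv(kernel, file.path(out_dir, "kernel.tsv"))
  # -- evaluation under CV
  plan <- cv_plan(rownames(genotypes), config$outer_folds,
                  config$inner_folds, seed = seed_stream(config$seed, "cv"))
  evaluation <- stage("evaluate",
    run_nested_cv(phenotypes, genotypes, config$models, plan,
                  settings = config$settings, mode = config$cv_mode))
  write.table(as.data.frame(evaluation),
              file.path(out_dir, "evaluation_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_report(as.data.frame(evaluation),
                    file.path(out_dir, "evaluation_report.json"))
  # -- bias-variance sweep (synthetic truth when available)
  bv <- stage("biasvar", {
    if (!is.null(config$synthetic)) {
      bv_cfg <- config$synthetic
      bv_cfg$n_markers <- min(bv_cfg$n_markers, 500L)
      bv_cfg$missing_rate <- 0
      knn_bias_variance(bv_cfg, k_grid = config$bv_k_grid,
                        n_test = config$bv_n_test, B = config$bv_B,
                        seed = seed_stream(config$seed, "bv"))
    } else {
      lev <- phenotypes$n_level[1]
      ph <- phenotypes[phenotypes$n_level == lev, ]
      y <- ph$NUE[match(rownames(genotypes), ph$genotype_id)]
      decompose_bias_variance(
        function(tx, ty, sx, k) knn_predict(tx, ty, sx, k),
        list(x = coded, y = y), complexity_grid = config$bv_k_grid,
        B = config$bv_B, seed = seed_stream(config$seed, "bv"))
    }
  })
  write.table(as.data.frame(bv), file.path(out_dir, "bias_variance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # -- pairwise comparison on a common 75/25 test partition
  comparison <- stage("compare",
    pipeline_comparison(phenotypes, genotypes, coded, grm, kernel, config))
  write.table(as.data.frame(comparison$normalized),
              file.path(out_dir, "comparison_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write_json_report(list(raw = comparison$raw,
                         normalized = comparison$normalized,
                         fdr_threshold = comparison$fdr_threshold,
                         n_resamples = comparison$n_resamples),
                    file.path(out_dir, "comparison_matrix.json"))
  # -- selection gain
  gain <- stage("gain",
    gain_report(phenotypes, genotypes, model = config$gain_model,
                k = config$gain_k, y_years = config$gain_years,
                settings = config$settings,
                seed = seed_stream(config$seed, "gain")))
  write.table(as.data.frame(gain$summary),
              file.path(out_dir, "gain_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_report(list(summary = gain$summary, top = gain$top,
                         overlap = gain$overlap,
                         allele_contrast = gain$allele_contrast$contrast),
                    file.path(out_dir, "gain_report.json"))
  # -- manifest
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(seed = config$seed,
                   models = config$models,
                   n_genotypes = nrow(genotypes),
                   n_markers_post_qc = ncol(genotypes),
                   checksums = as.list(checksums))
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(genotypes = genotypes, phenotypes = phenotypes,
                 qc = qc$report, grm = grm, kernel = kernel,
                 evaluation = evaluation, bias_variance = bv,
                 comparison = comparison, gain = gain,
                 architecture = res$architecture,
                 manifest = manifest,
                 manifest_path = file.path(out_dir, "manifest.json")))
}

# Fit all models once on a 75/25 split and compare them pairwise.
pipeline_comparison <- function(phenotypes, genotypes, coded, grm, kernel,
                                config) {
  ids <- rownames(genotypes)
  split <- split_train_test(ids, 0.75, seed_stream(config$seed, "cmp-split"))
  tr <- match(split$train, ids)
  te <- match(split$test, ids)
  lev <- sort(unique(phenotypes$n_level))[1]
  ph <- phenotypes[phenotypes$n_level == lev, ]
  y <- ph$NUE[match(ids, ph$genotype_id)]
  fits <- fit_gs_models(y[tr], coded[tr, , drop = FALSE],
                        G = grm[tr, tr], K = kernel[tr, tr],
                        models = config$models, settings = config$settings,
                        inner_folds = 5,
                        seed = seed_stream(config$seed, "cmp-fit"))
  preds <- lapply(config$models, function(m)
    predict_gs(fits[[m]], m, coded[te, , drop = FALSE],
               grm[te, tr, drop = FALSE], kernel[te, tr, drop = FALSE],
               fits = fits))
  names(preds) <- config$models
  effs <- lapply(config$models, function(m)
    marker_effects(fits[[m]], X = coded[tr, , drop = FALSE]))
  names(effs) <- config$models
  adaptive_se_matrix(preds, y[te], effs, fdr = config$cmp_fdr,
                     n_resamples = config$cmp_n_resamples,
                     seed = seed_stream(config$seed, "cmp-se"))
}
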