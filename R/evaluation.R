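#' Cross-validation plan
#'
#' Partitions genotypes into `outer_folds` test folds (every genotype in
#' exactly one) and carries the inner fold count used for hyper-parameter
#' tuning inside each training split -- the nested reading of a 10-fold
#' training / 5-fold testing cross-validation design.
#'
#' @param genotype_ids Character vector of genotype identifiers.
#' @param outer_folds Outer (testing) folds, default 5.
#' @param inner_folds Inner (training/tuning) folds, default 10.
#' @param seed Assignment seed.
#' @return A `cv_plan`: tibble of genotype_id/outer_fold plus settings.
#' @export
cv_plan <- function(genotype_ids, outer_folds = 5, inner_folds = 10,
                    seed = 1) {
  assert_that(is_count(outer_folds) && outer_folds >= 2,
              "outer_folds must be >= 2")
  assert_that(is_count(inner_folds) && inner_folds >= 2,
              "inner_folds must be >= 2")
  n <- length(genotype_ids)
  assert_that(n >= 2 * outer_folds, "too few genotypes for the fold count")
  assign <- local_rng(seed_stream(seed, "cv-plan"),
                      sample(rep_len(seq_len(outer_folds), n)))
  structure(list(
    assignment = tibble::tibble(genotype_id = genotype_ids,
                                outer_fold = assign),
    outer_folds = as.integer(outer_folds),
    inner_folds = as.integer(inner_folds),
    seed = seed
  ), class = "cv_plan")
}

#' Prediction accuracy
#'
#' Pearson correlation r between observed values and GEBVs, the standard
#' accuracy measure of genomic selection.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 3), both
#'   with positive variance.
#' @return Correlation in [-1, 1].
#' @export
accuracy <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) &&
                length(observed) >= 3,
              "need equal-length vectors of at least 3 values")
  if (stats::var(observed) <= 0 || stats::var(predicted) <= 0)
    abort("accuracy undefined: zero variance in observed or predicted")
  cor(observed, predicted)
}

#' Percentile bootstrap of a GEBV mean
#'
#' Resamples genotypes with replacement `n_boot` times and returns the mean
#' with its percentile confidence interval.
#'
#' @param gebvs Numeric vector (>= 2 values).
#' @param n_boot Bootstrap replicates (>= 100).
#' @param conf Interval coverage (default 0.95).
#' @param seed Resampling seed.
#' @return List: `mean`, `boot_mean`, `lower`, `upper`, `conf`.
#' @export
bootstrap_gebv_mean <- function(gebvs, n_boot = 1000, conf = 0.95,
                                seed = 1) {
  assert_that(length(gebvs) >= 2, "need at least 2 values")
  assert_that(is_count(n_boot) && n_boot >= 100,
              "n_boot must be a count >= 100")
  assert_that(is_prob(conf) && conf > 0 && conf < 1,
              "conf must lie in (0, 1)")
  local_rng(seed_stream(seed, "boot-mean"), {
    n <- length(gebvs)
    means <- vapply(seq_len(n_boot),
                    function(b) mean(gebvs[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    qs <- quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE)
    list(mean = mean(gebvs), boot_mean = mean(means),
         lower = qs[1], upper = qs[2], conf = conf)
  })
}

#' Decaying learning-rate schedule
#'
#' alpha_j = 100 alpha0 / (100 + j) for epochs j = 0..j_max. With alpha0 =
#' 1 and j_max = 9900 the schedule decays from 1 to its minimum 0.01. The
#' product alpha_j (100 + j) is constant along the trace.
#'
#' @param alpha0 Initial learning rate (> 0).
#' @param j_max Last epoch counter (>= 0).
#' @return List: `alpha` (full trace, j = 0..j_max), `j` (epoch counter),
#'   `minimum` (attained at j_max).
#' @export
#' @examples
#' learning_rate_schedule(1, 9900)$minimum
learning_rate_schedule <- function(alpha0 = 1, j_max = 9900) {
  assert_that(is.numeric(alpha0) && alpha0 > 0, "alpha0 must be > 0")
  assert_that(is.numeric(j_max) && j_max >= 0 && j_max == floor(j_max),
              "j_max must be a nonnegative integer")
  j <- 0:j_max
  alpha <- 100 * alpha0 / (100 + j)
  list(alpha = alpha, j = j, minimum = alpha[length(alpha)])
}

#' Welch test of train-phase vs test-phase GEBV means
#'
#' Two-sample unequal-variance t-test of the null that the mean GEBV does
#' not differ between the training and testing phases, starred at the 0.05
#' level.
#'
#' @param train,test GEBV vectors (each of length >= 2).
#' @return Tibble: `t`, `df`, `p_value`, `signif` ("*" or "ns").
#' @export
compare_train_test_means <- function(train, test) {
  assert_that(length(train) >= 2 && length(test) >= 2,
              "need at least 2 GEBVs per group")
  if (isTRUE(all.equal(c(train), c(test))) && stats::var(train) > 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = 2 * length(train) - 2),
               p.value = 1)
  } else {
    tt <- t.test(train, test, var.equal = FALSE)
  }
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 signif = ifelse(tt$p.value <= 0.05, "*", "ns"))
}

#' Nested cross-validation of GS models
#'
#' Outer folds hold out genotypes for testing; each training split fits
#' every requested model (LASSO tunes its penalty on the inner folds;
#' rrBLUP/gBLUP/RKHS estimate their shrinkage by REML; stacking learns its
#' meta-weights from inner out-of-fold base predictions), then predicts the
#' held-out genotypes. Reports, per model and N level, the SNP
#' heritability, GEBV means in the training and testing phases with a
#' bootstrap interval, genetic and error variances, accuracy r, the
#' learning-rate summary and the Welch test of train-vs-test GEBV means.
#'
#' @param phenotypes Tibble with genotype_id, n_level and the trait column.
#' @param genotypes QC'd (complete) dosage matrix aligned by genotype id.
#' @param models Character subset of `c("rrblup","gblup","lasso","bglr",
#'   "rkhs","svm","boost","bagg","stack")`.
#' @param plan A [cv_plan()].
#' @param trait Name of the trait column (default "NUE").
#' @param settings Per-model settings from [model_settings()].
#' @param mode `"nested"` (outer test folds, inner tuning) or
#'   `"independent"` (two separate K-fold CVs, the literal two-CV reading).
#' @return An `evaluation_report` tibble (one row per model x N level) with
#'   per-fold detail in `attr(, "folds")`.
#' @export
run_nested_cv <- function(phenotypes, genotypes, models, plan,
                          trait = "NUE", settings = model_settings(),
                          mode = c("nested", "independent")) {
  mode <- match.arg(mode)
  models <- match.arg(models, gs_model_names(), several.ok = TRUE)
  assert_that(all(c("genotype_id", "n_level", trait) %in% names(phenotypes)),
              "phenotypes must have genotype_id, n_level and the trait column")
  ids <- rownames(genotypes)
  assert_that(all(phenotypes$genotype_id %in% ids),
              "phenotypes and genotypes are not aligned")
  coded <- recode_centered(genotypes)
  G <- build_grm(coded)
  K <- build_gaussian_kernel(coded, settings$kernel_bandwidth)
  rows <- list()
  fold_rows <- list()
  for (lev in unique(phenotypes$n_level)) {
    ph <- phenotypes[phenotypes$n_level == lev, ]
    ph <- ph[match(ids, ph$genotype_id), ]
    y <- ph[[trait]]
    assign <- plan$assignment$outer_fold[match(ids, plan$assignment$genotype_id)]
    phase <- cv_phase(y, coded, G, K, models, assign, plan, settings,
                      lev)
    if (mode == "independent") {
      # literal two-CV reading: a separate inner_folds-fold CV supplies the
      # training-phase predictions
      assign10 <- local_rng(seed_stream(plan$seed, paste0("indep", lev)),
                            sample(rep_len(seq_len(plan$inner_folds),
                                           length(y))))
      phase_tr <- cv_phase(y, coded, G, K, models, assign10, plan,
                           settings, paste0(lev, "-train"))
    }
    for (m in models) {
      pm <- phase[[m]]
      train_gebv <- if (mode == "nested") pm$train_gebv else
        phase_tr[[m]]$test_pred
      acc_train <- if (mode == "nested") mean_na(pm$acc_train) else
        mean_na(phase_tr[[m]]$acc_test)
      boot <- bootstrap_gebv_mean(pm$test_pred, n_boot = settings$n_boot,
                                  seed = seed_stream(plan$seed, paste0("boot", m, lev)))
      cmp <- compare_train_test_means(train_gebv, pm$test_pred)
      rows[[length(rows) + 1]] <- tibble::tibble(
        model = m, n_level = lev,
        snp_h2 = mean_na(pm$h2), vg = mean_na(pm$vg), ve = mean_na(pm$ve),
        gebv_mean_train = mean(train_gebv),
        gebv_mean_test = mean(pm$test_pred),
        boot_gebv_mean = boot$boot_mean,
        boot_lower = boot$lower, boot_upper = boot$upper,
        accuracy_train = acc_train,
        accuracy_test = mean_na(pm$acc_test),
        learning_rate_min = model_learning_rate(m, settings),
        p_value = cmp$p_value, signif = cmp$signif
      )
      fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
        n_level = lev, model = m, fold = seq_along(pm$acc_test),
        acc_train = pm$acc_train, acc_test = pm$acc_test,
        h2 = pm$h2, vg = pm$vg, ve = pm$ve
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, folds = dplyr::bind_rows(fold_rows), plan = plan,
            mode = mode, class = c("evaluation_report", class(out)))
}

# One K-fold pass: fit on held-in folds, predict held-out genotypes.
cv_phase <- function(y, coded, G, K, models, assign, plan, settings, tag) {
  per_model <- lapply(models, function(m)
    list(test_pred = numeric(0), test_obs = numeric(0),
         train_gebv = numeric(0), acc_train = c(), acc_test = c(),
         vg = c(), ve = c(), h2 = c()))
  names(per_model) <- models
  for (f in sort(unique(assign))) {
    tr <- which(assign != f)
    te <- which(assign == f)
    if (length(te) < 2 || length(tr) < 2) abort("fold with < 2 genotypes")
    fits <- fit_gs_models(y[tr], coded[tr, , drop = FALSE],
                          G = G[tr, tr], K = K[tr, tr],
                          models = models, settings = settings,
                          inner_folds = plan$inner_folds,
                          seed = seed_stream(plan$seed, paste0("fold", f, tag)))
    for (m in models) {
      fit <- fits[[m]]
      pred <- predict_gs(fit, m, coded_new = coded[te, , drop = FALSE],
                         G_cross = G[te, tr, drop = FALSE],
                         K_cross = K[te, tr, drop = FALSE],
                         fits = fits)
      vc <- fit$vc %||% empirical_vc(fit)
      pm <- per_model[[m]]
      pm$test_pred <- c(pm$test_pred, pred)
      pm$test_obs <- c(pm$test_obs, y[te])
      pm$train_gebv <- c(pm$train_gebv, fit$gebv)
      pm$acc_train <- c(pm$acc_train, safe_cor(y[tr], fit$gebv))
      pm$acc_test <- c(pm$acc_test, safe_cor(y[te], pred))
      pm$vg <- c(pm$vg, vc$sigma2_a)
      pm$ve <- c(pm$ve, vc$sigma2_e)
      pm$h2 <- c(pm$h2, vc$h2)
      per_model[[m]] <- pm
    }
  }
  per_model
}

# fold mean that tolerates degenerate folds (all-NA stays NA)
mean_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}

# cor() that returns NA silently for constant vectors (e.g. a stack whose
# meta-weights are all zero on a no-signal fold)
safe_cor <- function(a, b) {
  if (stats::var(a) <= 0 || stats::var(b) <= 0) return(NA_real_)
  cor(a, b)
}

gs_model_names <- function() {
  c("rrblup", "gblup", "lasso", "bglr", "rkhs", "svm", "boost", "bagg",
    "stack")
}

#' Per-model settings for pipeline and cross-validation runs
#'
#' One place for every tunable the nine models expose. Defaults keep a
#' full nested-CV run of all models on a 221 x 2000 panel inside a few
#' minutes on one core (sizes discussed in the methods vignette).
#'
#' @param ... Overrides of the defaults.
#' @return Named list of settings.
#' @export
model_settings <- function(...) {
  defaults <- list(
    kernel_bandwidth = "median",
    lasso_n_lambda = 15, lasso_min_ratio = 0.05,
    bglr_n_iter = 1500, bglr_burn_in = 500,
    svm_epsilon = NULL, svm_C = NULL,
    boost_rounds = 40, boost_rate = 0.1, boost_depth = 2,
    boost_schedule = FALSE, boost_alpha0 = 1,
    bagg_bags = 40, bagg_depth = 3,
    stack_oof_folds = 3, stack_epsilon = 0, stack_bases = NULL,
    n_boot = 500
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  assert_that(!length(unknown),
              paste("unknown settings:", paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, overrides)
}

model_learning_rate <- function(model, settings) {
  # decaying-schedule models report the schedule minimum; constant-rate
  # models their constant
  if (model == "boost" && settings$boost_schedule)
    learning_rate_schedule(settings$boost_alpha0, settings$boost_rounds - 1)$minimum
  else if (model == "boost") settings$boost_rate
  else NA_real_
}

empirical_vc <- function(fit) {
  s2a <- stats::var(fit$gebv)
  s2e <- stats::var(fit$residuals)
  structure(list(sigma2_a = s2a, sigma2_e = s2e,
                 h2 = if (s2a + s2e > 0) s2a / (s2a + s2e) else NA_real_,
                 lambda = if (s2a > 0) s2e / s2a else NA_real_),
            class = "variance_components")
}

# Fit the requested models on one training split.
fit_gs_models <- function(y, coded, G, K, models, settings, inner_folds,
                          seed) {
  fits <- list()
  base_models <- setdiff(models, "stack")
  if ("stack" %in% models && length(base_models) < 2)
    abort("stacking needs at least 2 base models in `models`")
  for (m in base_models)
    fits[[m]] <- fit_one_gs(m, y, coded, G, K, settings, inner_folds, seed)
  if ("stack" %in% models) {
    bases <- settings$stack_bases %||% base_models
    # the OOF sub-fits reuse the hyper-parameters already tuned on this
    # training split (penalties from REML/inner CV), so stacking adds three
    # cheap refits per base instead of three tuning runs
    fixed <- lapply(fits, function(f) f$regularization)
    oof <- stack_oof(y, coded, G, K, bases, settings, inner_folds, seed,
                     fixed = fixed)
    base_gebv <- vapply(bases, function(m) unname(fits[[m]]$gebv),
                        numeric(length(y)))
    fits$stack <- fit_stacking(y, oof, base_gebv = base_gebv,
                               epsilon = settings$stack_epsilon)
  }
  fits
}

fit_one_gs <- function(model, y, coded, G, K, settings, inner_folds, seed,
                       fixed = NULL) {
  fx <- fixed[[model]]
  switch(model,
    rrblup = fit_rrblup(y, coded, lambda = fx$lambda),
    gblup = fit_gblup(y, G, lambda = fx$lambda),
    lasso = if (!is.null(fx$lambda)) fit_lasso(y, coded, lambda = fx$lambda)
            else fit_lasso(y, coded, cv_folds = inner_folds,
                           n_lambda = settings$lasso_n_lambda,
                           lambda_min_ratio = settings$lasso_min_ratio,
                           seed = seed),
    bglr = fit_bayesian_ridge(y, coded, n_iter = settings$bglr_n_iter,
                              burn_in = settings$bglr_burn_in, seed = seed),
    rkhs = fit_rkhs(y, K, lambda = fx$lambda),
    svm = fit_svr(y, K, epsilon = settings$svm_epsilon, C = settings$svm_C,
                  seed = seed),
    boost = fit_boosting(y, coded, learning_rate = settings$boost_rate,
                         n_rounds = settings$boost_rounds,
                         max_depth = settings$boost_depth,
                         schedule = settings$boost_schedule,
                         alpha0 = settings$boost_alpha0),
    bagg = fit_bagging(y, coded, n_bags = settings$bagg_bags,
                       max_depth = settings$bagg_depth, seed = seed)
  )
}

# Out-of-fold predictions of the base models inside one training split.
stack_oof <- function(y, coded, G, K, bases, settings, inner_folds, seed,
                      fixed = NULL) {
  n <- length(y)
  k <- min(settings$stack_oof_folds, n - 1)
  folds <- local_rng(seed_stream(seed, "stack-oof"),
                     sample(rep_len(seq_len(k), n)))
  oof <- matrix(NA_real_, n, length(bases),
                dimnames = list(NULL, bases))
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    fits <- list()
    for (m in bases)
      fits[[m]] <- fit_one_gs(m, y[tr], coded[tr, , drop = FALSE],
                              G[tr, tr], K[tr, tr], settings,
                              inner_folds = max(2, min(inner_folds, sum(tr) - 1)),
                              seed = seed_stream(seed, paste0("oof", f)),
                              fixed = fixed)
    for (m in bases)
      oof[te, m] <- predict_gs(fits[[m]], m,
                               coded_new = coded[te, , drop = FALSE],
                               G_cross = G[te, tr, drop = FALSE],
                               K_cross = K[te, tr, drop = FALSE],
                               fits = fits)
  }
  oof
}

# Route a model to the right prediction inputs.
predict_gs <- function(fit, model, coded_new, G_cross, K_cross, fits = NULL) {
  switch(model,
    rrblup = , lasso = , bglr = , boost = , bagg =
      predict(fit, coded_new),
    gblup = predict(fit, G_cross),
    rkhs = , svm = predict(fit, K_cross),
    stack = {
      bases <- names(fit$training_meta$weights)
      base_preds <- vapply(bases, function(m)
        predict_gs(fits[[m]], m, coded_new, G_cross, K_cross),
        numeric(nrow(coded_new)))
      if (!is.matrix(base_preds))
        base_preds <- matrix(base_preds, nrow = nrow(coded_new),
                             dimnames = list(NULL, bases))
      predict(fit, base_preds)
    }
  )
}
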