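#' Null resampling of SNP effects
#'
#' Standardizes a model's marker effects (zero mean, unit variance), then
#' resamples the standardized pool with replacement `n_resamples` times and
#' returns, per marker position, the standard error (standard deviation
#' across resamples) of the resampled effect distribution -- the N(0, 1)
#' null reference the pairwise model comparison screens against. A
#' degenerate effect vector (all equal) standardizes to zeros and yields a
#' zero SE vector.
#'
#' @param effects Per-marker effect vector (>= 10 markers), or a `gs_fit`
#'   carrying marker effects.
#' @param n_resamples Resampling draws (default 2000).
#' @param seed Resampling seed.
#' @return Named numeric vector of per-marker standard errors.
#' @export
null_effect_resampling <- function(effects, n_resamples = 2000, seed = 1) {
  if (inherits(effects, "gs_fit")) effects <- marker_effects(effects)
  assert_that(is.numeric(effects) && length(effects) >= 10,
              "need at least 10 marker effects")
  m <- length(effects)
  s <- sd(effects)
  z <- if (s > 0) (effects - mean(effects)) / s else rep(0, m)
  local_rng(seed_stream(seed, "null-resampling"), {
    draws <- matrix(sample(z, m * n_resamples, replace = TRUE), m,
                    n_resamples)
    out <- apply(draws, 1, sd)
    names(out) <- names(effects)
    out
  })
}

# Two-sided p-values of standardized effects against the N(0, 1) null.
effect_null_pvalues <- function(effects) {
  s <- sd(effects)
  z <- if (s > 0) (effects - mean(effects)) / s else rep(0, length(effects))
  2 * pnorm(-abs(z))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level q: adjusted p-values are monotone in rank
#' and hypotheses with adjusted p <= q are rejected.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List: `reject` (logical mask), `p_adjusted`, `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  assert_that(is.numeric(p_values) && all(is.finite(p_values)) &&
                all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  assert_that(is_prob(q), "q must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, q = q)
}

#' Adaptive standard error of prediction for pairwise model comparison
#'
#' For every pair of fitted models sharing a test partition, computes the
#' bootstrap standard error of the mean paired difference in squared
#' prediction errors -- but only after an FDR screen: the two models'
#' standardized marker-effect profiles are tested against the N(0, 1) null
#' ([null_effect_resampling()] supplies the reference; two-sided normal
#' p-values, Benjamini-Hochberg at `fdr`). Pairs in which neither model
#' shows any effect signal beyond the null are reported with a zero raw
#' adaptive SE (indistinguishable from noise). Raw values, including the
#' zero self-comparisons, are min-max normalized to [-0.2, 1].
#'
#' @param predictions Named list of per-model test-set prediction vectors,
#'   aligned to `observed`.
#' @param observed Observed test-set phenotypes.
#' @param effects Named list of per-model marker-effect vectors (native or
#'   back-projected; see [marker_effects()]).
#' @param fdr FDR level of the screen (default 0.05).
#' @param n_resamples Bootstrap resamples for the SE (default 2000).
#' @param seed Seed.
#' @return A `comparison_matrix`: list with `raw` and `normalized` square
#'   matrices, the pairwise `p_value` matrix, `screen` (per-model signal
#'   indicator), bounds and settings.
#' @export
adaptive_se_matrix <- function(predictions, observed, effects,
                               fdr = 0.05, n_resamples = 2000, seed = 1) {
  assert_that(is.list(predictions) && length(predictions) >= 2,
              "need predictions from at least 2 models")
  labels <- names(predictions)
  assert_that(!is.null(labels) && all(nzchar(labels)),
              "predictions must be a named list")
  n <- length(observed)
  assert_that(n >= 3 && all(vapply(predictions, length, 1L) == n),
              "no common test genotypes")
  assert_that(is.list(effects) && setequal(names(effects), labels),
              "effects must be named like predictions")
  has_signal <- vapply(labels, function(l) {
    any(bh_fdr(effect_null_pvalues(effects[[l]]), q = fdr)$reject)
  }, logical(1))
  m <- length(labels)
  raw <- matrix(0, m, m, dimnames = list(labels, labels))
  pmat <- matrix(1, m, m, dimnames = list(labels, labels))
  local_rng(seed_stream(seed, "adaptive-se"), {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- (observed - predictions[[i]])^2 -
        (observed - predictions[[j]])^2
      if ((has_signal[i] || has_signal[j]) && sd(d) > 0) {
        boots <- vapply(seq_len(n_resamples), function(b)
          mean(d[sample.int(n, n, replace = TRUE)]), numeric(1))
        se <- sd(boots)
        raw[i, j] <- raw[j, i] <- se
        pmat[i, j] <- pmat[j, i] <-
          if (se > 0) 2 * pnorm(-abs(mean(d)) / se) else as.numeric(mean(d) == 0)
      }
    }
  })
  lo <- -0.2
  hi <- 1
  rng <- range(raw)
  normalized <- if (diff(rng) > 0)
    lo + (hi - lo) * (raw - rng[1]) / diff(rng)
  else matrix(lo, m, m, dimnames = dimnames(raw))
  structure(list(raw = raw, normalized = normalized, p_value = pmat,
                 screen = has_signal, bounds = c(lo, hi),
                 n_resamples = n_resamples, fdr_threshold = fdr),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("Adaptive SE of prediction,", nrow(x$raw), "models;",
      "normalized to [", x$bounds[1], ",", x$bounds[2], "]\n")
  print(round(x$normalized, 3))
  invisible(x)
}

#' Pairwise difference declarations from a comparison matrix
#'
#' Applies Benjamini-Hochberg at level `q` to the pairwise p-values of the
#' adaptive-SE comparison and reports which model pairs are declared to
#' predict differently.
#'
#' @param cmp A `comparison_matrix`.
#' @param q FDR level.
#' @return Tibble with one row per unordered pair: `model_a`, `model_b`,
#'   `p_value`, `p_adjusted`, `different`.
#' @export
declare_differences <- function(cmp, q = 0.05) {
  assert_that(inherits(cmp, "comparison_matrix"),
              "cmp must be a comparison_matrix")
  labels <- rownames(cmp$p_value)
  pairs <- utils::combn(seq_along(labels), 2)
  p <- cmp$p_value[t(pairs)]
  adj <- bh_fdr(p, q)
  tibble::tibble(model_a = labels[pairs[1, ]],
                 model_b = labels[pairs[2, ]],
                 p_value = p, p_adjusted = adj$p_adjusted,
                 different = adj$reject)
}
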