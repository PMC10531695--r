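#' Per-marker minor allele frequency
#'
#' Folded allele frequency per marker: with `f` the alternate-allele
#' frequency (sum of non-missing dosages over twice the non-missing count),
#' MAF = min(f, 1 - f). Missing calls are excluded from numerator and
#' denominator. All-missing markers get `NA` (they fall to the call-rate
#' filter in [apply_qc()]).
#'
#' @param G Dosage matrix (genotypes x markers, values 0/1/2/NA).
#' @return Named numeric vector of MAFs in [0, 0.5].
#' @export
compute_maf <- function(G) {
  f <- alt_allele_freq(G)
  pmin(f, 1 - f)
}

alt_allele_freq <- function(G) {
  assert_that(is.matrix(G), "G must be a matrix")
  n_called <- colSums(!is.na(G))
  f <- colSums(G, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0] <- NA_real_
  f
}

#' Hardy-Weinberg equilibrium chi-square per marker
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the observed genotype
#' counts (n0, n1, n2) against the p^2, 2pq, q^2 expectations, with p the
#' unfolded alternate-allele frequency of the marker. Monomorphic markers
#' (p in {0, 1}) have an expected count of zero and are reported as `NA`.
#'
#' @param G Dosage matrix (0/1/2/NA).
#' @return Tibble with `marker_id`, `chisq`, `p_value`.
#' @export
hwe_chisq <- function(G) {
  assert_that(is.matrix(G), "G must be a matrix")
  n0 <- colSums(G == 0, na.rm = TRUE)
  n1 <- colSums(G == 1, na.rm = TRUE)
  n2 <- colSums(G == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  exp0 <- n * q^2
  exp1 <- n * 2 * p * q
  exp2 <- n * p^2
  chisq <- (n0 - exp0)^2 / exp0 + (n1 - exp1)^2 / exp1 + (n2 - exp2)^2 / exp2
  chisq[n == 0 | p == 0 | p == 1] <- NA_real_
  tibble::tibble(
    marker_id = colnames(G) %||% marker_ids(ncol(G)),
    chisq = unname(chisq),
    p_value = stats::pchisq(unname(chisq), df = 1, lower.tail = FALSE)
  )
}

#' Marker quality control
#'
#' Applies, in order, the minor-allele-frequency filter (inclusive: markers
#' with MAF <= `maf_threshold` are removed), the Hardy-Weinberg screen
#' (markers with HWE p < `hwe_alpha` removed) and the call-rate filter
#' (markers called in fewer than `min_call_rate` of genotypes removed). The
#' removal reason recorded per marker is the first failing rule in that
#' order, so the report counts add up without double counting. Remaining
#' missing dosages are imputed by the per-marker mean, yielding a complete
#' numeric matrix for the linear algebra downstream.
#'
#' @param G Dosage matrix (0/1/2/NA).
#' @param maf_threshold Remove markers with MAF <= this value (default 0.05).
#' @param hwe_alpha HWE p-value cutoff (default 1e-4); set to 0 to disable.
#' @param min_call_rate Minimum fraction of non-missing calls (default 0.95).
#' @return List with `genotypes` (filtered, mean-imputed numeric matrix) and
#'   `report` (class `qc_report`: totals plus a per-marker tibble).
#' @export
apply_qc <- function(G, maf_threshold = 0.05, hwe_alpha = 1e-4,
                     min_call_rate = 0.95) {
  assert_that(is.matrix(G), "G must be a matrix")
  assert_that(is.numeric(maf_threshold) && length(maf_threshold) == 1 &&
                maf_threshold >= 0 && maf_threshold < 0.5,
              "maf_threshold must lie in [0, 0.5)")
  assert_that(is_prob(hwe_alpha), "hwe_alpha must lie in [0, 1]")
  assert_that(is_prob(min_call_rate), "min_call_rate must lie in [0, 1]")
  if (is.null(colnames(G))) colnames(G) <- marker_ids(ncol(G))
  maf <- compute_maf(G)
  hwe <- hwe_chisq(G)
  call_rate <- colMeans(!is.na(G))
  fail_maf <- !is.na(maf) & maf <= maf_threshold
  fail_hwe <- !is.na(hwe$p_value) & hwe$p_value < hwe_alpha
  fail_cr <- call_rate < min_call_rate
  removed_by <- rep(NA_character_, ncol(G))
  removed_by[fail_cr] <- "call_rate"
  removed_by[fail_hwe] <- "hwe"
  removed_by[fail_maf] <- "maf" # first rule wins: assigned last, overwrites
  keep <- is.na(removed_by)
  if (!any(keep)) abort("quality control removed every marker (empty panel)")
  per_marker <- tibble::tibble(
    marker_id = colnames(G),
    maf = unname(maf),
    hwe_chisq = hwe$chisq,
    hwe_p = hwe$p_value,
    call_rate = unname(call_rate),
    removed_by = removed_by
  )
  report <- structure(list(
    n_markers_in = ncol(G),
    n_removed_maf = sum(removed_by == "maf", na.rm = TRUE),
    n_removed_hwe = sum(removed_by == "hwe", na.rm = TRUE),
    n_removed_callrate = sum(removed_by == "call_rate", na.rm = TRUE),
    n_markers_out = sum(keep),
    maf_threshold = maf_threshold, hwe_alpha = hwe_alpha,
    min_call_rate = min_call_rate,
    per_marker = per_marker
  ), class = "qc_report")
  list(genotypes = impute_marker_mean(G[, keep, drop = FALSE]),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC:", x$n_markers_in, "in ->", x$n_markers_out, "out\n")
  cat("  removed by MAF <=", x$maf_threshold, ":", x$n_removed_maf, "\n")
  cat("  removed by HWE p <", x$hwe_alpha, ":", x$n_removed_hwe, "\n")
  cat("  removed by call rate <", x$min_call_rate, ":",
      x$n_removed_callrate, "\n")
  invisible(x)
}

#' Centered (-1, 0, 1) marker coding
#'
#' Maps dosages 0/1/2 to -1/0/+1 (dosage minus one), the coding used by the
#' linear GS models. Requires a complete matrix (run [apply_qc()] first);
#' mean-imputed entries map to intermediate values on the same scale.
#'
#' @param G Complete dosage matrix.
#' @return Numeric matrix in [-1, 1].
#' @export
recode_centered <- function(G) {
  assert_that(is.matrix(G), "G must be a matrix")
  if (anyNA(G)) abort("missing values present; apply QC/imputation first")
  G - 1
}
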