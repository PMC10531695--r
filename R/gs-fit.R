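#' @title Fitted GS model container
#' @description Internal constructor shared by all nine GS predictors. Every
#'   fit stores the training GEBVs, the intercept, marker effects where the
#'   model defines them, variance components where estimated, the
#'   regularization scalars actually used, training metadata (iterations,
#'   learning-rate trace, seed) and training residuals.
#' @keywords internal
new_gs_fit <- function(model, y, gebv, intercept,
                       marker_effects = NULL, vc = NULL,
                       regularization = list(), training_meta = list(),
                       ...) {
  fit <- list(
    model = model,
    gebv = gebv,
    intercept = intercept,
    marker_effects = marker_effects,
    vc = vc,
    regularization = regularization,
    training_meta = training_meta,
    residuals = y - intercept - gebv,
    ...
  )
  structure(fit, class = c(paste0("gs_", model), "gs_fit"))
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("<gs_fit: %s> n = %d, intercept = %.4g\n",
              x$model, length(x$gebv), x$intercept))
  if (length(x$regularization))
    cat("  regularization:",
        paste(names(x$regularization),
              signif(unlist(x$regularization), 4), sep = " = ",
              collapse = ", "), "\n")
  if (!is.null(x$vc))
    cat(sprintf("  h2 = %.3f (sigma2_a = %.4g, sigma2_e = %.4g)\n",
                x$vc$h2, x$vc$sigma2_a, x$vc$sigma2_e))
  invisible(x)
}

#' Fitted values of a GS model on its training set
#' @param object A `gs_fit`.
#' @param ... Unused.
#' @export
fitted.gs_fit <- function(object, ...) object$intercept + object$gebv

#' Marker effects or ridge back-projected pseudo-effects
#'
#' Linear and Bayesian models carry marker effects directly. Kernel and
#' ensemble models predict at the genotype level only; for analyses that
#' need a per-marker profile (the null-resampling error comparison), their
#' GEBVs are back-projected onto the coded marker matrix by a light ridge
#' solve, beta = X' (X X' + eta I)^-1 gebv.
#'
#' @param fit A `gs_fit`.
#' @param X Coded marker matrix used for back-projection when the model has
#'   no native marker effects.
#' @param eta Ridge used in the back-projection (relative to the mean
#'   diagonal of X X').
#' @return Named numeric vector of per-marker effects.
#' @export
marker_effects <- function(fit, X = NULL, eta = 1e-3) {
  assert_that(inherits(fit, "gs_fit"), "fit must be a gs_fit")
  if (!is.null(fit$marker_effects)) return(fit$marker_effects)
  assert_that(is.matrix(X) && nrow(X) == length(fit$gebv),
              "X needed to back-project pseudo-effects for this model")
  M <- tcrossprod(X)
  ridge <- eta * mean(diag(M))
  a <- solve(M + diag(ridge, nrow(M)), fit$gebv)
  beta <- drop(crossprod(X, a))
  names(beta) <- colnames(X)
  beta
}
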