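# Prediction for new genotypes. Linear/Bayesian models take coded marker
# rows; kernel models take cross-kinship/kernel rows against the training
# set; ensembles apply their fitted trees; stacking composes base
# predictions. All methods return GEBVs (add the intercept for phenotype
# scale predictions).

check_markers <- function(fit_names, new_names) {
  if (is.null(fit_names) || is.null(new_names)) return(invisible(TRUE))
  missing <- setdiff(fit_names, new_names)
  if (length(missing))
    abort(paste0("newdata lacks training markers: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5)))
  invisible(TRUE)
}

#' Predict GEBVs for new genotypes
#'
#' @param object A `gs_fit`.
#' @param newdata Coded marker rows (linear, Bayesian and ensemble models),
#'   cross-kernel/relationship rows against the training genotypes (kernel
#'   models), or a matrix of base-model predictions (stacking).
#' @param ... Unused.
#' @return Named numeric vector of GEBVs for the new genotypes.
#' @export
predict.gs_rrblup <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_markers(names(object$marker_effects), colnames(newdata))
  if (!is.null(colnames(newdata)) && !is.null(names(object$marker_effects)))
    newdata <- newdata[, names(object$marker_effects), drop = FALSE]
  drop(newdata %*% object$marker_effects)
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_lasso <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_markers(names(object$marker_effects), colnames(newdata))
  if (!is.null(colnames(newdata)) && !is.null(names(object$marker_effects)))
    newdata <- newdata[, names(object$marker_effects), drop = FALSE]
  Xc <- sweep(newdata, 2, object$training_meta$x_center)
  drop(Xc %*% object$marker_effects)
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_bglr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_markers(names(object$marker_effects), colnames(newdata))
  if (!is.null(colnames(newdata)) && !is.null(names(object$marker_effects)))
    newdata <- newdata[, names(object$marker_effects), drop = FALSE]
  Xc <- sweep(newdata, 2, object$training_meta$x_center)
  drop(Xc %*% object$marker_effects)
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_gblup <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata) # rows: new genotypes x training genotypes
  drop(newdata %*% object$training_meta$dual_coef)
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_rkhs <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$training_meta$alpha)
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$training_meta$beta)
}

predict_trees <- function(trees, newdata) {
  preds <- vapply(trees, function(tr) {
    if (is.numeric(tr)) rep(tr, nrow(newdata))
    else predict_marker_tree(tr, newdata)
  }, numeric(nrow(newdata)))
  if (!is.matrix(preds)) preds <- matrix(preds, nrow = nrow(newdata))
  preds
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_boost <- function(object, newdata, ...) {
  preds <- predict_trees(object$training_meta$trees, as.matrix(newdata))
  out <- drop(preds %*% object$training_meta$rates)
  names(out) <- rownames(newdata)
  out
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_bagg <- function(object, newdata, ...) {
  preds <- predict_trees(object$training_meta$trees, as.matrix(newdata))
  out <- rowMeans(preds)
  names(out) <- rownames(newdata)
  out
}

#' @rdname predict.gs_rrblup
#' @export
predict.gs_stack <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  w <- object$training_meta$weights
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(names(w), colnames(newdata))
    if (length(missing))
      abort(paste("newdata lacks base-model columns:",
                  paste(missing, collapse = ", ")))
    newdata <- newdata[, names(w), drop = FALSE]
  }
  drop(newdata %*% w)
}
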