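# Depth-limited regression trees specialised for coded marker columns.
# Marker dosages take three levels (-1, 0, 1; mean-imputed values in
# between), so candidate splits are the two thresholds between levels and
# the exhaustive variance-reduction search over all markers reduces to two
# crossprod() calls per node. That makes a tree fit a few milliseconds on
# thousands of markers, which is what lets boosting and bagging run whole
# panels without feature subsampling, and it is deterministic.

fit_marker_tree <- function(X, y, max_depth, minsplit = 5, minbucket = 2,
                            thresholds = c(-0.5, 0.5)) {
  grow <- function(idx, depth) {
    n <- length(idx)
    mu <- mean(y[idx])
    if (depth >= max_depth || n < minsplit) return(list(value = mu))
    Xs <- X[idx, , drop = FALSE]
    ys <- y[idx]
    S <- sum(ys)
    base <- S^2 / n
    best <- list(score = base + 1e-12)
    for (t in thresholds) {
      L <- Xs <= t
      nL <- colSums(L)
      SL <- drop(crossprod(L, ys))
      ok <- nL >= minbucket & (n - nL) >= minbucket
      if (!any(ok)) next
      score <- rep(-Inf, ncol(Xs))
      score[ok] <- SL[ok]^2 / nL[ok] + (S - SL[ok])^2 / (n - nL[ok])
      j <- which.max(score)
      if (score[j] > best$score) best <- list(score = score[j], var = j, t = t)
    }
    if (is.null(best$var)) return(list(value = mu))
    go_left <- Xs[, best$var] <= best$t
    list(var = best$var, t = best$t,
         left = grow(idx[go_left], depth + 1),
         right = grow(idx[!go_left], depth + 1))
  }
  structure(grow(seq_along(y), 0), class = "marker_tree")
}

predict_marker_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (!is.null(node$value)) {
      out[idx] <<- node$value
      return(invisible())
    }
    go_left <- X[idx, node$var] <= node$t
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(tree, seq_len(nrow(X)))
  out
}
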