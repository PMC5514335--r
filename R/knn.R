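# Exact weighted k-nearest-neighbour classifier used by every subspace of
# the ensemble. Distances are Euclidean after per-feature min-max scaling
# fit on the training data only. Votes are inverse-distance weighted by
# default; a query sitting exactly on training points is decided by the
# majority label among its zero-distance neighbours. All ties break to the
# negative class (conservative for interaction calls).

.fit_scaler <- function(x) {
  mins <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - mins
  rng[rng == 0 | !is.finite(rng)] <- 1  # degenerate features pass through
  list(min = mins, range = rng)
}

.apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$min, "-"), 2L, scaler$range, "/")
}

# squared Euclidean distances between rows of q (m x p) and rows of x (n x p)
.cross_dist2 <- function(q, x) {
  d2 <- outer(rowSums(q^2), rowSums(x^2), "+") - 2 * tcrossprod(q, x)
  d2[d2 < 0] <- 0
  d2
}

# one weighted vote from a vector of distances to all training points
.knn_vote <- function(d, y, k, weighting) {
  zero <- which(d < .Machine$double.eps^0.5)
  if (length(zero) && weighting == "inverse") {
    score <- mean(y[zero] == 1L)
    return(c(label = as.numeric(score > 0.5), score = score))
  }
  ord <- order(d, seq_along(d))  # index tie-break keeps ordering deterministic
  nb <- ord[seq_len(min(k, length(d)))]
  w <- if (weighting == "inverse") 1 / d[nb] else rep(1, length(nb))
  score <- sum(w[y[nb] == 1L]) / sum(w)
  c(label = as.numeric(score > 0.5), score = score)
}

#' Fit a weighted kNN classifier
#'
#' Stores min-max-scaled training vectors for exact neighbour search.
#'
#' @param x Numeric training matrix (instances x features).
#' @param y Binary labels (0/1), one per row of `x`.
#' @param k Number of neighbours; must not exceed `nrow(x)`.
#' @param weighting `"inverse"` (1/distance, default) or `"uniform"`.
#' @param scale Fit a per-feature min-max scaler on `x` (default `TRUE`).
#' @return Object of class `knn_model`.
#' @export
knn_fit <- function(x, y, k, weighting = c("inverse", "uniform"), scale = TRUE) {
  weighting <- match.arg(weighting)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) < 2L) stop("need at least two training instances")
  if (length(y) != nrow(x)) stop("labels do not match training rows")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) stop("k must lie in 1..", nrow(x))
  scaler <- if (scale) .fit_scaler(x) else list(min = rep(0, ncol(x)),
                                                range = rep(1, ncol(x)))
  structure(
    list(x = .apply_scaler(x, scaler), y = y, k = k,
         weighting = weighting, scaler = scaler),
    class = "knn_model"
  )
}

#' Predict with a fitted kNN classifier
#'
#' @param object A `knn_model`.
#' @param newx Query matrix (or single vector) in the model's original
#'   feature space; the training scaler is applied.
#' @param ... Ignored.
#' @return data.frame with `label` (0/1) and `score` (positive-class weight
#'   fraction in the neighbour vote).
#' @export
predict.knn_model <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  if (ncol(newx) != ncol(object$x)) {
    stop("query has ", ncol(newx), " features, model expects ", ncol(object$x))
  }
  q <- .apply_scaler(newx, object$scaler)
  d <- sqrt(.cross_dist2(q, object$x))
  res <- t(apply(d, 1L, .knn_vote, y = object$y, k = object$k,
                 weighting = object$weighting))
  data.frame(label = as.integer(res[, "label"]), score = res[, "score"])
}

# leave-one-out accuracies over a set of k candidates, from one distance
# matrix; all candidates share one neighbour ordering per point, so the
# votes come from cumulative weight sums. Returns a named vector acc[k].
.loo_accuracy_grid <- function(x, y, k_candidates, weighting) {
  n <- nrow(x)
  d <- sqrt(.cross_dist2(x, x))
  diag(d) <- Inf
  kmax <- min(max(k_candidates), n - 1L)
  pos <- y == 1L
  eps <- .Machine$double.eps^0.5
  correct <- matrix(0L, nrow = n, ncol = length(k_candidates))
  for (i in seq_len(n)) {
    dv <- d[i, ]
    zero <- dv < eps
    if (weighting == "inverse" && any(zero)) {
      lab <- as.numeric(mean(y[zero] == 1L) > 0.5)
      correct[i, ] <- as.integer(lab == y[i])
      next
    }
    ord <- order(dv, seq_along(dv))[seq_len(kmax)]
    w <- if (weighting == "inverse") 1 / dv[ord] else rep(1, kmax)
    cw <- cumsum(w)
    cwp <- cumsum(w * pos[ord])
    ks <- pmin(k_candidates, kmax)
    sc <- cwp[ks] / cw[ks]
    correct[i, ] <- as.integer((sc > 0.5) == pos[i])
  }
  stats::setNames(colMeans(correct), k_candidates)
}

#' Leave-one-out accuracy of a kNN configuration
#'
#' @param x,y Training matrix and 0/1 labels.
#' @param k Number of neighbours.
#' @param weighting Vote weighting, see [knn_fit()].
#' @param scale Apply min-max scaling (fit on all of `x`).
#' @return Fraction of instances whose held-out prediction matches their
#'   label.
#' @export
knn_loo_accuracy <- function(x, y, k, weighting = c("inverse", "uniform"),
                             scale = TRUE) {
  weighting <- match.arg(weighting)
  x <- as.matrix(x); y <- as.integer(y)
  if (scale) x <- .apply_scaler(x, .fit_scaler(x))
  unname(.loo_accuracy_grid(x, y, k, weighting))
}

#' Choose the number of neighbours by internal cross-validation
#'
#' Evaluates every candidate `k` by leave-one-out (default) or by
#' stratified V-fold cross-validation on the training data and returns the
#' candidate with the highest accuracy; ties break to the smallest `k`.
#' The default candidate grid is the odd values `1, 3, ..., 2*ceil(sqrt(n))+1`.
#'
#' @param x,y Training matrix and 0/1 labels (both classes required).
#' @param k_candidates Integer vector of candidate neighbour counts.
#' @param method `"loo"` (default) or `"cv"`.
#' @param folds Number of folds when `method = "cv"`.
#' @param seed Seed for the fold assignment when `method = "cv"`; unused
#'   for leave-one-out, which is deterministic.
#' @param weighting Vote weighting, see [knn_fit()].
#' @param scale Apply min-max scaling (fit on all of `x`).
#' @return The selected `k` (integer); the full accuracy grid is attached
#'   as attribute `"accuracy"`.
#' @export
select_k <- function(x, y, k_candidates = NULL, method = c("loo", "cv"),
                     folds = 5L, seed = NULL,
                     weighting = c("inverse", "uniform"), scale = TRUE) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  x <- as.matrix(x); y <- as.integer(y)
  n <- nrow(x)
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  if (min(table(y)) < 2L) stop("need at least two instances per class")
  if (is.null(k_candidates)) {
    k_max <- 2L * as.integer(ceiling(sqrt(n))) + 1L
    k_candidates <- seq(1L, min(k_max, n - 1L), by = 2L)
  }
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (!length(k_candidates)) stop("empty k candidate set")
  if (max(k_candidates) > n - 1L) stop("k candidates exceed n - 1 usable neighbours")
  if (scale) x <- .apply_scaler(x, .fit_scaler(x))
  acc <- if (method == "loo") {
    .loo_accuracy_grid(x, y, k_candidates, weighting)
  } else {
    if (!is.null(seed)) set.seed(seed)
    fold_id <- kfold_assign(y, k = folds)
    correct <- numeric(length(k_candidates))
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f; te <- fold_id == f
      if (length(unique(y[tr])) < 2L) stop("single-class training fold in select_k")
      d <- sqrt(.cross_dist2(x[te, , drop = FALSE], x[tr, , drop = FALSE]))
      for (ci in seq_along(k_candidates)) {
        kk <- min(k_candidates[ci], sum(tr))
        pred <- apply(d, 1L, function(dr) .knn_vote(dr, y[tr], kk, weighting)[["label"]])
        correct[ci] <- correct[ci] + sum(pred == y[te])
      }
    }
    stats::setNames(correct / n, k_candidates)
  }
  best <- k_candidates[which.max(acc)]  # which.max returns the first (smallest k)
  attr(best, "accuracy") <- acc
  best
}
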