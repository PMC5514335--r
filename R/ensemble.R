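# The classifier grid: one kNN per (protein-component, drug-group) feature
# subspace, combined by a unanimity (default) or majority vote.

#' Build the grid of feature subspaces
#'
#' Each subspace joins the descriptor group `Fd_j` (drug block of the pair
#' vector) with the component feature group `Ft_i` (protein block, offset
#' by the descriptor count). With `n_pca = 7` protein components, 10
#' fragments and 1444 descriptors this yields 49 subspaces, 42 of them with
#' 206 + 200 = 406 features (the last descriptor group absorbs the
#' 2-descriptor remainder).
#'
#' @param n_pca Number of protein principal components; also the number of
#'   descriptor groups, so the grid is `n_pca` x `n_pca`.
#' @param n_frag Number of protein sequence fragments.
#' @param d_dim Number of drug descriptors (used to build a partition when
#'   none is given).
#' @param partition Optional [partition_descriptors()] result; its group
#'   count must equal `n_pca`.
#' @return List of `n_pca^2` subspaces, each a list with `i` (protein
#'   component), `j` (drug group) and strictly increasing `feature_indices`
#'   into the pair vector; ordered row-major (i outer, j inner).
#' @export
build_subspaces <- function(n_pca, n_frag, d_dim = NULL, partition = NULL) {
  n_pca <- as.integer(n_pca)
  if (is.null(partition)) {
    if (is.null(d_dim)) stop("give d_dim or a descriptor partition")
    partition <- partition_descriptors(d_dim, n_pca)
  }
  if (nrow(partition) != n_pca) {
    stop("descriptor partition has ", nrow(partition),
         " groups but n_pca = ", n_pca)
  }
  d_dim <- partition[nrow(partition), "end"]
  out <- vector("list", n_pca^2)
  idx <- 0L
  for (i in seq_len(n_pca)) {
    ft <- d_dim + component_feature_group(n_pca, n_frag, i)
    for (j in seq_len(n_pca)) {
      idx <- idx + 1L
      out[[idx]] <- list(i = i, j = j,
                         feature_indices = c(partition_group(partition, j), ft))
    }
  }
  out
}

#' Fit one subspace kNN classifier
#'
#' Projects the pair vectors onto the subspace's features, fits the
#' min-max scaler there, selects `k` by leave-one-out if not fixed, and
#' stores the training data for exact neighbour search.
#'
#' @param pairs A `pair_set` (training instances).
#' @param subspace One element of [build_subspaces()].
#' @param k Fixed neighbour count, or `NULL` to select by [select_k()].
#' @param k_candidates Candidate grid forwarded to [select_k()].
#' @param weighting Vote weighting, see [knn_fit()].
#' @return A `knn_model` with the subspace stored as attribute
#'   `"subspace"`.
#' @export
fit_subspace_knn <- function(pairs, subspace, k = NULL, k_candidates = NULL,
                             weighting = c("inverse", "uniform")) {
  weighting <- match.arg(weighting)
  if (!length(subspace$feature_indices)) stop("empty feature subspace")
  if (max(subspace$feature_indices) > ncol(pairs$x)) {
    stop("subspace indices exceed pair vector length")
  }
  xs <- pairs$x[, subspace$feature_indices, drop = FALSE]
  if (is.null(k)) {
    k <- as.integer(select_k(xs, pairs$label, k_candidates = k_candidates,
                             weighting = weighting))
  }
  m <- knn_fit(xs, pairs$label, k = k, weighting = weighting)
  attr(m, "subspace") <- subspace
  m
}

#' Fit the full subspace kNN ensemble
#'
#' Trains one kNN classifier per (protein component, descriptor group)
#' subspace — `n_pca^2` in total — on the same instances. Each classifier
#' selects its own `k` by leave-one-out unless `k` is fixed.
#'
#' @param pairs A `pair_set` of training instances (both classes present).
#' @param n_pca Number of protein components used in the encoding; the
#'   protein block of `pairs` must have `n_pca * n_frag * 20` features.
#' @param n_frag Number of protein fragments used in the encoding.
#' @param vote_rule `"unanimity"` (default: positive only if every
#'   classifier votes positive) or `"majority"` (positive if more than half
#'   do; exact half breaks negative).
#' @param weighting Vote weighting for every base classifier.
#' @param k Fixed `k` shared by all classifiers, or `NULL` for independent
#'   per-classifier leave-one-out selection.
#' @param k_candidates Candidate grid for the selection.
#' @return Object of class `dti_ensemble`.
#' @export
fit_dti_ensemble <- function(pairs, n_pca = 7L, n_frag = 10L,
                             vote_rule = c("unanimity", "majority"),
                             weighting = c("inverse", "uniform"),
                             k = NULL, k_candidates = NULL) {
  vote_rule <- match.arg(vote_rule)
  weighting <- match.arg(weighting)
  stopifnot(inherits(pairs, "pair_set"))
  n_pca <- as.integer(n_pca); n_frag <- as.integer(n_frag)
  if (pairs$p_dim != n_pca * n_frag * 20L) {
    stop("protein block has ", pairs$p_dim, " features; expected ",
         n_pca * n_frag * 20L, " for n_pca = ", n_pca, ", n_frag = ", n_frag)
  }
  subspaces <- build_subspaces(n_pca, n_frag, d_dim = pairs$d_dim)
  classifiers <- lapply(subspaces, function(ss) {
    fit_subspace_knn(pairs, ss, k = k, k_candidates = k_candidates,
                     weighting = weighting)
  })
  structure(
    list(classifiers = classifiers, subspaces = subspaces,
         n_pca = n_pca, n_frag = n_frag, d_dim = pairs$d_dim,
         p_dim = pairs$p_dim, vote_rule = vote_rule, weighting = weighting,
         x_train = pairs$x, y_train = pairs$label),
    class = "dti_ensemble"
  )
}

#' @export
print.dti_ensemble <- function(x, ...) {
  ks <- vapply(x$classifiers, `[[`, integer(1L), "k")
  cat(sprintf(paste0("dti_ensemble: %d x %d kNN grid (%s vote, %s weighting), ",
                     "k in [%d, %d]\n"),
              x$n_pca, x$n_pca, x$vote_rule, x$weighting, min(ks), max(ks)))
  invisible(x)
}

#' Combine per-classifier votes into final labels
#'
#' @param votes 0/1 matrix, instances x classifiers.
#' @param rule `"unanimity"` or `"majority"`; an exact majority tie breaks
#'   to negative.
#' @return Integer 0/1 vector.
#' @export
combine_votes <- function(votes, rule = c("unanimity", "majority")) {
  rule <- match.arg(rule)
  votes <- as.matrix(votes)
  if (rule == "unanimity") {
    as.integer(rowSums(votes == 1L) == ncol(votes))
  } else {
    as.integer(rowMeans(votes) > 0.5)
  }
}

#' Predict drug-target interactions with the ensemble
#'
#' @param object A `dti_ensemble`.
#' @param newdata A `pair_set` or a plain matrix of full-length pair
#'   vectors.
#' @param rule Override the ensemble's vote rule for this call.
#' @param ... Ignored.
#' @return List with `label` (final 0/1 calls), `votes` (instances x
#'   classifiers 0/1 matrix, columns `s{i}_{j}`), and `scores` (the base
#'   classifiers' positive-weight fractions).
#' @export
predict.dti_ensemble <- function(object, newdata, rule = NULL, ...) {
  if (inherits(newdata, "pair_set")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$d_dim + object$p_dim) {
    stop("query vectors have ", ncol(newdata), " features; ensemble expects ",
         object$d_dim + object$p_dim)
  }
  rule <- if (is.null(rule)) object$vote_rule else
    match.arg(rule, c("unanimity", "majority"))
  votes <- matrix(0L, nrow = nrow(newdata), ncol = length(object$classifiers))
  scores <- matrix(0, nrow = nrow(newdata), ncol = length(object$classifiers))
  for (ci in seq_along(object$classifiers)) {
    m <- object$classifiers[[ci]]
    ss <- attr(m, "subspace")
    p <- predict(m, newdata[, ss$feature_indices, drop = FALSE])
    votes[, ci] <- p$label
    scores[, ci] <- p$score
  }
  nm <- vapply(object$subspaces, function(s) sprintf("s%d_%d", s$i, s$j), "")
  colnames(votes) <- colnames(scores) <- nm
  list(label = combine_votes(votes, rule), votes = votes, scores = scores)
}

#' Persist / restore a trained ensemble
#'
#' Writes a directory bundle: a JSON manifest (geometry, vote rule,
#' per-classifier k and scaler) plus the full-precision training matrix and
#' labels, sufficient to reproduce every prediction exactly.
#'
#' @param ensemble A `dti_ensemble`.
#' @param dir Bundle directory (created if absent).
#' @return `dir` invisibly / the restored `dti_ensemble`.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "dti_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per_clf <- lapply(ensemble$classifiers, function(m) {
    ss <- attr(m, "subspace")
    list(i = ss$i, j = ss$j, feature_indices = ss$feature_indices,
         k = m$k, weighting = m$weighting,
         scaler_min = unname(m$scaler$min), scaler_range = unname(m$scaler$range),
         labels = m$y)
  })
  # classifiers store scaled projections of one shared training matrix;
  # persist the raw matrix once and rebuild the projections on load
  x_raw <- ensemble$x_train
  manifest <- list(
    format = "dtiSubspace.ensemble", version = 1L,
    n_pca = ensemble$n_pca, n_frag = ensemble$n_frag,
    d_dim = ensemble$d_dim, p_dim = ensemble$p_dim,
    vote_rule = ensemble$vote_rule, weighting = ensemble$weighting,
    n_train = nrow(x_raw),
    classifiers = per_clf
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  jsonlite::write_json(list(x = as.numeric(x_raw), dim = dim(x_raw)),
                       file.path(dir, "training_matrix.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(manifest$format) || manifest$format != "dtiSubspace.ensemble") {
    stop("not an ensemble bundle: ", dir)
  }
  xm <- jsonlite::read_json(file.path(dir, "training_matrix.json"),
                            simplifyVector = TRUE)
  x <- matrix(as.numeric(xm$x), nrow = xm$dim[1L], ncol = xm$dim[2L])
  clfs <- manifest$classifiers
  take <- function(rec, f) if (is.data.frame(clfs)) clfs[[f]][[rec]] else clfs[[rec]][[f]]
  n_clf <- if (is.data.frame(clfs)) nrow(clfs) else length(clfs)
  classifiers <- vector("list", n_clf)
  subspaces <- vector("list", n_clf)
  for (ci in seq_len(n_clf)) {
    fi <- as.integer(unlist(take(ci, "feature_indices")))
    ss <- list(i = as.integer(take(ci, "i")), j = as.integer(take(ci, "j")),
               feature_indices = fi)
    scaler <- list(min = as.numeric(unlist(take(ci, "scaler_min"))),
                   range = as.numeric(unlist(take(ci, "scaler_range"))))
    m <- structure(
      list(x = .apply_scaler(x[, fi, drop = FALSE], scaler),
           y = as.integer(unlist(take(ci, "labels"))),
           k = as.integer(take(ci, "k")),
           weighting = as.character(take(ci, "weighting")),
           scaler = scaler),
      class = "knn_model"
    )
    attr(m, "subspace") <- ss
    classifiers[[ci]] <- m
    subspaces[[ci]] <- ss
  }
  structure(
    list(classifiers = classifiers, subspaces = subspaces,
         n_pca = as.integer(manifest$n_pca), n_frag = as.integer(manifest$n_frag),
         d_dim = as.integer(manifest$d_dim), p_dim = as.integer(manifest$p_dim),
         vote_rule = manifest$vote_rule, weighting = manifest$weighting,
         x_train = x,
         y_train = classifiers[[1L]]$y),
    class = "dti_ensemble"
  )
}
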