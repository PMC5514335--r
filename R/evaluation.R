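# Negative-pair recoupling, the stratified 10-fold protocol, and the
# confusion-matrix metric suite.

#' Sample presumed non-interacting pairs by recoupling
#'
#' The candidate pool is the full cross product of the observed drugs and
#' targets minus the known positive pairs; negatives are drawn from it
#' uniformly without replacement until they number `ratio` times the
#' positives (rounded). With the usual ratio of 2 a class with 2719
#' positives yields 5438 negatives.
#'
#' @param positives data.frame with `drug_id` and `protein_id` columns
#'   (the known interactions).
#' @param drugs,proteins Optional id universes; default: the ids observed
#'   in `positives`.
#' @param ratio Negatives per positive (default 2).
#' @param seed Optional seed making the draw reproducible.
#' @return data.frame `drug_id`, `protein_id` of sampled negatives.
#' @export
sample_negatives <- function(positives, drugs = NULL, proteins = NULL,
                             ratio = 2, seed = NULL) {
  stopifnot(all(c("drug_id", "protein_id") %in% colnames(positives)))
  if (ratio <= 0) stop("ratio must be positive")
  drugs <- if (is.null(drugs)) unique(positives$drug_id) else unique(as.character(drugs))
  proteins <- if (is.null(proteins)) unique(positives$protein_id) else unique(as.character(proteins))
  n_pos <- nrow(positives)
  n_neg <- round(ratio * n_pos)
  pos_key <- paste(positives$drug_id, positives$protein_id, sep = "\r")
  pool <- expand.grid(drug_id = drugs, protein_id = proteins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pool <- pool[!(paste(pool$drug_id, pool$protein_id, sep = "\r") %in% pos_key), ,
               drop = FALSE]
  if (nrow(pool) < n_neg) {
    stop("candidate pool of ", nrow(pool), " recoupled pairs is smaller than ",
         "the requested ", n_neg, " negatives")
  }
  if (!is.null(seed)) set.seed(seed)
  take <- sample.int(nrow(pool), n_neg)
  out <- pool[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign stratified cross-validation folds
#'
#' Instances are split into `k` folds whose per-class sizes differ by at
#' most one (when `stratified`), so small classes stay represented in
#' every fold.
#'
#' @param labels 0/1 (or factor) class labels, one per instance.
#' @param k Number of folds (default 10).
#' @param stratified Balance classes across folds (default `TRUE`).
#' @param seed Optional seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`.
#' @export
kfold_assign <- function(labels, k = 10L, stratified = TRUE, seed = NULL) {
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L) stop("need at least 2 folds")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("class ", cl, " has ", length(idx),
             " instances, fewer than k = ", k, " folds")
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    if (n < k) stop("fewer instances than folds")
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Confusion-matrix metrics
#'
#' Computes recall, precision, accuracy, F1 and the Matthews correlation
#' coefficient from the four confusion counts. A metric whose denominator
#' is zero (e.g. precision with no positive calls) is reported as `NA`
#' with a warning, never silently as 0.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts, at least one positive.
#' @return Object of class `evaluation_report`: list with the counts and
#'   `rec`, `prec`, `acc`, `f1`, `mcc`.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  ratio_or_na <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  rec <- ratio_or_na(tp, tp + fn, "recall")
  prec <- ratio_or_na(tp, tp + fp, "precision")
  acc <- (tp + tn) / (tp + fp + tn + fn)
  f1 <- if (is.na(rec) || is.na(prec) || (prec + rec) == 0) {
    if (!is.na(rec) && !is.na(prec)) {
      warning("F1 undefined (precision + recall = 0); reported as NA",
              call. = FALSE)
    }
    NA_real_
  } else 2 * prec * rec / (prec + rec)
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den2 == 0) {
    warning("MCC undefined (degenerate confusion margin); reported as NA",
            call. = FALSE)
    NA_real_
  } else (tp * tn - fp * fn) / sqrt(mcc_den2)
  structure(
    list(tp = as.integer(round(tp)), fp = as.integer(round(fp)),
         tn = as.integer(round(tn)), fn = as.integer(round(fn)),
         rec = rec, prec = prec, acc = acc, mcc = mcc, f1 = f1),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  Rec=%.4f Prec=%.4f Acc=%.4f MCC=%.4f F1=%.4f\n",
              x$rec, x$prec, x$acc, x$mcc, x$f1))
  invisible(x)
}

#' Metrics from paired label/prediction vectors
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return An `evaluation_report`.
#' @export
metrics_from_predictions <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  compute_metrics(tp = sum(truth == 1L & pred == 1L),
                  fp = sum(truth == 0L & pred == 1L),
                  tn = sum(truth == 0L & pred == 0L),
                  fn = sum(truth == 1L & pred == 0L))
}

#' Cross-validate the subspace ensemble
#'
#' Runs the k-fold protocol: for each fold the full ensemble — including
#' every per-classifier neighbour-count selection and min-max scaler — is
#' refit on the training folds only and applied to the held-out fold, so no
#' test information leaks into any fitting step. Confusion counts are
#' pooled over the folds (every instance is tested exactly once).
#'
#' @param pairs A `pair_set` with labels.
#' @param folds Number of folds (default 10).
#' @param stratified Stratify the fold assignment by class (default `TRUE`).
#' @param seed Seed for the fold assignment.
#' @param n_pca,n_frag Encoding geometry, forwarded to
#'   [fit_dti_ensemble()].
#' @param vote_rule,weighting,k,k_candidates Forwarded to
#'   [fit_dti_ensemble()].
#' @return List with `pooled` (an `evaluation_report`), `per_fold` (list of
#'   reports), `fold_id`, `predictions` (held-out ensemble calls), and
#'   `votes` (held-out per-classifier 0/1 votes, instances x classifiers).
#' @export
cross_validate <- function(pairs, folds = 10L, stratified = TRUE, seed = NULL,
                           n_pca = 7L, n_frag = 10L,
                           vote_rule = c("unanimity", "majority"),
                           weighting = c("inverse", "uniform"),
                           k = NULL, k_candidates = NULL) {
  vote_rule <- match.arg(vote_rule)
  weighting <- match.arg(weighting)
  stopifnot(inherits(pairs, "pair_set"))
  n <- nrow(pairs$x)
  fold_id <- kfold_assign(pairs$label, k = folds, stratified = stratified,
                          seed = seed)
  predictions <- integer(n)
  votes <- matrix(NA_integer_, nrow = n, ncol = as.integer(n_pca)^2)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    res <- tryCatch({
      ens <- fit_dti_ensemble(pairs[tr], n_pca = n_pca, n_frag = n_frag,
                              vote_rule = vote_rule, weighting = weighting,
                              k = k, k_candidates = k_candidates)
      predict(ens, pairs[te])
    }, error = function(e) {
      stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    predictions[te] <- res$label
    votes[te, ] <- res$votes
    colnames(votes) <- colnames(res$votes)
    per_fold[[f]] <- suppressWarnings(
      metrics_from_predictions(pairs$label[te], res$label)
    )
  }
  pooled <- metrics_from_predictions(pairs$label, predictions)
  list(pooled = pooled, per_fold = per_fold, fold_id = fold_id,
       predictions = predictions, votes = votes)
}
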