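# Shared builders and independent oracles. Oracles deliberately use naive
# per-element loops / formulas so they share no code path with the package.

# random orthonormal loading model (QR of a Gaussian matrix), variance
# fractions fixed to a decreasing profile
toy_pca_model <- function(n_pca, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(20 * 20), 20)))
  load <- q[, seq_len(n_pca), drop = FALSE]
  for (j in seq_len(n_pca)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- aa_alphabet()
  fr <- rev(seq_len(20)); fr <- fr / sum(fr)
  structure(list(loadings = load, variance_fractions = fr,
                 center = rep(0, 20), scale = rep(1, 20),
                 n_components = n_pca, alphabet = aa_alphabet()),
            class = "aa_pca")
}

random_sequence <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# small planted study used by several module tests (9-classifier grid)
tiny_study <- function(seed = 5, effect_size = 3) {
  simulate_dti_study(fixture_spec(
    n_drugs = 30L, n_proteins = 30L, n_positive = 40L,
    seq_len_range = c(60L, 120L), n_descriptors = 150L, n_properties = 60L,
    property_rank = 3L, signal_subspace = c(2L, 3L),
    effect_size = effect_size, n_pca = 3L, n_frag = 5L, seed = seed))
}

# independent exhaustive kNN: per-query loop, sweep-based min-max scaling,
# same vote contract (inverse/uniform weights, zero-distance majority,
# ties negative)
naive_knn_predict <- function(train, y, queries, k, weighting, scale = TRUE) {
  if (scale) {
    mins <- apply(train, 2, min)
    rng <- apply(train, 2, max) - mins
    rng[rng == 0] <- 1
    tr <- sweep(sweep(train, 2, mins), 2, rng, "/")
    qs <- sweep(sweep(queries, 2, mins), 2, rng, "/")
  } else {
    tr <- train
    qs <- queries
  }
  vapply(seq_len(nrow(qs)), function(qi) {
    d <- sqrt(rowSums((tr - matrix(qs[qi, ], nrow(tr), ncol(tr),
                                   byrow = TRUE))^2))
    zero <- d < 1e-8
    if (weighting == "inverse" && any(zero)) {
      return(as.integer(mean(y[zero] == 1) > 0.5))
    }
    nb <- order(d, seq_along(d))[seq_len(k)]
    w <- if (weighting == "inverse") 1 / d[nb] else rep(1, k)
    as.integer(sum(w[y[nb] == 1]) / sum(w) > 0.5)
  }, integer(1))
}

# leave-one-out accuracy by brute force re-prediction (no internal scaling:
# the caller decides, matching the contract that the scaler is fit once on
# the full training set)
naive_loo_accuracy <- function(x, y, k, weighting = "inverse") {
  hits <- vapply(seq_len(nrow(x)), function(i) {
    p <- naive_knn_predict(x[-i, , drop = FALSE], y[-i],
                           x[i, , drop = FALSE], k, weighting, scale = FALSE)
    as.integer(p == y[i])
  }, integer(1))
  mean(hits)
}

# write a syntactically valid AAindex1 flat file from rows of 20 values
write_aaindex_fixture <- function(path, entries) {
  lines <- character(0)
  for (nm in names(entries)) {
    v <- entries[[nm]]
    fmt <- function(x) paste(ifelse(is.na(x), "NA", format(x)), collapse = "   ")
    lines <- c(lines,
               paste("H", nm),
               paste("D", "synthetic fixture property", nm),
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               paste0("     ", fmt(v[1:10])),
               paste0("     ", fmt(v[11:20])),
               "//")
  }
  writeLines(lines, path)
  path
}
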