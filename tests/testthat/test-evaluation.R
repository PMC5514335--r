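test_that("negative recoupling samples the stated pool without collisions", {
  pos <- data.frame(drug_id = c("d1", "d2"), protein_id = c("p1", "p2"))
  # pool is only {(d1,p2),(d2,p1)}: too small for ratio 2
  expect_error(sample_negatives(pos, ratio = 2), "pool of 2.*4 negatives")

  set.seed(50)
  pos2 <- data.frame(drug_id = sample(sprintf("d%02d", 1:30), 60, TRUE),
                     protein_id = sample(sprintf("p%02d", 1:30), 60, TRUE))
  pos2 <- unique(pos2)
  neg <- sample_negatives(pos2, ratio = 2, seed = 99)
  expect_equal(nrow(neg), round(2 * nrow(pos2)))
  expect_equal(nrow(unique(neg)), nrow(neg))
  overlap <- merge(neg, pos2)
  expect_equal(nrow(overlap), 0L)
  # reproducible under the seed, different otherwise
  neg_again <- sample_negatives(pos2, ratio = 2, seed = 99)
  expect_identical(neg, neg_again)
  neg_other <- sample_negatives(pos2, ratio = 2, seed = 100)
  expect_false(identical(neg, neg_other))
})

test_that("stratified folds balance both classes to within one instance", {
  y <- rep(c(1L, 0L), c(34, 66))
  f <- kfold_assign(y, k = 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  for (fold in 1:10) {
    expect_true(sum(y == 1 & f == fold) %in% 3:4)
    expect_true(sum(y == 0 & f == fold) %in% 6:7)
  }
  expect_identical(kfold_assign(y, k = 10, seed = 7),
                   kfold_assign(y, k = 10, seed = 7))
  expect_error(kfold_assign(rep(c(0, 1), c(95, 5)), k = 10), "fewer than")
})

test_that("metrics reproduce hand and formula oracles", {
  r <- compute_metrics(tp = 1, fp = 1, tn = 1, fn = 1)
  expect_equal(unlist(r[c("rec", "prec", "acc", "mcc", "f1")]),
               c(rec = 0.5, prec = 0.5, acc = 0.5, mcc = 0, f1 = 0.5))

  r2 <- compute_metrics(tp = 50, fp = 5, tn = 100, fn = 10)
  expect_equal(r2$mcc, 4950 / sqrt(55 * 60 * 105 * 110), tolerance = 1e-12)
  expect_equal(r2$mcc, 0.8018, tolerance = 1e-4)

  perfect <- compute_metrics(tp = 10, fp = 0, tn = 20, fn = 0)
  expect_equal(unlist(perfect[c("rec", "prec", "acc", "mcc", "f1")]),
               c(rec = 1, prec = 1, acc = 1, mcc = 1, f1 = 1))

  # undefined ratios surface as NA with a warning, never as silent zero
  w <- capture_warnings(nopos <- compute_metrics(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_match(w, "precision undefined", all = FALSE)
  expect_match(w, "MCC undefined", all = FALSE)
  expect_true(is.na(nopos$prec))
  expect_true(is.na(nopos$mcc))
  expect_error(compute_metrics(0, 0, 0, 0), "all confusion counts are zero")
  expect_error(compute_metrics(-1, 0, 2, 0), "nonnegative")

  # 1000 random quadruples against independently written formulas
  set.seed(51)
  for (i in 1:1000) {
    cts <- rpois(4, 20)
    if (sum(cts) == 0) next
    tp <- cts[1]; fp <- cts[2]; tn <- cts[3]; fn <- cts[4]
    r <- suppressWarnings(compute_metrics(tp, fp, tn, fn))
    expect_equal(r$acc, (tp + tn) / sum(cts), tolerance = 1e-12)
    if (tp + fn > 0) expect_equal(r$rec, tp / (tp + fn), tolerance = 1e-12)
    if (tp + fp > 0) expect_equal(r$prec, tp / (tp + fp), tolerance = 1e-12)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (den > 0) {
      expect_equal(r$mcc, (tp * tn - fp * fn) / den, tolerance = 1e-12)
    }
  }
})

test_that("metric symmetries hold: flipped predictions negate the MCC", {
  set.seed(52)
  for (i in 1:50) {
    truth <- rbinom(60, 1, 0.4)
    pred <- rbinom(60, 1, 0.5)
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    a <- metrics_from_predictions(truth, pred)
    b <- metrics_from_predictions(truth, 1L - pred)
    expect_equal(a$mcc, -b$mcc, tolerance = 1e-12)
    expect_equal(a$acc + b$acc, 1, tolerance = 1e-12)
    # agreement with a direct confusion-matrix tabulation
    tab <- table(factor(truth, 0:1), factor(pred, 0:1))
    expect_equal(a$tp, unname(tab["1", "1"]))
    expect_equal(a$fp, unname(tab["0", "1"]))
    expect_equal(a$tn, unname(tab["0", "0"]))
    expect_equal(a$fn, unname(tab["1", "0"]))
  }
})

test_that("cross-validation tests every instance exactly once, leak-free", {
  st <- tiny_study(seed = 10)
  cv <- suppressWarnings(
    cross_validate(st$pairs, folds = 5, seed = 2, n_pca = 3, n_frag = 5, k = 3)
  )
  counts <- vapply(cv$per_fold, function(r) r$tp + r$fp + r$tn + r$fn,
                   numeric(1))
  expect_equal(sum(counts), nrow(st$pairs$x))
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  expect_equal(with(cv$pooled, tp + fp + tn + fn), nrow(st$pairs$x))
  expect_false(anyNA(cv$votes))
  # replay determinism
  cv2 <- suppressWarnings(
    cross_validate(st$pairs, folds = 5, seed = 2, n_pca = 3, n_frag = 5, k = 3)
  )
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(unclass(cv$pooled), unclass(cv2$pooled))
})

test_that("cross-validation recovers a planted subspace signal", {
  st <- tiny_study(seed = 11, effect_size = 3)
  cv <- suppressWarnings(
    cross_validate(st$pairs, folds = 5, seed = 3, n_pca = 3, n_frag = 5,
                   vote_rule = "majority")
  )
  expect_gt(cv$pooled$acc, 0.8)
  expect_gt(cv$pooled$mcc, 0.5)
})
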