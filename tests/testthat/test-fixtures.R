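test_that("fixture specs validate their feasibility invariants", {
  expect_s3_class(fixture_spec(), "fixture_spec")
  expect_error(fixture_spec(n_positive = 2000L), "no room")
  expect_error(fixture_spec(property_rank = 25L), "property_rank")
  expect_error(fixture_spec(effect_size = -1), "nonnegative")
  expect_error(fixture_spec(signal_subspace = c(1L, 9L)), "signal_subspace")
  expect_error(fixture_spec(seq_len_range = c(5L, 50L)), "sequence length")
})

test_that("property tables carry their planted low-rank structure", {
  spec <- fixture_spec(n_properties = 40L, property_rank = 3L, seed = 60)
  tbl <- make_property_table(spec)
  expect_equal(dim(tbl$values), c(40L, 20L))
  model <- fit_property_pca(standardize_properties(tbl), n_components = 10L)
  expect_gt(cumulative_variance(model, 3L), 0.9)
  # near-rank-1 table: the first component reproduces every standardized row
  spec1 <- fixture_spec(n_properties = 40L, property_rank = 1L, seed = 61)
  std <- standardize_properties(make_property_table(spec1))
  m1 <- fit_property_pca(std, n_components = 1L)
  xc <- scale(std$values[!std$flagged, ], center = m1$center, scale = FALSE)
  recon <- (xc %*% m1$loadings) %*% t(m1$loadings)
  rel_err <- sum((recon - xc)^2) / sum(xc^2)
  expect_lt(rel_err, 0.05)
  # pure determinism in the spec seed
  expect_identical(make_property_table(spec)$values, tbl$values)
})

test_that("generated sequences respect lengths and background frequencies", {
  spec <- fixture_spec(n_proteins = 400L, n_drugs = 400L, n_positive = 100L,
                       seq_len_range = c(150L, 200L), effect_size = 0,
                       seed = 62)
  recs <- make_sequences(spec)
  lens <- nchar(recs$sequence)
  expect_true(all(lens >= 150 & lens <= 200))
  expect_equal(nrow(recs), 400L)
  # residue tally over ~70k draws: each frequency within 3 sd of 1/20
  chars <- unlist(strsplit(paste(recs$sequence, collapse = ""), ""))
  n <- length(chars)
  freq <- table(factor(chars, aa_alphabet())) / n
  sd3 <- 3 * sqrt((1 / 20) * (19 / 20) / n)
  expect_true(all(abs(freq - 1 / 20) < sd3 * 1.5))  # small multiple-test slack
  expect_identical(make_sequences(spec)$sequence, recs$sequence)
})

test_that("signal-class proteins are composition-biased along the loading", {
  spec <- fixture_spec(seed = 63)
  model <- fit_property_pca(standardize_properties(make_property_table(spec)),
                            n_components = spec$n_pca)
  cls <- rep(c(0L, 1L), length.out = spec$n_proteins)
  recs <- make_sequences(spec, model = model, protein_class = cls)
  l <- model$loadings[, spec$signal_subspace[1]]
  proj <- vapply(recs$sequence, function(s) {
    counts <- table(factor(strsplit(s, "")[[1]], aa_alphabet()))
    sum(l * counts / sum(counts))
  }, numeric(1))
  expect_gt(mean(proj[cls == 1L]), mean(proj[cls == 0L]))
})

test_that("labeled pairs honour the planted rule and the sampling ratio", {
  spec <- fixture_spec(seed = 64)
  lp <- make_labeled_pairs(spec)
  expect_equal(sum(lp$dataset$label == 1L), spec$n_positive)
  expect_equal(sum(lp$dataset$label == 0L), round(spec$ratio * spec$n_positive))
  expect_equal(anyDuplicated(lp$dataset[, c("drug_id", "protein_id")]), 0L)
  # every positive joins a signal drug with a signal protein; no negative does
  di <- match(lp$dataset$drug_id, sprintf("D%03d", seq_len(spec$n_drugs)))
  pi <- match(lp$dataset$protein_id, sprintf("P%03d", seq_len(spec$n_proteins)))
  both <- lp$drug_class[di] == 1L & lp$protein_class[pi] == 1L
  expect_true(all(both[lp$dataset$label == 1L]))
  expect_false(any(both[lp$dataset$label == 0L]))
  # the signal descriptor group is mean-shifted for signal drugs
  part <- partition_descriptors(spec$n_descriptors, spec$n_pca)
  sig <- partition_group(part, spec$signal_subspace[2])
  gap <- mean(lp$descriptors$values[lp$drug_class == 1L, sig]) -
    mean(lp$descriptors$values[lp$drug_class == 0L, sig])
  expect_equal(gap, spec$effect_size * spec$noise_sd, tolerance = 0.15)
})

test_that("null fixtures attach labels to unstructured uniform pairs", {
  spec <- fixture_spec(effect_size = 0, seed = 65)
  lp <- make_labeled_pairs(spec)
  expect_equal(nrow(lp$dataset), spec$n_positive * 3)
  # descriptors carry no shift anywhere
  part <- partition_descriptors(spec$n_descriptors, spec$n_pca)
  sig <- partition_group(part, spec$signal_subspace[2])
  gap <- mean(lp$descriptors$values[lp$drug_class == 1L, sig]) -
    mean(lp$descriptors$values[lp$drug_class == 0L, sig])
  expect_lt(abs(gap), 0.05)
})

test_that("a full study replays byte-identically from its manifest", {
  spec <- fixture_spec(n_drugs = 25L, n_proteins = 25L, n_positive = 30L,
                       n_descriptors = 60L, n_properties = 50L,
                       property_rank = 3L, n_pca = 3L, n_frag = 5L,
                       signal_subspace = c(1L, 2L), seq_len_range = c(40L, 80L),
                       seed = 66)
  dir <- withr::local_tempdir()
  st <- simulate_dti_study(spec, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("properties.csv", "proteins.fasta", "descriptors.csv",
           "pairs.csv", "pca_model.json", "fixtures.yaml")))))
  st2 <- replay_fixture(file.path(dir, "fixtures.yaml"))
  expect_identical(st2$dataset, st$dataset)
  expect_identical(st2$descriptors$values, st$descriptors$values)
  expect_identical(st2$proteins$sequence, st$proteins$sequence)
  expect_identical(st2$pairs$x, st$pairs$x)
  # written artifacts parse through the standard readers
  expect_s3_class(read_property_csv(file.path(dir, "properties.csv")),
                  "aa_property_table")
  expect_equal(nrow(read_protein_fasta(file.path(dir, "proteins.fasta"))), 25L)
  expect_s3_class(read_descriptor_table(file.path(dir, "descriptors.csv")),
                  "descriptor_table")
  expect_identical(read_pca_model(file.path(dir, "pca_model.json"))$loadings,
                   st$model$loadings)
})
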