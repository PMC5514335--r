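test_that("AAindex1 flat files parse into canonically ordered tables", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_aaindex_fixture(f, list(FIX00001 = as.numeric(1:20),
                                FIX00002 = as.numeric(101:120)))
  tbl <- read_aaindex1(f)
  expect_s3_class(tbl, "aa_property_table")
  expect_equal(nrow(tbl$values), 2L)
  expect_equal(ncol(tbl$values), 20L)
  expect_equal(colnames(tbl$values), aa_alphabet())
  # two-row I layout: first row is residues A..I, second L..V of the
  # canonical order, so values 1..20 land untouched
  expect_equal(unname(tbl$values["FIX00001", "A"]), 1)
  expect_equal(unname(tbl$values["FIX00001", "I"]), 10)
  expect_equal(unname(tbl$values["FIX00001", "L"]), 11)
  expect_equal(unname(tbl$values["FIX00001", "V"]), 20)
  expect_false(any(tbl$flagged))
})

test_that("malformed and missing-marker records are rejected or flagged", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("H BAD00001", "D nineteen values only",
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               paste(1:10, collapse = "  "),
               paste(11:19, collapse = "  "),
               "//"), bad)
  expect_error(read_aaindex1(bad), "BAD00001.*19")

  nafile <- withr::local_tempfile(fileext = ".txt")
  v <- as.numeric(1:20); v[7] <- NA
  write_aaindex_fixture(nafile, list(OK000001 = as.numeric(21:40),
                                     MISS0001 = v,
                                     OK000002 = as.numeric(61:80)))
  tbl <- read_aaindex1(nafile)
  expect_equal(unname(tbl$flagged), c(FALSE, TRUE, FALSE))
  expect_true(tbl$flagged[tbl$accessions == "MISS0001"])
  # flagged rows stay out of the PCA
  model <- fit_property_pca(standardize_properties(tbl), n_components = 2L)
  expect_equal(model$n_components, 2L)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_aaindex1(empty), "empty")
})

test_that("standardization z-scores rows, flags constants, and is idempotent", {
  tbl <- aa_property_table(rbind(as.numeric(1:20), rep(5, 20),
                                 rnorm(20, 3, 10)))
  s <- standardize_properties(tbl)
  expect_equal(mean(s$values[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(s$values[1, ]), 1, tolerance = 1e-12)
  expect_true(s$flagged[2])   # zero-variance row excluded
  s2 <- standardize_properties(s)
  expect_equal(s2$values[!s2$flagged, ], s$values[!s$flagged, ],
               tolerance = 1e-12)

  allflat <- aa_property_table(rbind(rep(1, 20), rep(2, 20)))
  expect_error(standardize_properties(allflat), "flagged")
})

test_that("PCA matches a direct eigendecomposition oracle up to sign", {
  set.seed(42)
  tbl <- standardize_properties(aa_property_table(matrix(rnorm(30 * 20), 30)))
  model <- fit_property_pca(tbl, n_components = 20L)

  # oracle: eigen-decompose the sample covariance of the 30 x 20 matrix
  x <- tbl$values
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  oracle_frac <- ev$values / sum(ev$values)
  expect_equal(model$variance_fractions, oracle_frac, tolerance = 1e-8)
  for (j in 1:20) {
    expect_equal(abs(sum(model$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }

  # orthonormality and full-rank cumulative variance
  g <- crossprod(model$loadings)
  expect_equal(g, diag(20), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(cumulative_variance(model, 20L), 1, tolerance = 1e-8)

  # back-projection reconstructs the (column-centred) table
  xc <- scale(x, center = model$center, scale = FALSE)
  recon <- (xc %*% model$loadings) %*% t(model$loadings)
  expect_equal(recon, xc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("near-rank-1 tables concentrate variance on the first component", {
  set.seed(7)
  direction <- rnorm(20)
  rows <- t(vapply(rnorm(40, sd = 3), function(a) a * direction + rnorm(20, sd = 1e-3),
                   numeric(20)))
  model <- fit_property_pca(standardize_properties(aa_property_table(rows)),
                            n_components = 5L)
  expect_gt(model$variance_fractions[1], 0.99)
})

test_that("variance targets pick the smallest sufficient component count", {
  set.seed(11)
  tbl <- standardize_properties(aa_property_table(matrix(rnorm(50 * 20), 50)))
  full <- fit_property_pca(tbl, n_components = 20L)
  for (target in c(0.3, 0.6, 0.95)) {
    m <- fit_property_pca(tbl, variance_target = target)
    expect_gte(cumulative_variance(m, m$n_components), target)
    if (m$n_components > 1L) {
      expect_lt(cumulative_variance(full, m$n_components - 1L), target)
    }
  }
  expect_error(fit_property_pca(tbl, variance_target = 0), "variance_target")
  expect_error(fit_property_pca(tbl, variance_target = 1.2), "variance_target")
  small <- standardize_properties(aa_property_table(matrix(rnorm(3 * 20), 3)))
  expect_error(fit_property_pca(small, n_components = 10L), "fewer usable")
})

test_that("cumulative variance is monotone, bounded, and range-checked", {
  m <- toy_pca_model(7)
  expect_equal(cumulative_variance(m, 1L), m$variance_fractions[1])
  cv <- vapply(1:20, cumulative_variance, numeric(1), model = m)
  expect_true(all(diff(cv) >= 0))
  expect_lte(cv[20], 1 + 1e-8)
  expect_error(cumulative_variance(m, 0L), "out of range")
  expect_error(cumulative_variance(m, 21L), "out of range")
})

test_that("PCA models survive a JSON round trip exactly", {
  set.seed(3)
  tbl <- standardize_properties(aa_property_table(matrix(rnorm(25 * 20), 25)))
  model <- fit_property_pca(tbl, n_components = 6L)
  f <- withr::local_tempfile(fileext = ".json")
  write_pca_model(model, f)
  back <- read_pca_model(f)
  expect_identical(unname(back$loadings), unname(model$loadings))
  expect_identical(back$variance_fractions, model$variance_fractions)
  expect_identical(back$n_components, model$n_components)
})

test_that("property CSVs read back in canonical residue order", {
  f <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(rnorm(3 * 20), 3, dimnames = list(NULL, sample(aa_alphabet())))
  write.csv(data.frame(accession = c("a", "b", "c"), m, check.names = FALSE),
            f, row.names = FALSE)
  tbl <- read_property_csv(f)
  expect_equal(colnames(tbl$values), aa_alphabet())
  expect_equal(unname(tbl$values[, "C"]), unname(m[, "C"]))
})
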