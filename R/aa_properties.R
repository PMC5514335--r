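# Amino-acid property tables and the principal-component model used to
# weight fragment compositions.

#' Canonical amino-acid alphabet
#'
#' The 20 standard residues in the fixed order used by the two-row `I` field
#' of AAindex1 flat files (first row A R N D C Q E G H I, second row
#' L K M F P S T W Y V). Every property table, composition matrix and
#' feature-vector layout in this package uses this column order.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Construct an amino-acid property table
#'
#' A property table holds P numeric amino-acid indices (one row per
#' property, one column per residue type in [aa_alphabet()] order).
#' Rows containing missing values are flagged and excluded from
#' standardization and PCA rather than imputed.
#'
#' @param values Numeric matrix with 20 columns (P properties x 20 residues).
#' @param accessions Character vector of property identifiers (row names).
#' @param descriptions Optional character vector of free-text descriptions.
#' @return An object of class `aa_property_table` with fields `values`,
#'   `accessions`, `descriptions`, logical `flagged` (rows unusable for PCA)
#'   and logical `standardized`.
#' @export
aa_property_table <- function(values, accessions = NULL, descriptions = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 20L) {
    stop("a property table needs exactly 20 residue columns, got ", ncol(values))
  }
  if (nrow(values) < 1L) stop("a property table needs at least one property row")
  if (is.null(accessions)) accessions <- sprintf("PROP%04d", seq_len(nrow(values)))
  accessions <- as.character(accessions)
  if (anyDuplicated(accessions)) stop("duplicated property accessions")
  if (length(accessions) != nrow(values)) {
    stop("accessions length does not match number of property rows")
  }
  if (is.null(descriptions)) descriptions <- rep("", nrow(values))
  colnames(values) <- aa_alphabet()
  rownames(values) <- accessions
  storage.mode(values) <- "double"
  flagged <- apply(values, 1L, function(r) any(!is.finite(r)))
  structure(
    list(values = values, accessions = accessions,
         descriptions = as.character(descriptions),
         flagged = flagged, standardized = FALSE),
    class = "aa_property_table"
  )
}

#' @export
print.aa_property_table <- function(x, ...) {
  cat(sprintf("aa_property_table: %d properties x 20 residues (%d flagged%s)\n",
              nrow(x$values), sum(x$flagged),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Read an AAindex1 flat file
#'
#' Parses the classic AAindex1 record format: `H` holds the accession, `D`
#' the description, and `I` is followed by two rows of ten values giving the
#' index for the twenty residues in A/L, R/K, ... column pairs. Values are
#' remapped to [aa_alphabet()] order. Records carrying the `NA` missing
#' marker are kept but flagged, so they are excluded from PCA downstream.
#'
#' @param path Path to an AAindex1 flat file (records terminated by `//`).
#' @return An [aa_property_table()].
#' @export
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0L || all(trimws(lines) == "")) {
    stop("empty AAindex1 file: ", path)
  }
  # split into records on the // terminator
  rec_end <- grep("^//", lines)
  if (length(rec_end) == 0L) stop("no AAindex1 records (missing '//' terminators) in ", path)
  starts <- c(1L, utils::head(rec_end, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:e], starts, rec_end)

  acc <- character(0); desc <- character(0); vals <- list()
  for (rec in recs) {
    if (all(trimws(rec) %in% c("", "//"))) next
    h <- grep("^H ", rec, value = TRUE)
    if (length(h) == 0L) stop("AAindex1 record without an H (accession) line")
    accession <- trimws(sub("^H ?", "", h[1L]))
    d <- grep("^D ", rec, value = TRUE)
    description <- if (length(d)) trimws(sub("^D ?", "", d[1L])) else ""
    i_at <- grep("^I( |$)", rec)
    if (length(i_at) == 0L) stop("record ", accession, " has no I field")
    if (i_at[1L] + 2L > length(rec)) stop("record ", accession, " has a truncated I field")
    num_lines <- rec[(i_at[1L] + 1L):(i_at[1L] + 2L)]
    toks <- unlist(strsplit(trimws(num_lines), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != 20L) {
      stop("record ", accession, ": I field has ", length(toks),
           " values, expected 20")
    }
    v <- suppressWarnings(as.numeric(toks))
    bad <- is.na(v) & toks != "NA"
    if (any(bad)) {
      stop("record ", accession, ": unparseable value(s) ",
           paste(toks[bad], collapse = ", "))
    }
    # two rows of ten in column pairs: row1 = residues 1..10, row2 = 11..20
    # of the canonical alphabet, so simple concatenation restores the order
    acc <- c(acc, accession)
    desc <- c(desc, description)
    vals[[length(vals) + 1L]] <- v
  }
  if (length(vals) == 0L) stop("no AAindex1 records parsed from ", path)
  aa_property_table(do.call(rbind, vals), accessions = acc, descriptions = desc)
}

#' Read a plain property matrix CSV
#'
#' Alternative input format: first column the property accession, then 20
#' numeric residue columns. Columns named by one-letter residue codes are
#' reordered to [aa_alphabet()]; unnamed layouts are assumed already ordered.
#'
#' @param path CSV path.
#' @return An [aa_property_table()].
#' @export
read_property_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 21L) stop("property CSV needs 1 accession + 20 residue columns")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  nm <- colnames(m)
  if (!is.null(nm) && all(nm %in% aa_alphabet()) && !anyDuplicated(nm)) {
    m <- m[, aa_alphabet(), drop = FALSE]
  }
  aa_property_table(m, accessions = df[[1L]])
}

#' Standardize a property table
#'
#' Z-scores every unflagged property row across its 20 residue values so
#' that heterogeneous physical units cannot dominate the PCA. Rows with
#' (numerically) zero variance are flagged and excluded. The operation is a
#' fixed point: standardizing twice equals standardizing once.
#'
#' @param table An [aa_property_table()].
#' @return The table with unflagged rows centred/scaled and `standardized = TRUE`.
#' @export
standardize_properties <- function(table) {
  stopifnot(inherits(table, "aa_property_table"))
  usable <- !table$flagged
  if (sum(usable) < 2L) stop("need at least two unflagged property rows")
  v <- table$values
  for (i in which(usable)) {
    r <- v[i, ]
    s <- stats::sd(r)
    if (!is.finite(s) || s < 1e-12) {
      table$flagged[i] <- TRUE
      next
    }
    v[i, ] <- (r - mean(r)) / s
  }
  if (all(table$flagged)) stop("all property rows flagged (constant or missing)")
  table$values <- v
  table$standardized <- TRUE
  table
}

#' Fit the principal-component model of amino-acid properties
#'
#' Runs PCA on the P x 20 property matrix with properties as observations
#' and the 20 residue types as variables, so each loading is a length-20
#' vector assigning one weight per residue type. Either a fixed number of
#' components or a cumulative variance target can be requested. Loading
#' signs are fixed so the largest-magnitude entry of each loading is
#' positive, making the model deterministic.
#'
#' @param table A standardized [aa_property_table()] (standardized
#'   automatically if not, with a message).
#' @param n_components Number of components L to keep (<= 20 and <= number
#'   of usable rows). Mutually exclusive with `variance_target`.
#' @param variance_target Fraction in (0, 1]: keep the smallest L whose
#'   cumulative explained-variance fraction reaches the target.
#' @param standardize If `FALSE`, run the PCA on the raw property values
#'   (flagged rows still excluded). Default `TRUE`: z-scored rows, so no
#'   single property's units dominate.
#' @return An object of class `aa_pca` with `loadings` (20 x L matrix,
#'   orthonormal columns), `variance_fractions` (all 20, non-increasing),
#'   `center`/`scale` (length-20 column statistics applied before the
#'   eigendecomposition), `n_components`, and `alphabet`.
#' @export
fit_property_pca <- function(table, n_components = NULL, variance_target = NULL,
                             standardize = TRUE) {
  stopifnot(inherits(table, "aa_property_table"))
  if (standardize && !table$standardized) {
    message("standardizing property table before PCA")
    table <- standardize_properties(table)
  }
  x <- table$values[!table$flagged, , drop = FALSE]
  p <- nrow(x)
  if (p < 2L) stop("need at least two usable property rows for PCA")
  if (!is.null(n_components) && !is.null(variance_target)) {
    stop("give n_components or variance_target, not both")
  }
  if (!is.null(variance_target) &&
      (variance_target <= 0 || variance_target > 1)) {
    stop("variance_target must lie in (0, 1]")
  }
  max_rank <- min(20L, p)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  # pad to a fixed length-20 spectrum (trailing zeros beyond the rank)
  frac_all <- rep(0, 20L)
  frac_all[seq_along(ev)] <- ev / sum(ev)
  if (is.null(n_components)) {
    if (is.null(variance_target)) {
      stop("one of n_components or variance_target is required")
    }
    l <- which(cumsum(frac_all) >= variance_target - 1e-12)[1L]
    if (is.na(l)) l <- max_rank
  } else {
    l <- as.integer(n_components)
    if (l < 1L) stop("n_components must be positive")
    if (l > 20L) stop("n_components cannot exceed the 20 residue variables")
    if (l > p) stop("fewer usable property rows (", p, ") than requested components (", l, ")")
    if (l > ncol(pc$rotation)) stop("requested ", l, " components but rank is ", ncol(pc$rotation))
  }
  load <- pc$rotation[, seq_len(l), drop = FALSE]
  # sign convention: largest-|entry| of each loading positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- aa_alphabet()
  colnames(load) <- sprintf("PC%d", seq_len(l))
  structure(
    list(loadings = load,
         variance_fractions = frac_all,
         center = pc$center,
         scale = rep(1, 20L),
         n_components = l,
         alphabet = aa_alphabet()),
    class = "aa_pca"
  )
}

#' @export
print.aa_pca <- function(x, ...) {
  cat(sprintf("aa_pca: %d components over 20 residues; cumulative variance %.4f\n",
              x$n_components, cumulative_variance(x, x$n_components)))
  invisible(x)
}

#' Cumulative explained variance
#'
#' @param model An `aa_pca` model (or any object with a
#'   `variance_fractions` field).
#' @param k Number of leading components to sum over.
#' @return The sum of the first `k` explained-variance fractions.
#' @export
cumulative_variance <- function(model, k) {
  fr <- model$variance_fractions
  k <- as.integer(k)
  if (k < 1L || k > length(fr)) stop("k out of range 1..", length(fr))
  sum(fr[seq_len(k)])
}

#' Serialize / restore a principal-component model
#'
#' Writes the model as a small versioned JSON bundle so that protein
#' encodings are reproducible across runs and machines.
#'
#' @param model An `aa_pca` model.
#' @param path Output JSON path.
#' @return `path`, invisibly (`write_pca_model`); an `aa_pca`
#'   (`read_pca_model`).
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "aa_pca"))
  obj <- list(
    format = "dtiSubspace.aa_pca",
    version = 1L,
    alphabet = model$alphabet,
    n_components = model$n_components,
    loadings = as.numeric(model$loadings),  # column-major 20 x L
    variance_fractions = model$variance_fractions,
    center = unname(model$center),
    scale = unname(model$scale)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dtiSubspace.aa_pca") {
    stop("not a dtiSubspace PCA model bundle: ", path)
  }
  load <- matrix(as.numeric(obj$loadings), nrow = 20L)
  rownames(load) <- obj$alphabet
  colnames(load) <- sprintf("PC%d", seq_len(ncol(load)))
  structure(
    list(loadings = load,
         variance_fractions = as.numeric(obj$variance_fractions),
         center = as.numeric(obj$center),
         scale = as.numeric(obj$scale),
         n_components = as.integer(obj$n_components),
         alphabet = as.character(obj$alphabet)),
    class = "aa_pca"
  )
}
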