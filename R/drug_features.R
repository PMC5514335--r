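# Drug descriptor tables, cleaning, the ordered group partition, and the
# concatenated drug-target pair vectors.

#' Construct a drug descriptor table
#'
#' @param values Numeric matrix, drugs x descriptors. Descriptor (column)
#'   order is meaningful: groups are later cut from it in order.
#' @param drug_ids Character vector of unique drug identifiers.
#' @param descriptor_names Optional descriptor names.
#' @return An object of class `descriptor_table` with fields `values`,
#'   `drug_ids`, `descriptor_names`, and `dropped` (names removed by
#'   [clean_descriptors()], empty until cleaning).
#' @export
descriptor_table <- function(values, drug_ids, descriptor_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  drug_ids <- as.character(drug_ids)
  if (length(drug_ids) != nrow(values)) stop("drug_ids length != number of rows")
  dup <- unique(drug_ids[duplicated(drug_ids)])
  if (length(dup)) stop("duplicated drug id(s): ", paste(dup, collapse = ", "))
  if (ncol(values) < 1L) stop("descriptor table has no descriptor columns")
  if (is.null(descriptor_names)) {
    descriptor_names <- colnames(values)
    if (is.null(descriptor_names)) descriptor_names <- sprintf("desc%04d", seq_len(ncol(values)))
  }
  rownames(values) <- drug_ids
  colnames(values) <- descriptor_names
  structure(
    list(values = values, drug_ids = drug_ids,
         descriptor_names = as.character(descriptor_names),
         dropped = character(0)),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d drugs x %d descriptors (%d dropped by cleaning)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  invisible(x)
}

#' Read a drug descriptor CSV
#'
#' Accepts the usual descriptor-software export dialect: an id column
#' (`Name`, or simply the first column) followed by numeric descriptor
#' columns in a meaningful order. Non-numeric or non-finite cells become
#' `NA` and are handled by [clean_descriptors()].
#'
#' @param path CSV path.
#' @return A `descriptor_table`.
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (ncol(df) < 2L) stop("descriptor CSV needs an id column plus descriptor columns")
  id_col <- if ("Name" %in% colnames(df)) "Name" else colnames(df)[1L]
  ids <- as.character(df[[id_col]])
  rest <- df[, setdiff(colnames(df), id_col), drop = FALSE]
  m <- vapply(rest, function(col) suppressWarnings(as.numeric(col)),
              numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(NULL, colnames(rest)))
  m[!is.finite(m)] <- NA_real_
  descriptor_table(m, drug_ids = ids)
}

#' Drop unusable descriptors
#'
#' Removes every descriptor that is missing/non-finite for any drug or
#' constant across all drugs; survivors keep their original order. Dropped
#' names are recorded in the `dropped` field. Distances in the classifiers
#' require finite, non-degenerate features, so dropping (never imputing) is
#' the cleaning rule.
#'
#' @param table A `descriptor_table`.
#' @return The cleaned table.
#' @export
clean_descriptors <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  v <- table$values
  bad_missing <- apply(v, 2L, function(col) any(!is.finite(col)))
  bad_const <- rep(FALSE, ncol(v))
  ok_cols <- which(!bad_missing)
  if (nrow(v) > 1L) {
    bad_const[ok_cols] <- apply(v[, ok_cols, drop = FALSE], 2L,
                                function(col) max(col) - min(col) == 0)
  }
  drop <- bad_missing | bad_const
  if (all(drop)) stop("all descriptors dropped by cleaning")
  table$dropped <- c(table$dropped, table$descriptor_names[drop])
  table$values <- v[, !drop, drop = FALSE]
  table$descriptor_names <- table$descriptor_names[!drop]
  table
}

#' Partition descriptors into ordered contiguous groups
#'
#' Mirrors the protein fragment policy: the first `n_groups - 1` groups
#' have exactly `floor(D / n_groups)` descriptors and the last group
#' absorbs the remainder. With 1444 descriptors split 7 ways the sizes are
#' 206, 206, 206, 206, 206, 206, 208.
#'
#' @param D Number of descriptors.
#' @param n_groups Number of groups (the number of protein components, so
#'   the classifier grid is square).
#' @return Object of class `descriptor_partition`: integer matrix
#'   `n_groups` x 2 (`start`, `end`), 1-based inclusive.
#' @export
partition_descriptors <- function(D, n_groups) {
  D <- as.integer(D); n_groups <- as.integer(n_groups)
  if (n_groups < 1L) stop("n_groups must be positive")
  if (D < n_groups) stop("cannot split ", D, " descriptors into ", n_groups, " groups")
  b <- fragment_sequence(D, n_groups)
  class(b) <- c("descriptor_partition", class(b))
  b
}

#' Descriptor indices of one group
#'
#' @param partition A `descriptor_partition`.
#' @param j Group index.
#' @return Integer vector of descriptor positions.
#' @export
partition_group <- function(partition, j) {
  j <- as.integer(j)
  if (j < 1L || j > nrow(partition)) stop("group index j = ", j, " out of range")
  partition[j, 1L]:partition[j, 2L]
}

#' Build concatenated drug-target pair vectors
#'
#' Every labeled (drug, protein) pair becomes one row: the drug descriptor
#' vector first, then the protein feature vector, giving a
#' `D + n_pca * n_frag * 20` dimensional instance (2844 at the reference
#' geometry of 1444 descriptors and a 1400-feature protein encoding).
#'
#' @param pairs data.frame with columns `drug_id`, `protein_id`, `label`
#'   (0/1).
#' @param drugs A `descriptor_table` (cleaned).
#' @param proteins Protein feature matrix from [encode_proteins()]
#'   (rownames = protein ids).
#' @return Object of class `pair_set`: list with `x` (matrix, one row per
#'   pair, drug block then protein block), `drug_id`, `protein_id`,
#'   `label` (integer 0/1), `d_dim`, `p_dim`.
#' @export
build_pair_vectors <- function(pairs, drugs, proteins) {
  stopifnot(inherits(drugs, "descriptor_table"))
  req <- c("drug_id", "protein_id", "label")
  if (!all(req %in% colnames(pairs))) {
    stop("pairs needs columns ", paste(req, collapse = ", "))
  }
  miss_d <- setdiff(unique(pairs$drug_id), drugs$drug_ids)
  miss_p <- setdiff(unique(pairs$protein_id), rownames(proteins))
  if (length(miss_d) || length(miss_p)) {
    stop("unknown ids in pair table: ",
         paste(c(sprintf("drug %s", miss_d), sprintf("protein %s", miss_p)),
               collapse = ", "))
  }
  lab <- as.integer(pairs$label)
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) stop("labels must be 0/1")
  x <- cbind(drugs$values[pairs$drug_id, , drop = FALSE],
             proteins[pairs$protein_id, , drop = FALSE])
  rownames(x) <- NULL
  structure(
    list(x = x,
         drug_id = as.character(pairs$drug_id),
         protein_id = as.character(pairs$protein_id),
         label = lab,
         d_dim = ncol(drugs$values),
         p_dim = ncol(proteins)),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d pairs (%d positive), %d = %d drug + %d protein features\n",
              nrow(x$x), sum(x$label), ncol(x$x), x$d_dim, x$p_dim))
  invisible(x)
}

#' Subset a pair set by row
#'
#' @param x A `pair_set`.
#' @param i Row indices.
#' @param ... Ignored.
#' @return A `pair_set` with the selected pairs.
#' @export
`[.pair_set` <- function(x, i, ...) {
  structure(
    list(x = x$x[i, , drop = FALSE],
         drug_id = x$drug_id[i], protein_id = x$protein_id[i],
         label = x$label[i], d_dim = x$d_dim, p_dim = x$p_dim),
    class = "pair_set"
  )
}
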