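# Fragment-composition protein encoding weighted by property principal
# components. A sequence of length Len is cut into n_frag contiguous
# fragments of INT(Len/n_frag) residues (the last fragment absorbing the
# remainder); the 20 residue types are counted per fragment; and each count
# is multiplied by the matching loading entry of every retained principal
# component. The feature vector is laid out component-major:
# (component l, fragment j, residue n) -> ((l-1)*n_frag + (j-1))*20 + n.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path (plain text). The record id is the first
#'   whitespace-delimited token of the header.
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicated sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Fragment a sequence into near-equal contiguous pieces
#'
#' The first `n_frag - 1` fragments have exactly `floor(len / n_frag)`
#' residues; the last (C-terminal) fragment absorbs the remainder.
#'
#' @param len Sequence length, or a sequence string whose nchar is used.
#' @param n_frag Number of fragments; must not exceed the length.
#' @return Integer matrix `n_frag` x 2 with columns `start`, `end`
#'   (1-based, inclusive).
#' @export
#' @examples
#' fragment_sequence(25, 10)  # nine fragments of 2, last of 7
fragment_sequence <- function(len, n_frag) {
  if (is.character(len)) len <- nchar(len)
  len <- as.integer(len); n_frag <- as.integer(n_frag)
  if (n_frag < 1L) stop("n_frag must be positive")
  if (len < n_frag) {
    stop("sequence length ", len, " shorter than n_frag = ", n_frag,
         ": a fragment would be empty")
  }
  base <- len %/% n_frag
  sizes <- rep(base, n_frag)
  sizes[n_frag] <- len - base * (n_frag - 1L)
  ends <- cumsum(sizes)
  cbind(start = c(1L, utils::head(ends, -1L) + 1L), end = ends)
}

.split_residues <- function(seq, policy = c("reject", "skip")) {
  policy <- match.arg(policy)
  chars <- strsplit(toupper(seq), "")[[1L]]
  ok <- chars %in% aa_alphabet()
  if (!all(ok)) {
    if (policy == "reject") {
      stop("non-standard residue(s) in sequence: ",
           paste(unique(chars[!ok]), collapse = ", "),
           " (use policy = \"skip\" to drop them)")
    }
    chars <- chars[ok]
  }
  chars
}

#' Count per-fragment residue composition
#'
#' @param seq Residue string over the standard 20-letter alphabet.
#' @param bounds Fragment bounds from [fragment_sequence()]; computed from
#'   `n_frag` when omitted.
#' @param n_frag Number of fragments (used when `bounds` is missing).
#' @param policy `"reject"` (default) errors on non-standard residues;
#'   `"skip"` drops them before fragmenting, so bounds refer to the cleaned
#'   sequence.
#' @return Integer matrix `n_frag` x 20 of residue counts, columns in
#'   [aa_alphabet()] order; attribute `bounds` carries the fragment ranges.
#' @export
count_composition <- function(seq, bounds = NULL, n_frag = NULL,
                              policy = c("reject", "skip")) {
  chars <- .split_residues(seq, policy)
  if (is.null(bounds)) {
    if (is.null(n_frag)) stop("give bounds or n_frag")
    bounds <- fragment_sequence(length(chars), n_frag)
  }
  if (bounds[nrow(bounds), "end"] != length(chars)) {
    stop("fragment bounds do not cover the (cleaned) sequence")
  }
  alpha <- aa_alphabet()
  counts <- matrix(0L, nrow = nrow(bounds), ncol = 20L,
                   dimnames = list(NULL, alpha))
  for (j in seq_len(nrow(bounds))) {
    tab <- table(factor(chars[bounds[j, 1L]:bounds[j, 2L]], levels = alpha))
    counts[j, ] <- as.integer(tab)
  }
  attr(counts, "bounds") <- bounds
  counts
}

#' Encode one protein as a component x fragment x residue feature vector
#'
#' Feature `(l, j, n)` is `loading_l(n) * count_j(n)`: the count of residue
#' type `n` in fragment `j` weighted by that residue's loading in principal
#' component `l`. With `n_pca = 7` components and `n_frag = 10` fragments
#' the vector has 7 * 10 * 20 = 1400 entries.
#'
#' @param seq Residue string (or a one-row data.frame with a `sequence`
#'   column).
#' @param model An `aa_pca` model supplying the loadings.
#' @param n_frag Number of sequence fragments.
#' @param policy Non-standard residue policy, see [count_composition()].
#' @param frequencies If `TRUE`, counts are divided by fragment length
#'   before weighting (off by default: raw counts).
#' @return Named numeric vector of length `n_pca * n_frag * 20`, names
#'   `c{l}_f{j}_{residue}`, component-major.
#' @export
encode_protein <- function(seq, model, n_frag = 10L,
                           policy = c("reject", "skip"),
                           frequencies = FALSE) {
  stopifnot(inherits(model, "aa_pca"))
  if (is.data.frame(seq)) seq <- seq$sequence[[1L]]
  counts <- count_composition(seq, n_frag = n_frag, policy = policy)
  comp <- counts
  if (frequencies) comp <- counts / rowSums(counts)
  l_n <- model$n_components
  # block for component l = every fragment row scaled elementwise by loading l
  blocks <- lapply(seq_len(l_n), function(l) {
    as.numeric(t(comp * rep(model$loadings[, l], each = nrow(comp))))
  })
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- protein_feature_names(l_n, n_frag)
  v
}

#' Feature names of the protein encoding layout
#'
#' @param n_pca,n_frag Layout parameters.
#' @return Character vector `c{l}_f{j}_{residue}` in storage order.
#' @export
protein_feature_names <- function(n_pca, n_frag) {
  grid <- expand.grid(aa = aa_alphabet(), j = seq_len(n_frag),
                      l = seq_len(n_pca), stringsAsFactors = FALSE)
  sprintf("c%d_f%d_%s", grid$l, grid$j, grid$aa)
}

#' Encode a set of proteins into a feature matrix
#'
#' @param records data.frame with `id` and `sequence` columns (for example
#'   from [read_protein_fasta()]).
#' @inheritParams encode_protein
#' @return Numeric matrix, one row per protein (rownames = ids), columns as
#'   in [protein_feature_names()].
#' @export
encode_proteins <- function(records, model, n_frag = 10L,
                            policy = c("reject", "skip"),
                            frequencies = FALSE) {
  rows <- lapply(records$sequence, encode_protein, model = model,
                 n_frag = n_frag, policy = policy, frequencies = frequencies)
  m <- do.call(rbind, rows)
  rownames(m) <- records$id
  m
}

#' Feature indices of one protein component group
#'
#' In the component-major layout, the `20 * n_frag` features generated by
#' principal component `l` occupy one contiguous run; the groups for
#' `l = 1..n_pca` partition the full index range.
#'
#' @param n_pca,n_frag Layout parameters.
#' @param l Component index in `1..n_pca`.
#' @return Integer vector of feature positions within the protein encoding.
#' @export
component_feature_group <- function(n_pca, n_frag, l) {
  n_pca <- as.integer(n_pca); n_frag <- as.integer(n_frag); l <- as.integer(l)
  if (l < 1L || l > n_pca) stop("component index l = ", l, " out of range 1..", n_pca)
  size <- 20L * n_frag
  ((l - 1L) * size + 1L):(l * size)
}

#' Write / read a protein feature matrix as CSV
#'
#' @param m Matrix from [encode_proteins()].
#' @param path CSV path; first column `id`, then one column per feature.
#' @return `path` invisibly / the matrix.
#' @export
write_protein_encoding <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protein_encoding
#' @export
read_protein_encoding <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}
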