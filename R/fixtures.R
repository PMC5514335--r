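# Synthetic study generator. It emulates the statistical structure the
# method assumes: a low-rank amino-acid property matrix, random protein
# sequences, Gaussian drug descriptors, and an interaction label planted in
# exactly one (protein-component, drug-group) feature subspace.
#
# The planted rule is an AND over latent binary entity classes: half the
# drugs and half the proteins carry the signal class, and a pair interacts
# exactly when both do. Signal-class drugs have their signal descriptor
# group mean-shifted by effect_size standard deviations; signal-class
# proteins have their residue composition biased along the signal
# component's loading direction. The (i, j) subspace therefore sees both
# halves of the rule, row i and column j of the grid see one half each, and
# the remaining subspaces see only the weak leakage of the composition bias
# through the other components.

#' Specify a synthetic drug-target study
#'
#' @param n_drugs,n_proteins Entity counts (half of each carries the
#'   latent signal class).
#' @param n_positive Number of interacting pairs to sample.
#' @param ratio Negatives per positive (default 2, the usual recoupling
#'   ratio).
#' @param seq_len_range Min/max protein sequence length.
#' @param n_descriptors Number of drug descriptors D. The default matches
#'   the method's design premise of balanced drug/protein feature counts:
#'   with 7 groups of 200 it mirrors the 1400-feature protein encoding, so
#'   no half of a subspace swamps the other in the distance.
#' @param n_properties Number of synthetic amino-acid properties P.
#' @param property_rank Effective rank of the property matrix (<= 20).
#' @param property_noise_sd Noise added on top of the low-rank property
#'   structure, on the scale of the standardized properties.
#' @param signal_subspace Length-2 integer `(i, j)`: protein component i
#'   and descriptor group j carrying the planted signal.
#' @param effect_size Class-mean separation of the signal descriptor
#'   features, in units of their standard deviation; also scales the
#'   protein composition bias. 0 plants no signal (null fixture).
#' @param noise_sd Descriptor standard deviation.
#' @param n_pca,n_frag Encoding geometry the fixture is meant for.
#' @param seed Integer master seed; every generator derives its stream
#'   from it, so the whole study is a pure function of this spec.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 60L, n_proteins = 60L, n_positive = 100L,
                         ratio = 2, seq_len_range = c(120L, 240L),
                         n_descriptors = 1400L, n_properties = 120L,
                         property_rank = 7L, property_noise_sd = 0.02,
                         signal_subspace = c(3L, 5L), effect_size = 3,
                         noise_sd = 1, n_pca = 7L, n_frag = 10L, seed = 1L) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_proteins = as.integer(n_proteins),
               n_positive = as.integer(n_positive),
               ratio = ratio,
               seq_len_range = as.integer(seq_len_range),
               n_descriptors = as.integer(n_descriptors),
               n_properties = as.integer(n_properties),
               property_rank = as.integer(property_rank),
               property_noise_sd = property_noise_sd,
               signal_subspace = as.integer(signal_subspace),
               effect_size = effect_size,
               noise_sd = noise_sd,
               n_pca = as.integer(n_pca),
               n_frag = as.integer(n_frag),
               seed = as.integer(seed))
  if (spec$property_rank < 1L || spec$property_rank > 20L) {
    stop("property_rank must lie in 1..20")
  }
  if (spec$effect_size < 0) stop("effect_size must be nonnegative")
  if (spec$n_positive > spec$n_drugs * spec$n_proteins / 3) {
    stop("n_positive leaves no room for 1:", spec$ratio, " negatives on a ",
         spec$n_drugs, " x ", spec$n_proteins, " grid")
  }
  if (length(spec$signal_subspace) != 2L ||
      any(spec$signal_subspace < 1L) ||
      any(spec$signal_subspace > spec$n_pca)) {
    stop("signal_subspace must be a pair of indices in 1..n_pca")
  }
  if (spec$seq_len_range[1L] < spec$n_frag) {
    stop("minimum sequence length must reach n_frag = ", spec$n_frag)
  }
  if (spec$n_descriptors < spec$n_pca) {
    stop("need at least n_pca descriptors to partition")
  }
  class(spec) <- "fixture_spec"
  spec
}

# latent binary classes: exactly half of each entity set carries the signal
.fixture_classes <- function(spec) {
  set.seed(spec$seed + 2L)
  dz <- integer(spec$n_drugs)
  dz[sample.int(spec$n_drugs, spec$n_drugs %/% 2L)] <- 1L
  pz <- integer(spec$n_proteins)
  pz[sample.int(spec$n_proteins, spec$n_proteins %/% 2L)] <- 1L
  list(drug = dz, protein = pz)
}

.fixture_drug_ids <- function(spec) sprintf("D%03d", seq_len(spec$n_drugs))
.fixture_protein_ids <- function(spec) sprintf("P%03d", seq_len(spec$n_proteins))

#' Generate a low-rank synthetic amino-acid property table
#'
#' Properties are random mixtures of `property_rank` latent residue
#' profiles with geometrically decreasing weights plus Gaussian noise, so
#' a PCA of the standardized table recovers the rank: the leading
#' `property_rank` components carry almost all the variance.
#'
#' @param spec A [fixture_spec()].
#' @return An [aa_property_table()] with `n_properties` rows.
#' @export
make_property_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  r <- spec$property_rank
  p <- spec$n_properties
  basis <- matrix(stats::rnorm(r * 20L), nrow = r)       # latent residue profiles
  scales <- 2 ^ seq(r - 1L, 0L)                          # separates the spectrum
  scores <- matrix(stats::rnorm(p * r), nrow = p) %*% diag(scales, r)
  values <- scores %*% basis +
    spec$property_noise_sd * matrix(stats::rnorm(p * 20L), nrow = p) *
      mean(abs(scales))
  aa_property_table(values)
}

#' Generate random protein sequences
#'
#' Residues are drawn i.i.d. over the 20-letter alphabet: uniformly for
#' background proteins, and with probabilities tilted along the signal
#' component's loading for proteins carrying the latent signal class (so
#' their fragment encodings separate in that component's feature block).
#'
#' @param spec A [fixture_spec()].
#' @param model Optional `aa_pca` model supplying the signal loading;
#'   without it (or with `effect_size = 0`) all sequences are uniform.
#' @param protein_class Optional 0/1 vector of latent classes; default:
#'   the spec's own class assignment.
#' @return data.frame with `id` and `sequence` columns.
#' @export
make_sequences <- function(spec, model = NULL, protein_class = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(protein_class)) protein_class <- .fixture_classes(spec)$protein
  set.seed(spec$seed + 3L)
  alpha <- aa_alphabet()
  p_bg <- rep(1 / 20, 20L)
  p_sig <- p_bg
  if (!is.null(model) && spec$effect_size > 0) {
    l <- model$loadings[, spec$signal_subspace[1L]]
    beta <- min(0.9, 0.25 * spec$effect_size)
    p_sig <- (1 + beta * l / max(abs(l))) / 20
    p_sig <- p_sig / sum(p_sig)
  }
  lens <- sample(seq(spec$seq_len_range[1L], spec$seq_len_range[2L]),
                 spec$n_proteins, replace = TRUE)
  seqs <- vapply(seq_len(spec$n_proteins), function(i) {
    pr <- if (protein_class[i] == 1L) p_sig else p_bg
    paste(sample(alpha, lens[i], replace = TRUE, prob = pr), collapse = "")
  }, "")
  data.frame(id = .fixture_protein_ids(spec), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Generate descriptors and labeled pairs with the planted rule
#'
#' Drug descriptors are Gaussian; the signal descriptor group is
#' mean-shifted by `effect_size` standard deviations for drugs carrying
#' the latent class. A pair interacts exactly when both its drug and its
#' protein carry the class: positives are sampled from that grid cell and
#' negatives (at `ratio` per positive) from its complement, so the rule is
#' deterministic in the latent classes and the two label groups never
#' overlap in feature space by construction.
#'
#' @param spec A [fixture_spec()].
#' @param drug_class,protein_class Optional 0/1 latent class vectors;
#'   default: the spec's own assignment.
#' @return List with `descriptors` (a `descriptor_table`), `dataset`
#'   (data.frame `drug_id`, `protein_id`, `label`), and the class vectors.
#' @export
make_labeled_pairs <- function(spec, drug_class = NULL, protein_class = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  cls <- .fixture_classes(spec)
  if (is.null(drug_class)) drug_class <- cls$drug
  if (is.null(protein_class)) protein_class <- cls$protein
  set.seed(spec$seed + 4L)
  d_ids <- .fixture_drug_ids(spec)
  p_ids <- .fixture_protein_ids(spec)

  part <- partition_descriptors(spec$n_descriptors, spec$n_pca)
  sig_cols <- partition_group(part, spec$signal_subspace[2L])
  values <- matrix(stats::rnorm(spec$n_drugs * spec$n_descriptors,
                                sd = spec$noise_sd),
                   nrow = spec$n_drugs)
  shift <- spec$effect_size * spec$noise_sd
  values[drug_class == 1L, sig_cols] <- values[drug_class == 1L, sig_cols] + shift
  descriptors <- descriptor_table(values, drug_ids = d_ids,
                                  descriptor_names = sprintf("desc%03d", seq_len(spec$n_descriptors)))

  grid <- expand.grid(di = seq_len(spec$n_drugs), pi = seq_len(spec$n_proteins),
                      KEEP.OUT.ATTRS = FALSE)
  n_neg <- round(spec$ratio * spec$n_positive)
  if (spec$effect_size > 0) {
    in_cell <- drug_class[grid$di] == 1L & protein_class[grid$pi] == 1L
    if (sum(in_cell) < spec$n_positive) {
      stop("signal cell holds only ", sum(in_cell), " candidate positives")
    }
    if (sum(!in_cell) < n_neg) {
      stop("complement holds only ", sum(!in_cell), " candidate negatives")
    }
    pos <- grid[sample(which(in_cell), spec$n_positive), ]
    neg <- grid[sample(which(!in_cell), n_neg), ]
  } else {
    # null study: labels must be independent of features AND of entity
    # identity (repeated drug/protein blocks would otherwise let a
    # neighbour search memorize an entity-level rule), so they attach to
    # uniformly drawn distinct pairs with no latent structure at all
    take <- sample.int(nrow(grid), spec$n_positive + n_neg)
    pos <- grid[take[seq_len(spec$n_positive)], ]
    neg <- grid[take[-seq_len(spec$n_positive)], ]
  }
  dataset <- data.frame(
    drug_id = d_ids[c(pos$di, neg$di)],
    protein_id = p_ids[c(pos$pi, neg$pi)],
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
    stringsAsFactors = FALSE
  )
  rownames(dataset) <- NULL
  list(descriptors = descriptors, dataset = dataset,
       drug_class = drug_class, protein_class = protein_class)
}

#' Generate a complete synthetic study
#'
#' Runs all fixture generators in order, fits the property PCA, encodes
#' the proteins and assembles the pair vectors, optionally writing every
#' artifact in the same plain-text formats the pipeline reads (property
#' CSV, FASTA, descriptor CSV, pair CSV) plus a `fixtures.yaml` manifest
#' from which [replay_fixture()] reproduces the study exactly.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return List with the spec, the generated tables, the fitted `aa_pca`
#'   model, the encoded protein matrix, the labeled `dataset` and the
#'   assembled `pair_set`.
#' @export
simulate_dti_study <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  properties <- make_property_table(spec)
  model <- fit_property_pca(standardize_properties(properties),
                            n_components = spec$n_pca)
  cls <- .fixture_classes(spec)
  proteins <- make_sequences(spec, model = model, protein_class = cls$protein)
  lp <- make_labeled_pairs(spec, drug_class = cls$drug,
                           protein_class = cls$protein)
  encoded <- encode_proteins(proteins, model, n_frag = spec$n_frag)
  pairs <- build_pair_vectors(lp$dataset, lp$descriptors, encoded)
  study <- list(spec = spec, properties = properties, model = model,
                proteins = proteins, descriptors = lp$descriptors,
                drug_class = lp$drug_class, protein_class = lp$protein_class,
                dataset = lp$dataset, encoded = encoded, pairs = pairs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(data.frame(accession = properties$accessions,
                                properties$values, check.names = FALSE),
                     file.path(dir, "properties.csv"), row.names = FALSE)
    write_protein_fasta(proteins, file.path(dir, "proteins.fasta"))
    utils::write.csv(data.frame(Name = lp$descriptors$drug_ids,
                                lp$descriptors$values, check.names = FALSE),
                     file.path(dir, "descriptors.csv"), row.names = FALSE)
    utils::write.csv(lp$dataset, file.path(dir, "pairs.csv"), row.names = FALSE)
    write_pca_model(model, file.path(dir, "pca_model.json"))
    yaml::write_yaml(list(format = "dtiSubspace.fixture", version = 1L,
                          spec = unclass(spec)),
                     file.path(dir, "fixtures.yaml"))
  }
  study
}

#' Replay a fixture manifest
#'
#' @param manifest Path to a `fixtures.yaml` written by
#'   [simulate_dti_study()], or the parsed list.
#' @param dir Optional directory to (re)write the artifacts into.
#' @return The regenerated study, identical to the original.
#' @export
replay_fixture <- function(manifest, dir = NULL) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  if (is.null(manifest$format) || manifest$format != "dtiSubspace.fixture") {
    stop("not a fixture manifest")
  }
  spec <- do.call(fixture_spec, manifest$spec)
  simulate_dti_study(spec, dir = dir)
}
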