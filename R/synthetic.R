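# Seeded synthetic CF-MS datasets with planted complex structure, so every
# pipeline stage is testable offline.
#
# Signal model: each complex draws one Gaussian elution apex; members jitter
# around it, so complex members co-elute. Background proteins draw
# independent apexes. Complex members share an 8-mer sequence motif with
# probability motif_share, one GO leaf term and one subcellular compartment,
# which gives the sequence encoder, the GO similarity and the colocalization
# score a planted signal to recover.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the generator's study conditions: 200 proteins over 40
#' fractions (within the 27-61 range typical of co-fractionation
#' experiments), 20 planted complexes of 3-8 members, Gaussian peaks with a
#' 2-fraction standard deviation, half-fraction apex jitter, 5% relative
#' noise and 5% missingness.
#'
#' @param n_proteins total number of proteins.
#' @param n_fractions number of chromatographic fractions.
#' @param n_complexes number of planted complexes (disjoint membership).
#' @param complex_size_range integer `(min, max)` members per complex.
#' @param peak_sd Gaussian peak width, in fractions.
#' @param apex_jitter standard deviation of per-member apex displacement,
#'   in fractions.
#' @param noise_sd additive noise standard deviation, relative to each
#'   profile's peak amplitude.
#' @param missing_rate probability that an intensity cell is masked missing.
#' @param seq_len_range integer `(min, max)` sequence length in residues.
#' @param motif_share probability that a complex member carries its
#'   complex's shared 8-mer motif.
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200L, n_fractions = 40L,
                       n_complexes = 20L, complex_size_range = c(3L, 8L),
                       peak_sd = 2, apex_jitter = 0.5, noise_sd = 0.05,
                       missing_rate = 0.05, seq_len_range = c(80L, 200L),
                       motif_share = 0.8, seed = 1L) {
  cfg <- list(n_proteins = assert_count(n_proteins, "n_proteins"),
              n_fractions = assert_count(n_fractions, "n_fractions"),
              n_complexes = assert_count(n_complexes, "n_complexes"),
              complex_size_range = as.integer(complex_size_range),
              peak_sd = peak_sd, apex_jitter = apex_jitter,
              noise_sd = noise_sd, missing_rate = missing_rate,
              seq_len_range = as.integer(seq_len_range),
              motif_share = motif_share, seed = as.integer(seed))
  if (length(cfg$complex_size_range) != 2 ||
      cfg$complex_size_range[1] > cfg$complex_size_range[2] ||
      cfg$complex_size_range[1] < 1)
    stop("`complex_size_range` must be (min, max) with 1 <= min <= max")
  if (length(cfg$seq_len_range) != 2 ||
      cfg$seq_len_range[1] > cfg$seq_len_range[2] ||
      cfg$seq_len_range[1] < 8)
    stop("`seq_len_range` must be (min, max) with 8 <= min <= max")
  assert_prob(cfg$missing_rate, "missing_rate")
  assert_prob(cfg$motif_share, "motif_share")
  if (cfg$peak_sd <= 0 || cfg$apex_jitter < 0 || cfg$noise_sd < 0)
    stop("peak_sd must be > 0; apex_jitter and noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic CF-MS dataset
#'
#' @param cfg a [sim_config()].
#' @return An object of class `synthetic_dataset` with fields:
#'   `elution` (raw `elution_matrix`, missing cells as `NA`), `sequences`
#'   (named character), `catalog` (`complex_catalog` of planted complexes),
#'   `godag` (`go_dag` with one leaf term per complex plus noise
#'   annotations), `localizations` (named character, one compartment per
#'   protein), and `truth_pairs` (a `pair_label_set` derived from the
#'   catalog and the preprocessed elution via the labeling rules).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes_possible <- cfg$complex_size_range[1]:cfg$complex_size_range[2]
  if (cfg$n_complexes * cfg$complex_size_range[1] > cfg$n_proteins)
    stop("complex sizes exceed n_proteins: cannot plant disjoint complexes")
  set.seed(cfg$seed)

  ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  sizes <- sample(sizes_possible, cfg$n_complexes, replace = TRUE)
  while (sum(sizes) > cfg$n_proteins)
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  if (any(sizes < cfg$complex_size_range[1]))
    stop("complex sizes exceed n_proteins: cannot plant disjoint complexes")
  member_pool <- sample(ids, sum(sizes))
  catalog <- vector("list", cfg$n_complexes)
  names(catalog) <- sprintf("CPX%03d", seq_len(cfg$n_complexes))
  offset <- 0L
  for (c_i in seq_len(cfg$n_complexes)) {
    catalog[[c_i]] <- sort(member_pool[offset + seq_len(sizes[c_i])])
    offset <- offset + sizes[c_i]
  }

  # Elution: Gaussian peak per protein; members share a complex apex.
  fr <- seq_len(cfg$n_fractions)
  apex <- stats::runif(cfg$n_proteins, 3, cfg$n_fractions - 2)
  names(apex) <- ids
  for (c_i in seq_len(cfg$n_complexes)) {
    ca <- stats::runif(1, 3, cfg$n_fractions - 2)
    m <- catalog[[c_i]]
    apex[m] <- ca + stats::rnorm(length(m), 0, cfg$apex_jitter)
  }
  amp <- stats::runif(cfg$n_proteins, 0.5, 2)
  V <- t(vapply(seq_len(cfg$n_proteins), function(i) {
    prof <- amp[i] * stats::dnorm(fr, apex[i], cfg$peak_sd)
    peak <- max(prof)
    prof <- prof + stats::rnorm(cfg$n_fractions, 0, cfg$noise_sd * peak)
    pmax(prof, 0)
  }, numeric(cfg$n_fractions)))
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(V)) < cfg$missing_rate,
                   nrow(V), ncol(V))
    V[mask] <- NA_real_
  }
  colnames(V) <- sprintf("F%d", fr)
  elution <- elution_matrix(V, ids)

  # Sequences: uniform over canonical residues; each complex has a fixed
  # 8-mer motif inserted at a random position with probability motif_share.
  seq_len_i <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2],
                      cfg$n_proteins, replace = TRUE)
  sequences <- vapply(seq_len_i, function(L)
    paste(sample(CANONICAL_AA, L, replace = TRUE), collapse = ""),
    character(1))
  names(sequences) <- ids
  motifs <- vapply(seq_len(cfg$n_complexes), function(i)
    paste(sample(CANONICAL_AA, 8, replace = TRUE), collapse = ""),
    character(1))
  for (c_i in seq_len(cfg$n_complexes)) {
    for (m in catalog[[c_i]]) {
      if (stats::runif(1) < cfg$motif_share) {
        s <- sequences[[m]]
        pos <- sample.int(nchar(s) - 8L, 1)
        substr(s, pos, pos + 7L) <- motifs[c_i]
        sequences[[m]] <- s
      }
    }
  }

  # GO DAG: a typed toy ontology with at least one leaf per complex; each
  # complex maps to one leaf, annotated to all members, plus noise terms.
  branching <- 3L
  n_levels <- 2L
  while (branching^(n_levels - 1) < cfg$n_complexes) n_levels <- n_levels + 1L
  godag <- make_toy_godag(n_levels, branching,
                          seed = cfg$seed + 1L)
  leaves <- godag_leaves(godag)
  complex_terms <- sample(leaves, cfg$n_complexes,
                          replace = length(leaves) < cfg$n_complexes)
  ann <- data.frame(gene = character(), term = character(),
                    ontology = character(), stringsAsFactors = FALSE)
  for (c_i in seq_len(cfg$n_complexes)) {
    m <- catalog[[c_i]]
    ann <- rbind(ann, data.frame(gene = m, term = complex_terms[c_i],
                                 ontology = "BP"))
  }
  noise_pick <- stats::runif(cfg$n_proteins) < 0.3
  background <- setdiff(ids, unlist(catalog))
  extra_genes <- union(background, ids[noise_pick])
  if (length(extra_genes))
    ann <- rbind(ann, data.frame(gene = extra_genes,
                                 term = sample(leaves, length(extra_genes),
                                               replace = TRUE),
                                 ontology = "BP"))
  ann <- unique(ann)
  godag <- set_annotations(godag, ann)

  # Localizations: one compartment per complex; background proteins random.
  compartments <- c("nucleus", "cytosol", "mitochondrion", "membrane",
                    "endoplasmic reticulum", "golgi", "peroxisome")
  loc <- stats::setNames(sample(compartments, cfg$n_proteins, replace = TRUE),
                         ids)
  cpx_comp <- sample(compartments, cfg$n_complexes, replace = TRUE)
  for (c_i in seq_len(cfg$n_complexes)) loc[catalog[[c_i]]] <- cpx_comp[c_i]

  cat_obj <- new_complex_catalog(catalog)
  truth <- derive_pair_labels(cat_obj, preprocess_elution(elution),
                              include_experimental = FALSE)
  structure(list(elution = elution, sequences = sequences,
                 catalog = cat_obj, godag = godag, localizations = loc,
                 truth_pairs = truth, config = cfg),
            class = "synthetic_dataset")
}

#' Build a small typed GO-like DAG
#'
#' Constructs a rooted tree with `n_levels` levels and `branching` children
#' per node; each child-parent edge is typed `is_a` (probability 0.75) or
#' `part_of`. Genes, when supplied, are each annotated to one random leaf.
#'
#' @param n_levels number of levels including the root (>= 2).
#' @param branching children per internal node.
#' @param seed integer seed.
#' @param genes optional character vector of gene ids to annotate to leaves.
#' @return A `go_dag`.
#' @export
make_toy_godag <- function(n_levels, branching, seed = 1L, genes = NULL) {
  n_levels <- assert_count(n_levels, "n_levels", min = 2)
  branching <- assert_count(branching, "branching")
  set.seed(seed)
  terms <- "GO:1"
  edges <- data.frame(child = character(), parent = character(),
                      type = character(), stringsAsFactors = FALSE)
  frontier <- terms
  counter <- 1L
  for (lvl in seq_len(n_levels - 1)) {
    nxt <- character(0)
    for (p in frontier) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- paste0("GO:", counter)
        type <- if (stats::runif(1) < 0.75) "is_a" else "part_of"
        edges <- rbind(edges, data.frame(child = id, parent = p, type = type))
        nxt <- c(nxt, id)
      }
    }
    terms <- c(terms, nxt)
    frontier <- nxt
  }
  ann <- if (!is.null(genes)) {
    data.frame(gene = genes,
               term = sample(frontier, length(genes), replace = TRUE),
               ontology = "BP", stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), term = character(), ontology = character())
  }
  go_dag(terms, edges, ann)
}

#' Write all components of a synthetic dataset to plain-text files
#'
#' Writes `elution.tsv`, `sequences.fasta`, `complexes.gmt`,
#' `ontology.obo`, `annotations.tsv` and `localizations.tsv` into `dir`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_elution(ds$elution, file.path(dir, "elution.tsv"))
  aa <- Biostrings::AAStringSet(ds$sequences)
  Biostrings::writeXStringSet(aa, file.path(dir, "sequences.fasta"))
  write_complexes(ds$catalog, file.path(dir, "complexes.gmt"))
  write_obo(ds$godag, file.path(dir, "ontology.obo"))
  write_annotations(ds$godag, file.path(dir, "annotations.tsv"))
  utils::write.table(
    data.frame(protein = names(ds$localizations),
               localization = unname(ds$localizations)),
    file.path(dir, "localizations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d proteins, %d fractions, %d planted complexes\n",
    length(x$sequences), x$elution$original_fractions,
    length(x$catalog$complexes)))
  invisible(x)
}
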