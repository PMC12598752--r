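# Run configuration, manifests and pipeline orchestration.

#' Full pipeline run configuration
#'
#' Collects every stage parameter, with the package defaults, into one
#' manifest-ready list. Every stochastic step derives its seed from the
#' single `seed` field, so a manifest reproduces a run exactly.
#'
#' @param seed master integer seed.
#' @param sim a [sim_config()] for synthetic runs (`NULL` when reading
#'   real inputs).
#' @param resolution,scale FCGR parameters.
#' @param target_len padded profile length.
#' @param min_size minimum reference complex size.
#' @param folds cross-validation fold count.
#' @param model a [model_config()].
#' @param score_floor,expansion,inflation,iterations,tom_power,weightings,min_cluster,deep_split,limit,merge_threshold
#'   clustering-stack parameters (see [cluster_complexes()]).
#' @param saliency_margin saliency categorization band half-width.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = sim_config(seed = seed),
                       resolution = 16L, scale = 0.863271,
                       target_len = 200L, min_size = 3L, folds = 5L,
                       model = model_config(seed = seed),
                       score_floor = 0.5, expansion = 2L, inflation = 2,
                       iterations = 3L, tom_power = 2.5,
                       weightings = list(c(0.3, 0.7), c(0.1, 0.9)),
                       min_cluster = 3L, deep_split = 3L, limit = 100L,
                       merge_threshold = 0.25, saliency_margin = 0.1) {
  structure(list(seed = as.integer(seed), sim = sim,
                 resolution = resolution, scale = scale,
                 target_len = target_len, min_size = min_size,
                 folds = folds, model = model, score_floor = score_floor,
                 expansion = expansion, inflation = inflation,
                 iterations = iterations, tom_power = tom_power,
                 weightings = weightings, min_cluster = min_cluster,
                 deep_split = deep_split, limit = limit,
                 merge_threshold = merge_threshold,
                 saliency_margin = saliency_margin),
            class = "run_config")
}

#' Write a run configuration as a YAML manifest
#' @param cfg a `run_config`.
#' @param path output file path.
#' @export
write_manifest <- function(cfg, path) {
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(c(list(manifest_version = 1L), plain), path)
  invisible(path)
}

#' Read a YAML manifest back into a run configuration
#' @param path manifest file path.
#' @return A `run_config`.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  y$manifest_version <- NULL
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim)
  model <- do.call(model_config, y$model)
  y$sim <- NULL; y$model <- NULL
  y$weightings <- lapply(y$weightings, as.numeric)
  do.call(run_config, c(y, list(sim = sim, model = model)))
}

#' Run the full inference pipeline on a synthetic dataset
#'
#' Chains every stage: simulation, preprocessing and padding, FCGR
#' encoding, pair labeling and fold assignment, cross-validated training,
#' all-pairs scoring, complex detection, and evaluation by composite,
#' GOGO and colocalization scores plus saliency categorization. All
#' artifacts (TSV/GMT/JSON and the manifest) are written under `outdir`.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the dataset, model, edge list, clusters
#'   and the metrics report.
#' @export
run_pipeline <- function(cfg = run_config(), outdir = tempfile("cfnet_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("simulating dataset")
  ds <- simulate_dataset(cfg$sim)
  write_dataset(ds, file.path(outdir, "data"))

  say("preprocessing elution profiles")
  E <- pad_profiles(preprocess_elution(ds$elution), cfg$target_len)

  say("encoding sequences (FCGR)")
  S <- fcgr_encode_all(ds$sequences[E$protein_ids],
                       cfg$resolution, cfg$scale)

  say("labeling pairs and assigning folds")
  catalog <- restrict_catalog(ds$catalog, E$protein_ids, cfg$min_size)
  labels <- derive_pair_labels(catalog, E)
  labels <- make_folds(labels, k = cfg$folds, seed = cfg$seed)

  say("training classifier (", cfg$folds, "-fold CV)")
  model <- train_model(E, S, labels, cfg$model)

  say("scoring all pairs")
  edges <- score_edge_list(model, labels)
  utils::write.table(edges, file.path(outdir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("clustering")
  clusters <- cluster_complexes(
    edges, score_floor = cfg$score_floor, expansion = cfg$expansion,
    inflation = cfg$inflation, iterations = cfg$iterations,
    tom_power = cfg$tom_power, weightings = cfg$weightings,
    min_cluster = cfg$min_cluster, deep_split = cfg$deep_split,
    limit = cfg$limit, threshold = cfg$merge_threshold)
  write_complexes(clusters, file.path(outdir, "clusters.gmt"))
  write_clusters_long(clusters, file.path(outdir, "clusters_long.tsv"))

  say("evaluating")
  report <- evaluate_clusters(clusters, catalog, ds$godag,
                              ds$localizations)
  pred_pos <- edges[edges$score > 0.5, c("protein_a", "protein_b")]
  if (nrow(pred_pos) > 0) {
    n_sal <- min(nrow(pred_pos), 200L)
    set.seed(cfg$seed)
    sal <- saliency_categories(
      model, pred_pos[sample.int(nrow(pred_pos), n_sal), ],
      margin = cfg$saliency_margin)
    report$saliency_category_counts <- as.list(table(sal$category))
  }
  if (!is.null(model$cv_metrics))
    report$cv_mean <- as.list(colMeans(
      model$cv_metrics[, c("sensitivity", "specificity", "mcc",
                           "auc", "accuracy")]))
  jsonlite::write_json(report, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(cfg, file.path(outdir, "manifest.yaml"))
  invisible(list(dataset = ds, model = model, edges = edges,
                 clusters = clusters, report = report))
}

#' Evaluate a cluster set against reference structure, function and space
#'
#' @param clusters a `cluster_set`.
#' @param catalog reference `complex_catalog`.
#' @param godag a `go_dag` with annotations (or `NULL` to skip).
#' @param localizations named protein -> compartment vector (or `NULL`).
#' @return List with the composite-score components and the mean GOGO and
#'   colocalization scores across clusters.
#' @export
evaluate_clusters <- function(clusters, catalog, godag = NULL,
                              localizations = NULL) {
  report <- composite_score(clusters, catalog)
  cl <- clusters$clusters
  if (!is.null(godag)) {
    gogo <- suppressMessages(
      vapply(cl, gogo_cluster_score, numeric(1), dag = godag))
    report$gogo_mean <- mean(gogo, na.rm = TRUE)
  }
  if (!is.null(localizations)) {
    coloc <- suppressMessages(
      vapply(cl, colocalization_score, numeric(1),
             localizations = localizations))
    report$colocalization_mean <- mean(coloc, na.rm = TRUE)
  }
  report
}
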