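# Shared fixtures, built in code once per test run.

# Small, fast study conditions for unit tests (noiseless so planted
# structure is exactly recoverable).
tiny_sim <- function(seed = 3, ...) {
  sim_config(n_proteins = 60L, n_fractions = 30L, n_complexes = 8L,
             complex_size_range = c(3L, 6L), peak_sd = 1.5,
             apex_jitter = 0.3, noise_sd = 0, missing_rate = 0,
             seq_len_range = c(60L, 120L), motif_share = 0.9,
             seed = seed, ...)
}

# A light model configuration for architecture/behaviour tests.
tiny_model_cfg <- function(seed = 5, epochs = 15L, ...) {
  model_config(n_filters = 8L, kernel_width = 5L, fc_sizes = c(32L, 8L, 1L),
               dropout_rate = 0.1, epochs = epochs, seed = seed, ...)
}

# Three-node toy DAG: root R with children T1, T2.
toy_dag <- function(type = "is_a") {
  go_dag(c("R", "T1", "T2"),
         data.frame(child = c("T1", "T2"), parent = c("R", "R"),
                    type = type, stringsAsFactors = FALSE))
}

# Prepared tiny dataset shared across model-level tests (built lazily,
# cached for the whole run).
.fixture_env <- new.env()

tiny_prepared <- function() {
  if (is.null(.fixture_env$prep)) {
    ds <- simulate_dataset(tiny_sim())
    E <- pad_profiles(preprocess_elution(ds$elution))
    S <- fcgr_encode_all(ds$sequences[E$protein_ids])
    labels <- suppressMessages(derive_pair_labels(ds$catalog, E))
    labels <- make_folds(labels, k = 3, seed = 3)
    .fixture_env$prep <- list(ds = ds, E = E, S = S, labels = labels)
  }
  .fixture_env$prep
}

tiny_trained <- function() {
  if (is.null(.fixture_env$model)) {
    p <- tiny_prepared()
    .fixture_env$model <- train_model(p$E, p$S, p$labels, tiny_model_cfg())
  }
  .fixture_env$model
}

# Block-structured adjacency: `blocks` groups of `size` nodes with strong
# intra-block and zero inter-block weights.
block_adjacency <- function(blocks = 2, size = 5, w = 0.9) {
  n <- blocks * size
  ids <- sprintf("n%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (b in seq_len(blocks)) {
    idx <- ((b - 1) * size + 1):(b * size)
    W[idx, idx] <- w
  }
  diag(W) <- 0
  structure(list(node_ids = ids, W = W), class = "adjacency")
}
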