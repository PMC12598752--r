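# Public surface of the pair classifier: configuration, input assembly,
# cross-validated training, prediction and multi-dataset co-training.

#' Classifier configuration
#'
#' @param n_filters number of convolution filters F (default 32).
#' @param kernel_width odd convolution kernel width (default 5); odd so the
#'   length-preserving convolution is centred and the raw input can be
#'   re-added to each channel.
#' @param fc_sizes sizes of the three fully connected layers; the last must
#'   be 1 (the logistic output unit).
#' @param dropout_rate dropout probability on the two hidden FC layers.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs per fit.
#' @param batch_size minibatch size; 0 means full batch.
#' @param seed integer seed controlling initialization, dropout and
#'   shuffling.
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(n_filters = 32L, kernel_width = 5L,
                         fc_sizes = c(64L, 16L, 1L), dropout_rate = 0.2,
                         weight_decay = 1e-4, learning_rate = 1e-3,
                         epochs = 40L, batch_size = 0L, seed = 1L) {
  n_filters <- assert_count(n_filters, "n_filters")
  kernel_width <- assert_count(kernel_width, "kernel_width")
  if (kernel_width %% 2L == 0L)
    stop("`kernel_width` must be odd (length-preserving convolution)")
  fc_sizes <- as.integer(fc_sizes)
  if (length(fc_sizes) != 3 || fc_sizes[3] != 1L || any(fc_sizes < 1L))
    stop("`fc_sizes` must be three positive sizes ending in 1")
  assert_prob(dropout_rate, "dropout_rate")
  structure(list(n_filters = n_filters, kernel_width = kernel_width,
                 fc_sizes = fc_sizes, dropout_rate = dropout_rate,
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 epochs = assert_count(epochs, "epochs"),
                 batch_size = assert_count(batch_size, "batch_size", min = 0),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Assemble the classifier input matrix
#'
#' Each protein's row is the concatenation of its padded CF-MS profile
#' (length 200 by default) with the sum of its FCGR vector and its
#' trainable embedding row (length 256): `[E_i | S_i + C_i]`. Both blocks
#' are already scaled to `[0,1]` by the preprocessing and FCGR
#' normalization. Protein ordering must be identical across inputs.
#'
#' @param E a normalized, padded `elution_matrix`.
#' @param S an `fcgr_matrix` over the same proteins in the same order.
#' @param C embedding matrix (same shape as `S$vectors`) or `NULL` for the
#'   embedding-free variant.
#' @return Numeric matrix `N x (padded_len + resolution^2)` with protein
#'   ids as row names.
#' @export
assemble_input <- function(E, S, C = NULL) {
  stopifnot(inherits(E, "elution_matrix"), inherits(S, "fcgr_matrix"))
  if (!E$normalized || is.null(E$padded_to))
    stop("E must be normalized and padded before assembly")
  if (!identical(E$protein_ids, S$protein_ids)) {
    off <- union(setdiff(E$protein_ids, S$protein_ids),
                 setdiff(S$protein_ids, E$protein_ids))
    stop("protein ids differ between elution and FCGR matrices: ",
         paste(utils::head(off, 10), collapse = ", "),
         if (length(off) > 10) " ..." else "")
  }
  seq_block <- S$vectors
  if (!is.null(C)) {
    if (!all(dim(C) == dim(S$vectors)))
      stop("embedding matrix shape must match the FCGR matrix")
    seq_block <- seq_block + C
  }
  X <- cbind(E$values, seq_block)
  rownames(X) <- E$protein_ids
  X
}

pairs_to_index <- function(pairs, protein_ids) {
  if (is.data.frame(pairs))
    pairs <- cbind(pairs$protein_a, pairs$protein_b)
  if (is.character(pairs)) pairs <- matrix(pairs, ncol = 2)
  if (is.character(pairs[1])) {
    idx <- cbind(match(pairs[, 1], protein_ids),
                 match(pairs[, 2], protein_ids))
    if (anyNA(idx)) {
      bad <- unique(c(pairs[, 1][is.na(idx[, 1])],
                      pairs[, 2][is.na(idx[, 2])]))
      stop("unknown proteins in pairs: ", paste(bad, collapse = ", "))
    }
    idx
  } else {
    matrix(as.integer(pairs), ncol = 2)
  }
}

# Core fitting loop shared by train_model and co_train. `sets` is a list of
# per-dataset lists: Ecf (N x cfms_len), S (fcgr_matrix), pair index matrix,
# labels y. Batches are drawn round-robin across datasets within each epoch.
fit_network <- function(sets, cfg, use_embedding) {
  input_len <- ncol(sets[[1]]$Ecf) + ncol(sets[[1]]$S$vectors)
  for (s in sets)
    if (ncol(s$Ecf) + ncol(s$S$vectors) != input_len)
      stop("incompatible input widths across datasets")
  params <- nn_init(cfg, input_len, nrow(sets[[1]]$Ecf), use_embedding,
                    seq_len = ncol(sets[[1]]$S$vectors))
  state <- list(t = 0L, m = list(), v = list())
  seq_cols <- (ncol(sets[[1]]$Ecf) + 1L):input_len
  log <- data.frame(epoch = integer(), dataset = integer(), loss = numeric())
  for (ep in seq_len(cfg$epochs)) {
    for (d in seq_along(sets)) {
      s <- sets[[d]]
      np <- nrow(s$pairs)
      batches <- if (cfg$batch_size == 0L || cfg$batch_size >= np)
        list(seq_len(np))
      else
        split(sample.int(np), ceiling(seq_len(np) / cfg$batch_size))
      for (b in batches) {
        X <- cbind(s$Ecf, if (use_embedding && d == 1L)
          s$S$vectors + params$C else s$S$vectors)
        fwd <- nn_forward(params, X, s$pairs[b, , drop = FALSE],
                          training = TRUE, dropout_rate = cfg$dropout_rate)
        loss <- bce_loss(fwd$scores, s$y[b])
        if (!is.finite(loss))
          stop(sprintf("training loss diverged (non-finite) at epoch %d", ep))
        dU3 <- (fwd$scores - s$y[b]) / length(b)
        bwd <- nn_backward(params, fwd, dU3,
                           need_input_grad = use_embedding && d == 1L)
        grads <- bwd$grads
        if (use_embedding && d == 1L)
          grads$C <- bwd$dX[, seq_cols, drop = FALSE]
        upd <- adam_step(params, grads, state,
                         cfg$learning_rate, cfg$weight_decay)
        params <- upd$params; state <- upd$state
      }
      log <- rbind(log, data.frame(epoch = ep, dataset = d, loss = loss))
    }
  }
  list(params = params, log = log)
}

new_cfnet_model <- function(params, protein_ids, X, layout, cfg,
                            log, cv_metrics = NULL) {
  structure(list(params = params, embedding = params$C,
                 protein_ids = protein_ids, X = X, layout = layout,
                 config = cfg, training_log = log, cv_metrics = cv_metrics),
            class = "cfnet_model")
}

#' Train the pair classifier with cross-validated evaluation
#'
#' For each fold the model is trained from the same seeded initialization
#' on the remaining folds and evaluated on the held-out fold at the hard
#' 0.5 threshold (sensitivity, specificity, MCC, AUC); a final model is
#' then retrained on all balanced folds. The protein embedding matrix is a
#' trainable parameter updated by backpropagation, so complex-label
#' information is absorbed into the protein representations.
#'
#' @param E a normalized, padded `elution_matrix`.
#' @param S an `fcgr_matrix` over the same proteins.
#' @param labels a `pair_label_set` with folds assigned (see
#'   [make_folds()]).
#' @param cfg a [model_config()].
#' @param use_embedding set `FALSE` for the embedding-free variant.
#' @return An object of class `cfnet_model` with the trained parameters,
#'   the assembled input matrix, the per-fold metric table (`cv_metrics`)
#'   and the training log.
#' @export
train_model <- function(E, S, labels, cfg = model_config(),
                        use_embedding = TRUE) {
  stopifnot(inherits(labels, "pair_label_set"))
  bal <- labels[!is.na(labels$fold) & labels$label != "experimental", ]
  if (nrow(bal) == 0) stop("no balanced folds available; run make_folds()")
  idx <- pairs_to_index(bal, E$protein_ids)
  y <- as.numeric(bal$label == "positive")
  folds <- sort(unique(bal$fold))
  layout <- list(cfms_len = ncol(E$values), seq_len = ncol(S$vectors),
                 order = "cfms-then-sequence",
                 original_fractions = E$original_fractions)

  cv <- NULL
  if (length(folds) > 1) {
    cv <- do.call(rbind, lapply(folds, function(f) {
      tr <- bal$fold != f
      set.seed(cfg$seed + f)
      fit <- fit_network(list(list(Ecf = E$values, S = S,
                                   pairs = idx[tr, , drop = FALSE],
                                   y = y[tr])),
                         cfg, use_embedding)
      Xf <- cbind(E$values, if (use_embedding) S$vectors + fit$params$C
                  else S$vectors)
      sc <- nn_forward(fit$params, Xf, idx[!tr, , drop = FALSE],
                       keep_cache = FALSE)$scores
      m <- classification_metrics(y[!tr], sc)
      data.frame(fold = f, n_test = sum(!tr),
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 mcc = m$mcc, auc = m$auc,
                 accuracy = mean((sc > 0.5) == (y[!tr] == 1)))
    }))
  }
  set.seed(cfg$seed)
  fit <- fit_network(list(list(Ecf = E$values, S = S, pairs = idx, y = y)),
                     cfg, use_embedding)
  X <- cbind(E$values, if (use_embedding) S$vectors + fit$params$C
             else S$vectors)
  rownames(X) <- E$protein_ids
  new_cfnet_model(fit$params, E$protein_ids, X, layout, cfg, fit$log, cv)
}

#' Score protein pairs with a trained model
#'
#' Scores are symmetric in the pair order by construction (absolute
#' feature differences). Large pair lists are scored in chunks; each
#' protein row is convolved once per chunk regardless of how many pairs it
#' participates in, and the total number of convolved rows is attached as
#' attribute `conv_applications`.
#'
#' @param model a `cfnet_model`.
#' @param pairs two-column matrix/data.frame of protein ids or row indices.
#' @param X optional input matrix overriding the model's stored one (used
#'   for cross-dataset prediction with embedding-free models).
#' @param chunk_size pairs per scoring chunk.
#' @return Numeric vector of scores in `(0,1)`.
#' @export
predict_pairs <- function(model, pairs, X = model$X, chunk_size = 1024L) {
  stopifnot(inherits(model, "cfnet_model"))
  if (is.null(X)) stop("no input matrix available; supply X")
  idx <- pairs_to_index(pairs, rownames(X))
  np <- nrow(idx)
  scores <- numeric(np)
  fmaps <- nn_feature_maps(model$params, X)  # convolve each protein once
  starts <- seq(1L, np, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, np)
    fwd <- nn_forward(model$params, X, idx[s:e, , drop = FALSE],
                      keep_cache = FALSE, fmaps = fmaps)
    scores[s:e] <- fwd$scores
  }
  attr(scores, "conv_applications") <- fmaps$n_conv
  scores
}

#' Score pairs and return a labeled edge list
#'
#' @param model a `cfnet_model`.
#' @param labels a `pair_label_set`; all its pairs are scored.
#' @return data.frame with `protein_a`, `protein_b`, `label_origin`
#'   (`train`, `test` or `experimental`) and `score`.
#' @export
score_edge_list <- function(model, labels) {
  stopifnot(inherits(labels, "pair_label_set"))
  sc <- predict_pairs(model, labels)
  origin <- ifelse(labels$label == "experimental", "experimental",
                   ifelse(is.na(labels$fold), "experimental", "train"))
  data.frame(protein_a = labels$protein_a, protein_b = labels$protein_b,
             label_origin = origin, score = as.numeric(sc),
             stringsAsFactors = FALSE)
}

#' Co-train the embedding-free classifier on several datasets
#'
#' All elution matrices must be padded to the same length so the network
#' accepts every dataset. Training pair lists are down-sampled (seeded,
#' without replacement) to the size of the smallest set so each dataset
#' contributes equally, and batches are drawn round-robin across datasets.
#' The embedding layer is disabled: supervised embeddings are tied to one
#' dataset's protein roster, which cross-dataset training cannot share.
#'
#' @param datasets list of lists with elements `elution` (normalized,
#'   padded `elution_matrix`), `fcgr` (`fcgr_matrix`) and `labels`
#'   (a `pair_label_set` with folds assigned).
#' @param cfg a [model_config()].
#' @return A `cfnet_model` without embeddings (`X` is `NULL`; pass `X` to
#'   [predict_pairs()] built from any compatible dataset).
#' @export
co_train <- function(datasets, cfg = model_config()) {
  stopifnot(length(datasets) >= 1)
  sets <- lapply(datasets, function(d) {
    bal <- d$labels[!is.na(d$labels$fold) &
                      d$labels$label != "experimental", ]
    list(Ecf = d$elution$values, S = d$fcgr,
         pairs = pairs_to_index(bal, d$elution$protein_ids),
         y = as.numeric(bal$label == "positive"))
  })
  widths <- vapply(sets, function(s) ncol(s$Ecf) + ncol(s$S$vectors),
                   numeric(1))
  if (length(unique(widths)) != 1)
    stop("incompatible input widths: ", paste(widths, collapse = ", "))
  set.seed(cfg$seed)
  n_min <- min(vapply(sets, function(s) nrow(s$pairs), integer(1)))
  sets <- lapply(sets, function(s) {
    if (nrow(s$pairs) > n_min) {
      keep <- sort(sample.int(nrow(s$pairs), n_min))
      s$pairs <- s$pairs[keep, , drop = FALSE]
      s$y <- s$y[keep]
    }
    s
  })
  fit <- fit_network(sets, cfg, use_embedding = FALSE)
  layout <- list(cfms_len = ncol(sets[[1]]$Ecf),
                 seq_len = ncol(sets[[1]]$S$vectors),
                 order = "cfms-then-sequence",
                 original_fractions = NA_integer_)
  new_cfnet_model(fit$params, NULL, NULL, layout, cfg, fit$log)
}

#' Flattened convolutional feature representations of proteins
#'
#' Extracts the post-residual feature map for every protein and flattens
#' the filter dimension, giving one feature representation row per
#' protein (used e.g. for the complex-separation analysis).
#'
#' @param model a `cfnet_model`.
#' @param X optional input matrix overriding the model's stored one.
#' @return Numeric matrix `N x (input_len * n_filters)` with protein ids
#'   as row names.
#' @export
feature_representations <- function(model, X = model$X) {
  stopifnot(inherits(model, "cfnet_model"))
  if (is.null(X)) stop("no input matrix available; supply X")
  params <- model$params
  K <- nrow(params$Wc); F_ <- ncol(params$Wc)
  ctr <- (K + 1L) %/% 2L
  Xsh <- lapply(seq_len(K), function(k) shift_cols(X, k - ctr))
  out <- matrix(0, nrow(X), ncol(X) * F_)
  for (f in seq_len(F_)) {
    Pf <- matrix(params$bc[f], nrow(X), ncol(X))
    for (k in seq_len(K)) Pf <- Pf + params$Wc[k, f] * Xsh[[k]]
    out[, ((f - 1L) * ncol(X) + 1L):(f * ncol(X))] <- relu(Pf) + X
  }
  rownames(out) <- rownames(X)
  out
}

#' @export
print.cfnet_model <- function(x, ...) {
  cat(sprintf(
    "cfnet_model: input %d + %d, %d filters (kernel %d), fc %s%s\n",
    x$layout$cfms_len, x$layout$seq_len, ncol(x$params$Wc),
    nrow(x$params$Wc), paste(x$config$fc_sizes, collapse = "-"),
    if (is.null(x$params$C)) ", no embedding" else ""))
  if (!is.null(x$cv_metrics)) {
    cat("mean held-out metrics:\n")
    print(colMeans(x$cv_metrics[, c("sensitivity", "specificity",
                                    "mcc", "auc", "accuracy")]))
  }
  invisible(x)
}
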