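# Classifier architecture contracts and training behaviour.

test_that("assembled input concatenates CF-MS with FCGR plus embedding", {
  p <- tiny_prepared()
  n <- length(p$E$protein_ids)
  C0 <- matrix(0, n, 256)
  X <- assemble_input(p$E, p$S, C0)
  expect_equal(ncol(X), 200 + 256)
  # zero embedding: exact concatenation
  expect_equal(unname(X), unname(cbind(p$E$values, p$S$vectors)))
  # nonzero embedding adds to the sequence block only
  C1 <- matrix(0.5, n, 256)
  X1 <- assemble_input(p$E, p$S, C1)
  expect_equal(X1[, 1:200], X[, 1:200])
  expect_equal(unname(X1[, 201:456]), unname(p$S$vectors + 0.5))
  # permuting protein order permutes rows identically
  ord <- sample(n)
  Ep <- p$E; Ep$protein_ids <- p$E$protein_ids[ord]
  Ep$values <- p$E$values[ord, ]
  Sp <- p$S; Sp$protein_ids <- p$S$protein_ids[ord]
  Sp$vectors <- p$S$vectors[ord, ]
  Xp <- assemble_input(Ep, Sp, C0[ord, , drop = FALSE])
  expect_equal(Xp, X[ord, ])
  # id mismatch errors and names the offender
  Sbad <- p$S
  Sbad$protein_ids[1] <- "NOT_A_PROTEIN"
  expect_error(assemble_input(p$E, Sbad, C0), "NOT_A_PROTEIN")
})

test_that("training is seeded, deterministic, and reports fold metrics", {
  m1 <- tiny_trained()
  p <- tiny_prepared()
  m2 <- train_model(p$E, p$S, p$labels, tiny_model_cfg())
  expect_identical(m1$params$W1, m2$params$W1)
  expect_identical(tail(m1$training_log$loss, 1),
                   tail(m2$training_log$loss, 1))
  expect_equal(nrow(m1$cv_metrics), 3)
  expect_true(all(c("sensitivity", "specificity", "mcc", "auc") %in%
                    names(m1$cv_metrics)))
})

test_that("pair scores are symmetric, bounded, and self-pairs collapse", {
  m <- tiny_trained()
  n <- length(m$protein_ids)
  set.seed(61)
  pick <- cbind(sample(n, 25, replace = TRUE), sample(n, 25, replace = TRUE))
  pick <- pick[pick[, 1] != pick[, 2], , drop = FALSE]
  s_ij <- predict_pairs(m, pick)
  s_ji <- predict_pairs(m, pick[, 2:1])
  expect_equal(as.numeric(s_ij), as.numeric(s_ji), tolerance = 1e-12)
  expect_true(all(s_ij > 0 & s_ij < 1))
  # all self-pairs give one identical score (the zero-difference value)
  selfs <- predict_pairs(m, cbind(1:5, 1:5))
  expect_true(max(abs(selfs - selfs[1])) < 1e-12)
})

test_that("convolution applications scale with proteins, not pairs", {
  m <- tiny_trained()
  pairs10 <- t(combn(10, 2))  # 45 pairs over 10 proteins
  X10 <- m$X[1:10, , drop = FALSE]
  s <- predict_pairs(m, pairs10, X = X10)
  expect_length(s, 45)
  expect_equal(attr(s, "conv_applications"), 10)
  # with many more pairs over the same proteins, unchanged
  pairs_rep <- pairs10[rep(1:45, 4), ]
  s2 <- predict_pairs(m, pairs_rep, X = X10)
  expect_equal(attr(s2, "conv_applications"), 10)
})

test_that("convolution parameter count is kernel_width x filters plus biases", {
  m <- tiny_trained()
  cfg <- m$config
  expect_equal(dim(m$params$Wc), c(cfg$kernel_width, cfg$n_filters))
  expect_length(m$params$bc, cfg$n_filters)
  # pair-level convolution over stacked pairs would double the kernel rows
  expect_equal(length(m$params$Wc),
               (2 * cfg$kernel_width * cfg$n_filters) / 2)
})

test_that("embedding rows receive gradient during training", {
  p <- tiny_prepared()
  cfg <- tiny_model_cfg(epochs = 1L)
  m <- train_model(p$E, p$S, p$labels, cfg)
  init <- cfnet:::nn_init(cfg, 456L, length(p$E$protein_ids), TRUE)
  expect_gt(max(abs(m$params$C - init$C)), 0)
  # embedding-free variant has no embedding matrix
  m0 <- train_model(p$E, p$S, p$labels, cfg, use_embedding = FALSE)
  expect_null(m0$params$C)
})

test_that("training loss decreases on the noiseless fixture", {
  m <- tiny_trained()
  loss <- m$training_log$loss
  k <- length(loss)
  expect_lt(mean(tail(loss, 3)), mean(head(loss, 3)))
})

test_that("network gradients match finite differences", {
  # tiny instance, analytically checkable
  set.seed(62)
  cfg <- model_config(n_filters = 2L, kernel_width = 3L,
                      fc_sizes = c(4L, 3L, 1L), dropout_rate = 0,
                      epochs = 1L, seed = 7)
  X <- matrix(runif(4 * 10), 4, 10)
  pairs <- rbind(c(1L, 2L), c(3L, 4L))
  y <- c(1, 0)
  params <- cfnet:::nn_init(cfg, 10L, 4L, FALSE)
  fwd <- cfnet:::nn_forward(params, X, pairs)
  dU3 <- (fwd$scores - y) / 2
  bwd <- cfnet:::nn_backward(params, fwd, dU3, need_input_grad = TRUE)
  loss_at <- function(par) {
    f <- cfnet:::nn_forward(par, X, pairs, keep_cache = FALSE)
    cfnet:::bce_loss(f$scores, y)
  }
  eps <- 1e-6
  for (nm in c("Wc", "W1", "W3", "bc", "b2")) {
    g_num <- params[[nm]]
    for (i in seq_along(g_num)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g_num[i] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    }
    expect_equal(as.numeric(bwd$grads[[nm]]), as.numeric(g_num),
                 tolerance = 1e-4, label = paste("grad", nm))
  }
  # input gradient: perturb X entries touched by both paths
  gX_num <- matrix(0, 4, 10)
  for (i in seq_len(4)) for (j in seq_len(10)) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + eps
    Xm <- X; Xm[i, j] <- Xm[i, j] - eps
    fp <- cfnet:::nn_forward(params, Xp, pairs, keep_cache = FALSE)
    fm <- cfnet:::nn_forward(params, Xm, pairs, keep_cache = FALSE)
    gX_num[i, j] <- (cfnet:::bce_loss(fp$scores, y) -
                       cfnet:::bce_loss(fm$scores, y)) / (2 * eps)
  }
  expect_equal(bwd$dX, gX_num, tolerance = 1e-4)
})

test_that("co-training balances datasets and accepts mixed fraction counts", {
  # two synthetic "species" with different fraction counts, both padded
  ds1 <- simulate_dataset(tiny_sim(seed = 21))
  ds2 <- simulate_dataset(sim_config(
    n_proteins = 50L, n_fractions = 55L, n_complexes = 6L,
    complex_size_range = c(3L, 5L), peak_sd = 1.5, apex_jitter = 0.3,
    noise_sd = 0, missing_rate = 0, seq_len_range = c(60L, 120L),
    motif_share = 0.9, seed = 22))
  prep <- function(ds, k) {
    E <- pad_profiles(preprocess_elution(ds$elution), 200)
    S <- fcgr_encode_all(ds$sequences[E$protein_ids])
    L <- make_folds(suppressMessages(derive_pair_labels(ds$catalog, E)),
                    k = k, seed = 1)
    list(elution = E, fcgr = S, labels = L)
  }
  d1 <- prep(ds1, 3); d2 <- prep(ds2, 3)
  n1 <- sum(!is.na(d1$labels$fold)); n2 <- sum(!is.na(d2$labels$fold))
  expect_false(n1 == n2)  # genuinely different training sizes
  cfg <- tiny_model_cfg(epochs = 4L)
  m <- co_train(list(d1, d2), cfg)
  expect_null(m$params$C)
  # forward pass accepts both padded datasets
  X1 <- assemble_input(d1$elution, d1$fcgr)
  X2 <- assemble_input(d2$elution, d2$fcgr)
  s1 <- predict_pairs(m, cbind(1:3, 4:6), X = X1)
  s2 <- predict_pairs(m, cbind(1:3, 4:6), X = X2)
  expect_true(all(s1 > 0 & s1 < 1) && all(s2 > 0 & s2 < 1))
  # single dataset co-training equals embedding-free training
  m_single <- co_train(list(d1), cfg)
  m_plain <- train_model(d1$elution, d1$fcgr, d1$labels, cfg,
                         use_embedding = FALSE)
  expect_equal(m_single$params$W1, m_plain$params$W1, tolerance = 1e-12)
})

test_that("divergent training raises an informative error", {
  p <- tiny_prepared()
  cfg <- tiny_model_cfg(epochs = 3L, learning_rate = NaN)
  expect_error(train_model(p$E, p$S, p$labels, cfg), "epoch")
})
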