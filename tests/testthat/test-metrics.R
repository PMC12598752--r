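# Classification metrics, set scores, composite score, colocalization,
# representation separation and the bootstrap null.

test_that("classification metrics match direct substitution", {
  # construct scores realizing TP=3, FP=1, FN=2, TN=4 at threshold 0.5
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.6, 0.1, 0.2, 0.3, 0.4)
  m <- classification_metrics(labels, scores)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-9)
  # perfect separation
  mp <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unlist(mp), c(sensitivity = 1, specificity = 1,
                             mcc = 1, auc = 1))
  # a score of exactly 0.5 is classified negative
  mt <- suppressWarnings(classification_metrics(c(1, 0), c(0.5, 0.2)))
  expect_equal(mt$sensitivity, 0)
  # degenerate MCC returns 0 with warning
  expect_warning(mz <- classification_metrics(c(1, 0), c(0.9, 0.8)),
                 "MCC")
  expect_equal(mz$mcc, 0)
  # single-class labels: AUC undefined
  expect_error(classification_metrics(c(1, 1), c(0.2, 0.9)), "single class")
})

test_that("rank AUC equals the independent ROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:5) {
    n <- 200
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- runif(n) * 0.5 + labels * runif(n) * 0.5
    scores[sample(n, 20)] <- 0.5  # ties
    m <- classification_metrics(labels, scores)
    oracle <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(m$auc, oracle, tolerance = 1e-12)
  }
})

test_that("overlap and jaccard follow their formulas", {
  X <- c("a", "b", "c", "d"); Y <- c("a", "b", "e", "f")
  expect_equal(overlap_score(X, Y), 4 / 16)
  expect_equal(jaccard(X, Y), 2 / 6)
  expect_equal(overlap_score(X, X), 1)
  expect_equal(jaccard(X, X), 1)
  expect_error(overlap_score(character(0), X), "non-empty")
  # published worked examples: coverage/purity fractions imply the Jaccard
  # |X|=16 complex, |Y|=14 cluster, overlap 10: 62.50% / 71.43% -> 0.500
  cx <- sprintf("p%02d", 1:16)
  cl <- c(cx[1:10], sprintf("q%02d", 1:4))
  expect_equal(round(100 * 10 / 16, 2), 62.50)
  expect_equal(round(100 * 10 / 14, 2), 71.43)
  expect_equal(jaccard(cx, cl), 0.5)
  # full coverage, 80% purity -> 0.800
  cx2 <- sprintf("r%02d", 1:20)
  cl2 <- c(cx2, sprintf("s%02d", 1:5))
  expect_equal(jaccard(cx2, cl2), 0.8)
})

test_that("composite score is exact on perfect recovery and boundaries", {
  ref <- list(C1 = c("a", "b", "c"), C2 = c("d", "e", "f", "g"))
  perfect <- composite_score(ref, ref)
  expect_equal(perfect$composite, 3)
  expect_equal(perfect$mmr, 1)
  expect_equal(perfect$accuracy, 1)
  # overlap exactly 0.25 does not count (strict >)
  res <- composite_score(list(c("a", "b", "e", "f")),
                         list(R = c("a", "b", "c", "d")))
  expect_equal(res$overlap_frac, 0)
})

test_that("composite MMR equals exhaustive matching on small instances", {
  set.seed(31)
  pool <- letters
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    ref <- lapply(seq_len(n), function(i) sample(pool, sample(3:6, 1)))
    names(ref) <- paste0("R", seq_len(n))
    cl <- lapply(seq_len(m), function(i) sample(pool, sample(3:6, 1)))
    O <- outer(seq_len(n), seq_len(m),
               Vectorize(function(i, j) overlap_score(ref[[i]], cl[[j]])))
    res <- composite_score(cl, ref)
    expect_equal(res$mmr, oracle_matching_weight(O) / n, tolerance = 1e-9)
  }
})

test_that("composite components stay in range and ignore input order", {
  set.seed(32)
  ref <- list(A = letters[1:5], B = letters[6:11], C = letters[12:14])
  cl <- list(letters[c(1:4, 12)], letters[c(6:10)], letters[c(13, 14, 15)])
  r1 <- composite_score(cl, ref)
  for (v in c("overlap_frac", "sn", "ppv", "accuracy", "mmr"))
    expect_true(r1[[v]] >= 0 && r1[[v]] <= 1)
  expect_true(r1$composite >= 0 && r1$composite <= 3)
  r2 <- composite_score(rev(cl), ref[c(2, 3, 1)])
  expect_equal(r1$composite, r2$composite)
})

test_that("colocalization counts only annotated members", {
  loc <- c(p1 = "nucleus", p2 = "nucleus", p3 = "cytosol",
           p4 = "mitochondrion")
  expect_equal(colocalization_score(c("p1", "p2"), loc), 1)
  expect_equal(colocalization_score(c("p1", "p2", "p3", "p4"), loc), 0.5)
  # member without assignment excluded from the denominator
  expect_equal(colocalization_score(c("p1", "p2", "px"), loc), 1)
  expect_message(v <- colocalization_score(c("px", "py"), loc), "no cluster")
  expect_true(is.na(v))
})

test_that("representation separation detects planted block structure", {
  cat <- complex_catalog(list(C1 = c("a", "b", "c"), C2 = c("d", "e", "f")),
                         min_size = 3)
  R <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(1, 0, 0),
             d = c(0, 1, 0), e = c(0, 1, 0), f = c(0, 1, 0))
  res <- representation_separation(R, cat)
  expect_true(all(res$intra_distances < 1e-12))
  expect_lt(res$test_p, 0.05)
  # single complex: error
  expect_error(representation_separation(
    R, complex_catalog(list(C1 = c("a", "b", "c")), min_size = 3)),
    "two complexes")
  # degenerate all-zero rows: error
  R0 <- R; R0["a", ] <- 0
  expect_error(representation_separation(R0, cat), "zero")
})

test_that("shuffled representations give a calibrated rejection rate", {
  # under the null (labels shuffled), the Kruskal-Wallis p-value should be
  # roughly uniform: reject rate near alpha over repeated seeds
  cat <- complex_catalog(list(C1 = sprintf("p%02d", 1:5),
                              C2 = sprintf("p%02d", 6:10),
                              C3 = sprintf("p%02d", 11:15)), min_size = 3)
  n_rep <- 300
  rejects <- 0
  set.seed(77)
  for (r in seq_len(n_rep)) {
    R <- matrix(rnorm(15 * 6), 15)  # no association with complexes
    rownames(R) <- sprintf("p%02d", 1:15)
    p <- representation_separation(R, cat)$test_p
    rejects <- rejects + (p < 0.05)
  }
  rate <- rejects / n_rep
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.11)
})

test_that("bootstrap null is calibrated and detects shifts", {
  set.seed(41)
  pool <- lapply(3:7, function(s) rnorm(20, mean = 0.5, sd = 0.1))
  names(pool) <- as.character(3:7)
  sizes <- sample(3:7, 12, replace = TRUE)
  # shifted observations: strongly significant
  obs_hi <- vapply(as.character(sizes),
                   function(k) sample(pool[[k]], 1), numeric(1)) + 0.5
  res <- bootstrap_null(obs_hi, sizes, pool, n_boot = 2000, seed = 1)
  expect_lt(res$p_value, 0.01)
  # replicate count and determinism
  r1 <- bootstrap_null(obs_hi, sizes, pool, n_boot = 500, seed = 9)
  r2 <- bootstrap_null(obs_hi, sizes, pool, n_boot = 500, seed = 9)
  expect_identical(r1, r2)
  # missing size in pool
  expect_error(bootstrap_null(c(0.5), c(9), pool, n_boot = 10, seed = 1),
               "lacks sizes")
})

test_that("bootstrap null rejects at roughly the nominal rate under H0", {
  set.seed(42)
  pool <- lapply(3:7, function(s) rnorm(20, mean = 0.6, sd = 0.15))
  names(pool) <- as.character(3:7)
  n_rep <- 500
  rejects <- 0
  for (r in seq_len(n_rep)) {
    sizes <- sample(3:7, 15, replace = TRUE)
    obs <- vapply(as.character(sizes),
                  function(k) sample(pool[[k]], 1), numeric(1))
    res <- bootstrap_null(obs, sizes, pool, n_boot = 400, seed = 1000 + r)
    rejects <- rejects + (res$p_value < 0.05)
  }
  rate <- rejects / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})
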