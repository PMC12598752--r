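# Classification metrics, cluster-vs-reference composite score,
# colocalization, representation separation and the size-matched bootstrap
# null.

#' Binary classification metrics at a hard threshold
#'
#' Scores strictly above the threshold are called positive; scores less
#' than or equal to it are called negative. MCC follows the standard
#' product formula and returns 0 (with a warning) when any denominator
#' factor is zero. AUC is computed by the rank (Mann-Whitney) formulation
#' with midranks for ties.
#'
#' @param labels binary vector (0/1 or logical); 1 = interacting pair.
#' @param scores numeric scores in `[0,1]`.
#' @param threshold hard decision threshold (default 0.5).
#' @return List with `sensitivity`, `specificity`, `mcc`, `auc`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  if (length(unique(labels)) < 2)
    stop("AUC undefined: labels contain a single class")
  pred <- as.integer(scores > threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) {
    warning("MCC denominator is zero; returning 0")
    0
  } else (TP * TN - FP * FN) / sqrt(denom)
  list(sensitivity = sens, specificity = spec, mcc = mcc,
       auc = auc_rank(labels, scores))
}

# Mann-Whitney AUC with midranks for ties.
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Overlap score between two protein sets
#'
#' `|X intersect Y|^2 / (|X| * |Y|)`, the squared-overlap criterion used
#' both for matching predicted clusters to reference complexes and for
#' merging redundant clusters.
#'
#' @param x,y non-empty character vectors (sets).
#' @return Score in `[0,1]`.
#' @export
overlap_score <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 || length(y) == 0) stop("sets must be non-empty")
  length(intersect(x, y))^2 / (length(x) * length(y))
}

#' Jaccard similarity between two protein sets
#'
#' @inheritParams overlap_score
#' @return `|X intersect Y| / |X union Y|` in `[0,1]`.
#' @export
jaccard <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 || length(y) == 0) stop("sets must be non-empty")
  length(intersect(x, y)) / length(union(x, y))
}

# Maximum-weight one-to-one assignment on a non-negative weight matrix
# (rows to columns, matrix padded square internally). Hungarian algorithm,
# shortest augmenting path formulation.
max_weight_matching <- function(W) {
  stopifnot(all(W >= 0))
  n <- max(dim(W))
  A <- matrix(0, n, n)
  A[seq_len(nrow(W)), seq_len(ncol(W))] <- W
  cost <- max(A) - A  # minimize cost <=> maximize weight
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L  # column index offset by 0; column 1 is the virtual column
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)  # row -> column
  for (j in 2:(n + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  rows <- seq_len(nrow(W))
  match_col <- assign[rows]
  match_col[match_col > ncol(W)] <- 0L
  weight <- sum(W[cbind(rows[match_col > 0], match_col[match_col > 0])])
  list(match = match_col, weight = weight)
}

#' Composite structural score of predicted clusters against a reference
#'
#' Combines three components: the fraction of predicted clusters whose
#' overlap score with some reference complex is strictly larger than 0.25;
#' the geometric mean (accuracy) of complex-wise sensitivity
#' `Sn = sum_i max_j t_ij / sum_i |b_i|` and cluster-wise positive
#' predictive value `PPV = sum_j max_i T_ij / sum_j sum_i T_ij`, where
#' `t_ij = T_ij` is the member overlap count between complex i and cluster
#' j and `|b_i|` the complex size; and the maximum matching ratio (MMR):
#' the total overlap score of an optimal one-to-one matching between
#' reference complexes and clusters divided by the number of reference
#' complexes.
#'
#' @param clusters a `cluster_set` or list of character vectors.
#' @param reference a `complex_catalog` or list of character vectors.
#' @return List with `overlap_frac`, `sn`, `ppv`, `accuracy`, `mmr` and
#'   `composite` (= overlap_frac + accuracy + mmr, in `[0,3]`).
#' @export
composite_score <- function(clusters, reference) {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  ref <- if (inherits(reference, "complex_catalog")) reference$complexes
         else reference
  if (length(cl) == 0 || length(ref) == 0)
    stop("clusters and reference must be non-empty")
  n <- length(ref); m <- length(cl)
  Tij <- matrix(0L, n, m)
  O <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ov <- length(intersect(ref[[i]], cl[[j]]))
    Tij[i, j] <- ov
    O[i, j] <- ov^2 / (length(unique(ref[[i]])) * length(unique(cl[[j]])))
  }
  overlap_frac <- mean(apply(O, 2, max) > 0.25)
  sn <- sum(apply(Tij, 1, max)) / sum(lengths(lapply(ref, unique)))
  tot <- sum(Tij)
  ppv <- if (tot == 0) 0 else sum(apply(Tij, 2, max)) / tot
  accuracy <- sqrt(sn * ppv)
  mmr <- max_weight_matching(O)$weight / n
  list(overlap_frac = overlap_frac, sn = sn, ppv = ppv,
       accuracy = accuracy, mmr = mmr,
       composite = overlap_frac + accuracy + mmr)
}

#' Colocalization score of a cluster
#'
#' The maximum fraction of cluster members sharing one subcellular
#' compartment, among members with a localization assignment.
#'
#' @param cluster character vector of protein ids.
#' @param localizations named character vector protein -> compartment.
#' @return Score in `(0,1]`, or `NA` when no member has an assignment.
#' @export
colocalization_score <- function(cluster, localizations) {
  loc <- localizations[intersect(cluster, names(localizations))]
  loc <- loc[!is.na(loc)]
  if (length(loc) == 0) {
    message("no cluster member has a localization assignment")
    return(NA_real_)
  }
  max(table(loc)) / length(loc)
}

#' Cosine separation of protein representations by complex membership
#'
#' Computes cosine distances between all intra-complex and all
#' inter-complex pairs of representation rows (restricted to complex
#' members present in the matrix) and compares the two distance groups
#' with a Kruskal-Wallis rank test.
#'
#' @param representations numeric matrix with protein ids as row names.
#' @param catalog a `complex_catalog`.
#' @return List with `intra_distances`, `inter_distances` and `test_p`.
#' @export
representation_separation <- function(representations, catalog) {
  stopifnot(is.matrix(representations), !is.null(rownames(representations)))
  members <- lapply(catalog$complexes, intersect,
                    y = rownames(representations))
  members <- members[lengths(members) >= 2]
  if (length(members) < 2)
    stop("need at least two complexes with two or more members present")
  prots <- unique(unlist(members))
  M <- representations[prots, , drop = FALSE]
  D <- cosine_distance(M)
  idx <- stats::setNames(seq_along(prots), prots)
  same <- matrix(FALSE, length(prots), length(prots))
  for (m in members) {
    ii <- idx[m]
    same[ii, ii] <- TRUE
  }
  ut <- upper.tri(D)
  intra <- D[ut & same]
  inter <- D[ut & !same]
  kw <- stats::kruskal.test(list(intra, inter))
  list(intra_distances = intra, inter_distances = inter,
       test_p = kw$p.value)
}

#' Size-matched bootstrap null for per-cluster scores
#'
#' Builds a null distribution for the mean per-cluster score by drawing,
#' in each of `n_boot` replicates, one background score of matching size
#' for every observed cluster and recording the replicate mean. A
#' one-sample t-test then compares the observed scores against the mean of
#' the null distribution.
#'
#' @param observed_scores numeric vector of per-cluster scores.
#' @param observed_sizes integer vector of the corresponding cluster sizes.
#' @param pool named list: size (as character) -> numeric vector of
#'   background scores for random clusters of that size.
#' @param n_boot number of bootstrap replicates (default 100000).
#' @param seed integer seed.
#' @return List with `null_mean`, `null_sd`, `p_value` and `statistic`.
#' @export
bootstrap_null <- function(observed_scores, observed_sizes, pool,
                           n_boot = 100000L, seed = 1L) {
  stopifnot(length(observed_scores) == length(observed_sizes))
  n_boot <- assert_count(n_boot, "n_boot")
  keys <- as.character(observed_sizes)
  missing <- setdiff(unique(keys), names(pool))
  if (length(missing))
    stop("background pool lacks sizes: ", paste(missing, collapse = ", "))
  set.seed(seed)
  draws <- vapply(keys, function(k)
    sample(pool[[k]], n_boot, replace = TRUE), numeric(n_boot))
  null_means <- rowMeans(draws)
  null_mean <- mean(null_means)
  tt <- stats::t.test(observed_scores, mu = null_mean)
  list(null_mean = null_mean, null_sd = stats::sd(null_means),
       p_value = tt$p.value, statistic = unname(tt$statistic))
}
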