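# From predicted pair scores to protein complexes:
# adjacency -> Markov clustering -> topological overlap -> weighted hybrid
# importance matrices -> cosine/Ward clustering with an adaptive dendrogram
# cut -> size capping -> overlap merging.

#' Build a weighted adjacency matrix from scored pairs
#'
#' Keeps edges whose score is strictly above `score_floor`, symmetrizes,
#' and removes proteins left without any neighbor. Duplicate `(a,b)`/
#' `(b,a)` entries collapse to their maximum with a warning.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`, `score`
#'   (scores in `[0,1]`).
#' @param score_floor minimum retained score (default 0.5, the hard
#'   decision threshold of the classifier).
#' @return An object of class `adjacency`: list with `node_ids` and the
#'   symmetric weight matrix `W` (zero diagonal).
#' @export
build_adjacency <- function(edges, score_floor = 0.5) {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1))
    stop("scores must lie in [0,1]")
  cp <- canonical_pairs(edges$protein_a, edges$protein_b)
  if (nrow(cp) < nrow(unique(edges[, c("protein_a", "protein_b")])))
    warning("duplicate or reversed pairs collapsed (maximum score kept)")
  key <- paste(pmin(edges$protein_a, edges$protein_b),
               pmax(edges$protein_a, edges$protein_b))
  score <- tapply(edges$score, key, max)
  keep <- score > score_floor
  if (!any(keep)) stop("no edges above the score floor; empty graph")
  ab <- do.call(rbind, strsplit(names(score)[keep], " ", fixed = TRUE))
  ids <- sort(unique(c(ab[, 1], ab[, 2])))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  W[cbind(ab[, 1], ab[, 2])] <- score[keep]
  W[cbind(ab[, 2], ab[, 1])] <- score[keep]
  structure(list(node_ids = ids, W = W), class = "adjacency")
}

#' Markov clustering transform of an adjacency matrix
#'
#' Adds self-loops once, then alternates expansion (matrix power),
#' inflation (elementwise power) and column renormalization for exactly
#' `iterations` rounds, with no convergence test. The result is the
#' smoothed, column-stochastic flow matrix used downstream as one of the
#' two importance matrices.
#'
#' @param A an `adjacency`.
#' @param expansion matrix power per iteration (default 2).
#' @param inflation elementwise power per iteration (default 2).
#' @param iterations number of iterations (default 3).
#' @return Column-stochastic numeric matrix with the adjacency's dimnames.
#' @export
mcl <- function(A, expansion = 2L, inflation = 2, iterations = 3L) {
  stopifnot(inherits(A, "adjacency"))
  expansion <- assert_count(expansion, "expansion")
  iterations <- assert_count(iterations, "iterations")
  M <- A$W
  diag(M) <- 1  # self-loops, added once before iterating
  col_norm <- function(X) {
    cs <- colSums(X)
    if (any(cs == 0)) stop("zero column encountered during normalization")
    sweep(X, 2, cs, "/")
  }
  for (it in seq_len(iterations)) {
    M <- col_norm(M)
    if (expansion > 1) {
      P <- M
      for (e in seq_len(expansion - 1)) P <- P %*% M
      M <- P
    }
    M <- M^inflation
    M <- col_norm(M)
  }
  M
}

#' Topological overlap matrix of a weighted graph
#'
#' Soft-thresholds the adjacency by an elementwise power, then augments
#' each edge weight with shared-neighbor structure:
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and connectivity `k_i = sum_u a_iu`.
#' The diagonal is set to 1 (full self-overlap).
#'
#' @param A an `adjacency`.
#' @param power elementwise soft-thresholding power (default 2.5).
#' @return Numeric matrix in `[0,1]` with unit diagonal.
#' @export
tom <- function(A, power = 2.5) {
  stopifnot(inherits(A, "adjacency"))
  a <- A$W^power
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  mink <- outer(k, k, pmin)
  W <- (l + a) / (mink + 1 - a)
  diag(W) <- 1
  W
}

# Adaptive dendrogram cut. Ward trees are cut at candidate cluster counts
# 2..kmax (kmax limited by deep_split) and each partition is scored by its
# mean silhouette width. The cut keeps the finest partition whose
# silhouette stays within a deep_split-dependent fraction of the maximum:
# deep_split therefore trades compactness against resolution, with level 0
# demanding the silhouette optimum and higher levels accepting finer
# partitions. Clusters below min_cluster are then merged into their
# nearest cluster by average distance. Deterministic throughout.
adaptive_cut <- function(D, min_cluster = 3L, deep_split = 3L) {
  n <- nrow(D)
  if (n < min_cluster) stop(sprintf("fewer than %d proteins", min_cluster))
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  divisor <- c(12, 8, 6, 4, 3)[deep_split + 1L]
  frac <- c(1, 0.95, 0.9, 0.8, 0.7)[deep_split + 1L]
  kmax <- max(2L, min(n - 1L, floor(n / divisor)))
  sils <- vapply(2:kmax, function(k)
    mean_silhouette(D, stats::cutree(hc, k)), numeric(1))
  ok <- sils >= frac * max(sils) - 1e-12
  best_k <- max((2:kmax)[ok])
  cl <- stats::cutree(hc, best_k)
  merge_small_clusters(D, cl, min_cluster)
}

# Mean silhouette width of a partition given a distance matrix.
mean_silhouette <- function(D, cl) {
  n <- length(cl)
  ks <- sort(unique(cl))
  ind <- vapply(ks, function(k) as.numeric(cl == k), numeric(n))
  sizes <- colSums(ind)
  sums <- D %*% ind                       # n x K: total distance to cluster k
  own <- ks[match(cl, ks)]
  s <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- match(cl[i], ks)
    if (sizes[k_i] <= 1) { s[i] <- 0; next }
    a <- sums[i, k_i] / (sizes[k_i] - 1)
    b <- min(sums[i, -k_i] / sizes[-k_i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Reassign members of clusters below min_cluster to the nearest remaining
# cluster (smallest average distance), iterating until all clusters comply.
merge_small_clusters <- function(D, cl, min_cluster) {
  repeat {
    tab <- table(cl)
    small <- names(tab)[tab < min_cluster]
    if (length(small) == 0 || length(tab) == 1) break
    victim <- small[which.min(tab[small])]
    idx <- which(cl == as.integer(victim))
    others <- setdiff(unique(cl), as.integer(victim))
    avg <- vapply(others, function(k) {
      mean(D[idx, cl == k, drop = FALSE])
    }, numeric(1))
    cl[idx] <- others[which.min(avg)]
  }
  cl
}

new_cluster_set <- function(clusters, provenance) {
  structure(list(clusters = clusters, provenance = provenance),
            class = "cluster_set")
}

#' Cluster proteins from weighted combinations of two importance matrices
#'
#' For each weighting `(alpha, beta)` the combined importance matrix
#' `M = alpha * A_ + beta * I_` is formed, pairwise cosine distances
#' between its rows are computed, Ward hierarchical clustering is applied
#' and the dendrogram is cut adaptively (silhouette-guided cut with
#' resolution capped by `deep_split`; clusters below `min_cluster` merged
#' into their nearest cluster). The clusterings from all weightings are
#' unioned into one possibly-overlapping cluster set.
#'
#' @param A_ Markov-clustered flow matrix (from [mcl()]).
#' @param I_ topological overlap matrix (from [tom()]).
#' @param weightings list of `(alpha, beta)` pairs, each summing to 1
#'   (defaults `(0.3, 0.7)` and `(0.1, 0.9)`).
#' @param min_cluster minimum cluster size (default 3).
#' @param deep_split split aggressiveness 0-4 (default 3; use 1 or 2 for
#'   relatively small datasets).
#' @return A `cluster_set`; the combined matrices are attached as
#'   attribute `importance` for size enforcement.
#' @export
hybrid_clusters <- function(A_, I_,
                            weightings = list(c(0.3, 0.7), c(0.1, 0.9)),
                            min_cluster = 3L, deep_split = 3L) {
  stopifnot(identical(dim(A_), dim(I_)))
  min_cluster <- assert_count(min_cluster, "min_cluster")
  deep_split <- assert_count(deep_split, "deep_split", min = 0)
  for (w in weightings)
    if (abs(sum(w) - 1) > 1e-9)
      stop("each weighting must sum to 1")
  ids <- rownames(A_)
  clusters <- list(); provenance <- character(0); importance <- list()
  for (w in weightings) {
    tag <- sprintf("w%g_%g", w[1], w[2])
    M <- w[1] * A_ + w[2] * I_
    importance[[tag]] <- M
    D <- cosine_distance(M)
    cl <- adaptive_cut(D, min_cluster, deep_split)
    for (k in sort(unique(cl))) {
      members <- sort(ids[cl == k])
      if (length(members) >= min_cluster) {
        clusters[[length(clusters) + 1L]] <- members
        provenance <- c(provenance, tag)
      }
    }
  }
  out <- new_cluster_set(clusters, provenance)
  attr(out, "importance") <- importance
  out
}

#' Re-split clusters exceeding a size limit
#'
#' Any cluster with `limit` or more members is re-clustered on the
#' corresponding submatrix of its importance matrix (same cosine / Ward /
#' adaptive-cut procedure), recursively, until every cluster is below the
#' limit. Recursion past `max_depth` levels raises an error.
#'
#' @param C a `cluster_set` (with the `importance` attribute from
#'   [hybrid_clusters()], or pass `matrices` explicitly).
#' @param matrices named list of importance matrices by provenance tag.
#' @param limit exclusive maximum cluster size (default 100).
#' @inheritParams hybrid_clusters
#' @param max_depth recursion cap (default 10).
#' @return A `cluster_set` with all clusters smaller than `limit`.
#' @export
enforce_max_size <- function(C, matrices = attr(C, "importance"),
                             limit = 100L, min_cluster = 3L,
                             deep_split = 3L, max_depth = 10L) {
  stopifnot(inherits(C, "cluster_set"), !is.null(matrices))
  limit <- assert_count(limit, "limit")
  split_rec <- function(members, M, depth) {
    if (length(members) < limit)
      return(list(members))
    if (depth > max_depth)
      stop("unsplittable oversized cluster: recursion depth exceeded")
    sub <- M[members, members, drop = FALSE]
    D <- cosine_distance(sub)
    cl <- adaptive_cut(D, min_cluster, deep_split)
    if (length(unique(cl)) == 1)
      stop("unsplittable oversized cluster: cut produced a single cluster")
    out <- list()
    for (k in sort(unique(cl)))
      out <- c(out, split_rec(members[cl == k], M, depth + 1L))
    out
  }
  clusters <- list(); provenance <- character(0)
  for (i in seq_along(C$clusters)) {
    tag <- C$provenance[i]
    M <- matrices[[tag]] %||% matrices[[1]]
    parts <- split_rec(C$clusters[[i]], M, 1L)
    for (p in parts) {
      if (length(p) >= min_cluster) {
        clusters[[length(clusters) + 1L]] <- sort(p)
        provenance <- c(provenance, tag)
      }
    }
  }
  out <- new_cluster_set(clusters, provenance)
  attr(out, "importance") <- matrices
  out
}

#' Merge highly overlapping clusters
#'
#' Iteratively computes the merge score `|X intersect Y|^2 / (|X| * |Y|)`
#' for every cluster pair and merges the highest-scoring pair whose score
#' strictly exceeds the threshold (ties broken lexicographically on the
#' member lists), until no pair qualifies. Exact duplicates always merge.
#'
#' @param C a `cluster_set`.
#' @param threshold merge threshold (default 0.25; a score equal to the
#'   threshold does not merge).
#' @return A `cluster_set`.
#' @export
merge_overlapping <- function(C, threshold = 0.25) {
  stopifnot(inherits(C, "cluster_set"))
  clusters <- C$clusters
  provenance <- C$provenance
  repeat {
    n <- length(clusters)
    if (n < 2) break
    keys <- vapply(clusters, function(x) paste(x, collapse = ","),
                   character(1))
    best <- NULL; best_score <- threshold
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sc <- overlap_score(clusters[[i]], clusters[[j]])
      better <- sc > best_score + 1e-12 ||
        (!is.null(best) && abs(sc - best_score) <= 1e-12 &&
           paste(keys[i], keys[j]) < paste(keys[best[1]], keys[best[2]]))
      if (sc > threshold && (is.null(best) || better)) {
        best <- c(i, j); best_score <- sc
      }
    }
    if (is.null(best)) break
    merged <- sort(union(clusters[[best[1]]], clusters[[best[2]]]))
    tag <- paste(unique(provenance[best]), collapse = "+")
    clusters <- clusters[-best]
    provenance <- provenance[-best]
    clusters[[length(clusters) + 1L]] <- merged
    provenance <- c(provenance, tag)
  }
  new_cluster_set(clusters, provenance)
}

#' Full clustering stack from a scored edge list
#'
#' Convenience wrapper: adjacency, Markov clustering, topological overlap,
#' hybrid weighted clustering, size enforcement and overlap merging, with
#' the standard defaults.
#'
#' @inheritParams build_adjacency
#' @inheritParams hybrid_clusters
#' @inheritParams enforce_max_size
#' @inheritParams merge_overlapping
#' @param expansion,inflation,iterations Markov clustering parameters.
#' @param tom_power soft-thresholding power for the topological overlap.
#' @return A `cluster_set`.
#' @export
cluster_complexes <- function(edges, score_floor = 0.5,
                              expansion = 2L, inflation = 2,
                              iterations = 3L, tom_power = 2.5,
                              weightings = list(c(0.3, 0.7), c(0.1, 0.9)),
                              min_cluster = 3L, deep_split = 3L,
                              limit = 100L, threshold = 0.25) {
  A <- build_adjacency(edges, score_floor)
  A_ <- mcl(A, expansion, inflation, iterations)
  I_ <- tom(A, tom_power)
  C <- hybrid_clusters(A_, I_, weightings, min_cluster, deep_split)
  C <- enforce_max_size(C, limit = limit, min_cluster = min_cluster,
                        deep_split = deep_split)
  merge_overlapping(C, threshold)
}

#' Write clusters as long-form TSV
#'
#' One `(protein, cluster_id)` row per membership; overlapping clusters
#' produce repeated proteins.
#'
#' @param C a `cluster_set`.
#' @param path output file path.
#' @export
write_clusters_long <- function(C, path) {
  stopifnot(inherits(C, "cluster_set"))
  df <- do.call(rbind, lapply(seq_along(C$clusters), function(i)
    data.frame(protein = C$clusters[[i]],
               cluster_id = paste0("cluster", i))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, sizes %s\n", length(x$clusters),
              paste(range(lengths(x$clusters)), collapse = "-")))
  invisible(x)
}
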