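# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# chaos-game recursion, written directly from the update rule
oracle_cgr <- function(seq, scale) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  th <- 2 * pi * (seq_along(aas) - 1) / 20
  V <- cbind(cos(th), sin(th))
  p <- c(0, 0)
  out <- NULL
  for (r in strsplit(seq, "")[[1]]) {
    p <- p + scale * (V[match(r, aas), ] - p)
    out <- rbind(out, p)
  }
  unname(out)
}

# topological overlap by explicit triple loop
oracle_tom <- function(W, power = 2.5) {
  a <- W^power; diag(a) <- 0
  n <- nrow(W)
  out <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  diag(out) <- 1
  dimnames(out) <- dimnames(W)
  out
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(oracle_permutations(v[-i]), function(p) c(v[i], p))))
}

# maximum one-to-one matching weight by full enumeration (<= 5x5)
oracle_matching_weight <- function(O) {
  n <- nrow(O); m <- ncol(O); k <- min(n, m)
  best <- 0
  rs <- combn(seq_len(n), k); cs <- combn(seq_len(m), k)
  for (ri in seq_len(ncol(rs))) for (ci in seq_len(ncol(cs)))
    for (p in oracle_permutations(cs[, ci]))
      best <- max(best, sum(O[cbind(rs[, ri], p)]))
  best
}

# AUC as the probability a random positive outranks a random negative,
# computed pair by pair (ties count one half)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random symmetric weighted graph on n nodes
random_graph <- function(n, p_edge = 0.4) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- ifelse(runif(sum(ut)) < p_edge, runif(sum(ut)), 0)
  W <- W + t(W)
  ids <- sprintf("n%03d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  W
}
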