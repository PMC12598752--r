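# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize a set of protein pairs
#'
#' Orders each pair alphabetically (a < b) and drops self-pairs and
#' duplicates, so that pair labels and scores are symmetric by construction.
#'
#' @param a,b character vectors of equal length.
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @keywords internal
canonical_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- a != b
  df <- unique(data.frame(protein_a = a[keep], protein_b = b[keep],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

# Cosine distance between rows of a matrix. Rows with zero norm are rejected:
# the direction of a zero vector is undefined.
cosine_distance <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("cosine distance undefined for all-zero rows")
  S <- (M / nrm) %*% t(M / nrm)
  S[S > 1] <- 1; S[S < -1] <- -1
  D <- 1 - S
  diag(D) <- 0
  D
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0,1]", name))
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}
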