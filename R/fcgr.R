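# Chaos game representation (FCGR) of protein sequences.
#
# Each of the 20 canonical amino acids is mapped to a vertex on the unit
# circle; the chaos game trajectory contracts toward the vertex of each
# successive residue, and trajectory points are binned on a resolution x
# resolution grid over [-1,1]^2 to give a fixed-length frequency vector.

CANONICAL_AA <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")

# Vertex layout: alphabetical order, evenly spaced on the unit circle
# starting at angle 0, counterclockwise.
aa_vertices <- function() {
  theta <- 2 * pi * (seq_along(CANONICAL_AA) - 1) / length(CANONICAL_AA)
  V <- cbind(cos(theta), sin(theta))
  rownames(V) <- CANONICAL_AA
  V
}

clean_sequence <- function(sequence, id = NULL) {
  res <- strsplit(toupper(sequence), "")[[1]]
  res <- res[res %in% CANONICAL_AA]
  if (length(res) == 0)
    stop(sprintf("sequence%s is empty after removing non-canonical residues",
                 if (is.null(id)) "" else paste0(" '", id, "'")))
  res
}

#' Chaos game trajectory of a protein sequence
#'
#' Starting at the origin, each residue moves the current point a fraction
#' `scale` of the way toward that residue's vertex:
#' `p_k = p_{k-1} + scale * (V(res_k) - p_{k-1})`. With `scale < 1` every
#' point stays inside `[-1,1]^2`. Residues outside the 20-letter canonical
#' alphabet (X, U, B, Z, *) are dropped before the recursion.
#'
#' @param sequence amino-acid string.
#' @param scale contraction factor in (0,1); the default 0.863271 keeps the
#'   20 attractor regions from overlapping.
#' @param id optional identifier used in error messages.
#' @return A numeric matrix with one `(x, y)` row per retained residue.
#' @export
cgr_trajectory <- function(sequence, scale = 0.863271, id = NULL) {
  if (!is.numeric(scale) || scale <= 0 || scale >= 1)
    stop("`scale` must lie in (0,1)")
  res <- clean_sequence(sequence, id)
  V <- aa_vertices()
  idx <- match(res, CANONICAL_AA)
  pts <- matrix(0, length(res), 2)
  p <- c(0, 0)
  for (k in seq_along(idx)) {
    p <- p + scale * (V[idx[k], ] - p)
    pts[k, ] <- p
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Encode a protein sequence as a flattened FCGR vector
#'
#' Bins the chaos game trajectory on a `resolution x resolution` grid over
#' `[-1,1]^2` (half-open cells, the last cell on each axis closed), flattens
#' the count matrix row-major, and divides by the maximum count so all
#' values lie in `[0,1]`.
#'
#' @inheritParams cgr_trajectory
#' @param resolution grid side length; the default 16 yields length-256
#'   vectors.
#' @return Numeric vector of length `resolution^2` with values in `[0,1]`.
#' @export
fcgr_encode <- function(sequence, resolution = 16L, scale = 0.863271,
                        id = NULL) {
  resolution <- assert_count(resolution, "resolution")
  pts <- cgr_trajectory(sequence, scale, id)
  bx <- pmin(floor((pts[, 1] + 1) / 2 * resolution) + 1L, resolution)
  by <- pmin(floor((pts[, 2] + 1) / 2 * resolution) + 1L, resolution)
  flat <- (by - 1L) * resolution + bx  # row-major: y selects the row
  tab <- tabulate(flat, nbins = resolution^2)
  tab / max(tab)
}

#' Encode many sequences into an FCGR matrix
#'
#' @param sequences named character vector of amino-acid sequences.
#' @inheritParams fcgr_encode
#' @return An object of class `fcgr_matrix` with fields `protein_ids`,
#'   `vectors` (N x resolution^2), `resolution` and `scale`.
#' @export
fcgr_encode_all <- function(sequences, resolution = 16L, scale = 0.863271) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("`sequences` must be named with unique protein ids")
  resolution <- assert_count(resolution, "resolution")
  vecs <- t(vapply(seq_along(sequences), function(i) {
    fcgr_encode(sequences[[i]], resolution, scale, id = names(sequences)[i])
  }, numeric(resolution^2)))
  rownames(vecs) <- names(sequences)
  structure(list(protein_ids = names(sequences), vectors = vecs,
                 resolution = resolution, scale = scale),
            class = "fcgr_matrix")
}

#' Read protein sequences from FASTA
#'
#' Identifiers are stripped of database prefixes (`sp|ACC|NAME` becomes
#' `ACC`) and of anything after the first whitespace, so they can be
#' matched against elution-matrix row ids.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  db <- grepl("^[a-z]{2}\\|[^|]+\\|", ids)
  ids[db] <- sub("^[a-z]{2}\\|([^|]+)\\|.*$", "\\1", ids[db])
  seqs <- as.character(aa)
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop("duplicate sequence ids after prefix stripping: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs
}

#' Write an FCGR matrix to TSV
#'
#' @param S an `fcgr_matrix`.
#' @param path output file path.
#' @export
write_fcgr <- function(S, path) {
  stopifnot(inherits(S, "fcgr_matrix"))
  df <- data.frame(protein = S$protein_ids, S$vectors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.fcgr_matrix <- function(x, ...) {
  cat(sprintf("fcgr_matrix: %d proteins, resolution %d (length %d), scale %g\n",
              nrow(x$vectors), x$resolution, x$resolution^2, x$scale))
  invisible(x)
}
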