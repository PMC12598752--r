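# CF-MS elution matrices: loading, cleaning, normalization, padding.

new_elution_matrix <- function(values, protein_ids,
                               normalized = FALSE, padded_to = NULL,
                               original_fractions = ncol(values)) {
  stopifnot(is.matrix(values), nrow(values) == length(protein_ids))
  rownames(values) <- protein_ids
  structure(list(protein_ids = protein_ids,
                 values = values,
                 original_fractions = as.integer(original_fractions),
                 normalized = isTRUE(normalized),
                 padded_to = padded_to),
            class = "elution_matrix")
}

#' Construct an elution matrix from intensities
#'
#' An elution matrix holds one co-fractionation mass spectrometry (CF-MS)
#' profile per protein: quantified intensities across chromatographic
#' fractions. Missing quantifications are represented as `NA` until
#' [preprocess_elution()] imputes them.
#'
#' @param values numeric matrix, proteins in rows, fractions in columns.
#'   `NA` entries mark missing quantifications.
#' @param protein_ids character vector of unique protein identifiers, one
#'   per row.
#' @return An object of class `elution_matrix`.
#' @export
elution_matrix <- function(values, protein_ids = rownames(values)) {
  if (is.null(protein_ids)) stop("protein ids are required")
  protein_ids <- as.character(protein_ids)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein ids: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  new_elution_matrix(values, protein_ids)
}

#' Load an elution matrix from a delimited file
#'
#' Expects one row per protein: the first column is the protein identifier,
#' the remaining columns are fraction intensities. Blank cells and `NA` are
#' parsed as missing. The delimiter is chosen from the file extension
#' (`.csv` uses a comma, anything else a tab).
#'
#' @param path path to a TSV/CSV file with a header row.
#' @return An `elution_matrix` with missing cells kept as `NA`.
#' @export
load_elution <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expected a protein-id column plus fraction columns")
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[, j])
    empty <- cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(num)
    if (any(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   which(bad)[1], colnames(raw)[j]))
    vals[, j] <- num
  }
  elution_matrix(vals, ids)
}

#' Impute, filter and row-normalize an elution matrix
#'
#' Missing intensities are replaced with zero; proteins whose profile is all
#' zero after imputation are removed (their ids are reported in a message);
#' every surviving profile is divided by its row sum so it sums to one.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param E an `elution_matrix`.
#' @return A normalized `elution_matrix` with no missing entries.
#' @export
preprocess_elution <- function(E) {
  stopifnot(inherits(E, "elution_matrix"))
  if (!is.null(E$padded_to))
    stop("preprocess must precede padding")
  V <- E$values
  V[is.na(V)] <- 0
  keep <- rowSums(V) > 0
  if (!all(keep))
    message("removed all-zero profiles: ",
            paste(E$protein_ids[!keep], collapse = ", "))
  V <- V[keep, , drop = FALSE]
  if (nrow(V) == 0) stop("no profiles remain after filtering")
  V <- V / rowSums(V)
  new_elution_matrix(V, E$protein_ids[keep], normalized = TRUE,
                     original_fractions = E$original_fractions)
}

#' Zero-pad elution profiles to a fixed length
#'
#' Appends zero columns so every profile has `target_len` fractions,
#' standardizing input dimensions across experiments with different
#' fraction counts. Padding is applied only at the end of each profile, so
#' the original coelution signal is untouched; profiles longer than
#' `target_len` are an error (never truncated). Padding requires a
#' normalized matrix so the appended zeros cannot dilute row sums.
#'
#' @param E a normalized `elution_matrix`.
#' @param target_len fixed output length in fractions (default 200).
#' @return An `elution_matrix` with `target_len` columns.
#' @export
pad_profiles <- function(E, target_len = 200L) {
  stopifnot(inherits(E, "elution_matrix"))
  target_len <- assert_count(target_len, "target_len")
  if (!E$normalized) stop("pad_profiles requires a normalized matrix")
  m <- ncol(E$values)
  if (E$original_fractions > target_len)
    stop(sprintf("profiles have %d fractions, more than target_len = %d",
                 E$original_fractions, target_len))
  if (m == target_len) {
    E$padded_to <- target_len
    return(E)
  }
  pad <- matrix(0, nrow(E$values), target_len - m)
  V <- cbind(E$values, pad)
  base_names <- colnames(E$values) %||% paste0("F", seq_len(m))
  colnames(V) <- c(base_names, paste0("pad", seq_len(target_len - m)))
  new_elution_matrix(V, E$protein_ids, normalized = TRUE,
                     padded_to = target_len,
                     original_fractions = E$original_fractions)
}

#' Write an elution matrix to TSV
#'
#' @param E an `elution_matrix`.
#' @param path output file path.
#' @export
write_elution <- function(E, path) {
  stopifnot(inherits(E, "elution_matrix"))
  df <- data.frame(protein = E$protein_ids, E$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.elution_matrix <- function(x, ...) {
  cat(sprintf(
    "elution_matrix: %d proteins x %d fractions (%d original%s%s)\n",
    nrow(x$values), ncol(x$values), x$original_fractions,
    if (x$normalized) ", normalized" else "",
    if (!is.null(x$padded_to)) sprintf(", padded to %d", x$padded_to) else ""))
  invisible(x)
}
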