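# Reference complex catalogs and positive/negative/experimental pair labels.

new_complex_catalog <- function(complexes) {
  structure(list(complexes = complexes), class = "complex_catalog")
}

#' Construct a complex catalog
#'
#' @param complexes named list: complex id -> character vector of member
#'   protein ids. Duplicate members within a complex are removed with a
#'   warning.
#' @param min_size complexes with fewer members are dropped (default 3,
#'   matching the usual curation rule for reference complex sets).
#' @return An object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes, min_size = 3L) {
  min_size <- assert_count(min_size, "min_size")
  if (is.null(names(complexes)) || anyDuplicated(names(complexes)))
    stop("`complexes` must be a uniquely named list")
  complexes <- lapply(complexes, function(m) {
    m <- as.character(m)
    if (anyDuplicated(m)) {
      warning("duplicate members within a complex were removed")
      m <- unique(m)
    }
    m
  })
  sizes <- lengths(complexes)
  dropped <- sum(sizes < min_size)
  if (dropped > 0)
    message(sprintf("dropped %d complex(es) with fewer than %d members",
                    dropped, min_size))
  kept <- complexes[sizes >= min_size]
  if (length(kept) == 0) stop("no complexes remain after size filtering")
  new_complex_catalog(kept)
}

#' Load reference complexes from a GMT-like file
#'
#' Each line is `complex_id<TAB>member<TAB>member...`.
#'
#' @param path file path.
#' @inheritParams complex_catalog
#' @return A `complex_catalog`.
#' @export
load_complexes <- function(path, min_size = 3L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty complex file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1)
  members <- lapply(fields, function(f) f[-1][nzchar(f[-1])])
  names(members) <- ids
  complex_catalog(members, min_size)
}

#' Write a complex catalog as GMT-like TSV
#'
#' @param catalog a `complex_catalog` or `cluster_set`.
#' @param path output file path.
#' @export
write_complexes <- function(catalog, path) {
  cl <- if (inherits(catalog, "complex_catalog")) catalog$complexes
        else if (inherits(catalog, "cluster_set")) {
          stats::setNames(catalog$clusters,
                          paste0("cluster", seq_along(catalog$clusters)))
        } else stop("unsupported object")
  writeLines(vapply(names(cl), function(id)
    paste(c(id, cl[[id]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Restrict a catalog to proteins present in an elution matrix
#'
#' @param catalog a `complex_catalog`.
#' @param protein_ids character vector of observed proteins.
#' @param min_size minimum size kept after intersection.
#' @return A `complex_catalog`.
#' @export
restrict_catalog <- function(catalog, protein_ids, min_size = 3L) {
  stopifnot(inherits(catalog, "complex_catalog"))
  kept <- lapply(catalog$complexes, intersect, y = protein_ids)
  kept <- kept[lengths(kept) >= min_size]
  if (length(kept) == 0) stop("no complexes overlap the observed proteins")
  new_complex_catalog(kept)
}

#' Label protein pairs as positive, negative or experimental
#'
#' Pairs whose two proteins share a reference complex are positive; pairs
#' whose proteins are both complex members but share no complex are
#' negative; every other observed pair is experimental (unlabeled, scored
#' at prediction time). A positive pair is reclassified to negative when it
#' lacks any coeluting characteristic: the maximum over fractions of the
#' product of the two normalized profiles must exceed 0.01, evaluated on
#' the un-padded fraction range.
#'
#' @param catalog a `complex_catalog`.
#' @param E a normalized `elution_matrix` (padded or not).
#' @param include_experimental if `FALSE`, only labeled pairs are returned
#'   (useful when the all-pairs experimental set would be very large).
#' @param coelution_min product threshold for the coelution check
#'   (default 0.01).
#' @return An object of class `pair_label_set`: a data.frame with columns
#'   `protein_a`, `protein_b` (canonical order a < b), `label` in
#'   `positive`/`negative`/`experimental`, and `fold` (`NA` until
#'   [make_folds()] assigns folds).
#' @export
derive_pair_labels <- function(catalog, E, include_experimental = TRUE,
                               coelution_min = 0.01) {
  stopifnot(inherits(catalog, "complex_catalog"), inherits(E, "elution_matrix"))
  if (!E$normalized) stop("derive_pair_labels requires a normalized matrix")
  ids <- E$protein_ids
  members <- lapply(catalog$complexes, intersect, y = ids)
  member_ids <- sort(unique(unlist(members)))

  pos <- do.call(rbind, lapply(members, function(m) {
    if (length(m) < 2) return(NULL)
    cmb <- utils::combn(sort(m), 2)
    data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  pos <- if (is.null(pos)) data.frame(protein_a = character(),
                                      protein_b = character())
         else unique(pos)
  pos_key <- paste(pos$protein_a, pos$protein_b)

  neg <- if (length(member_ids) >= 2) {
    cmb <- utils::combn(member_ids, 2)
    all_mem <- data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                          stringsAsFactors = FALSE)
    all_mem[!(paste(all_mem$protein_a, all_mem$protein_b) %in% pos_key), ]
  } else data.frame(protein_a = character(), protein_b = character())

  # Coelution check on the un-padded region: positives lacking a fraction
  # where the profile product exceeds the threshold become negatives.
  if (nrow(pos) > 0) {
    V <- E$values[, seq_len(E$original_fractions), drop = FALSE]
    prod_max <- vapply(seq_len(nrow(pos)), function(r) {
      max(V[pos$protein_a[r], ] * V[pos$protein_b[r], ])
    }, numeric(1))
    reclass <- prod_max <= coelution_min
    if (any(reclass)) {
      neg <- rbind(neg, pos[reclass, ])
      pos <- pos[!reclass, ]
    }
  }

  lab <- rbind(
    if (nrow(pos)) cbind(pos, label = "positive"),
    if (nrow(neg)) cbind(neg, label = "negative")
  )
  if (is.null(lab))
    lab <- data.frame(protein_a = character(), protein_b = character(),
                      label = character())

  if (include_experimental) {
    cmb <- utils::combn(sort(ids), 2)
    allp <- data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                       stringsAsFactors = FALSE)
    lab_key <- paste(lab$protein_a, lab$protein_b)
    exp_rows <- allp[!(paste(allp$protein_a, allp$protein_b) %in% lab_key), ]
    if (nrow(exp_rows))
      lab <- rbind(lab, cbind(exp_rows, label = "experimental"))
  }
  lab$fold <- NA_integer_
  rownames(lab) <- NULL
  class(lab) <- c("pair_label_set", "data.frame")
  lab
}

#' Balance labeled pairs and assign cross-validation folds
#'
#' Negatives are down-sampled uniformly at random (seeded, without
#' replacement) to match the number of positives (1:1 class balance). In
#' `cv` mode the balanced pairs are partitioned into `k` disjoint folds,
#' stratified by label; in `split` mode a single balanced train/test
#' partition is produced (fold 1 = train, fold 2 = test, with `test_frac`
#' of pairs in the test partition). Experimental pairs never enter folds.
#'
#' @param P a `pair_label_set`.
#' @param k number of folds for `cv` mode (default 5).
#' @param seed integer seed for down-sampling and fold assignment.
#' @param mode `"cv"` or `"split"`.
#' @param test_frac test fraction for `split` mode (default 0.3).
#' @return The `pair_label_set` with the `fold` column filled for the
#'   balanced pairs; unselected negatives and experimental pairs keep
#'   `fold = NA`.
#' @export
make_folds <- function(P, k = 5L, seed = 1L, mode = c("cv", "split"),
                       test_frac = 0.3) {
  stopifnot(inherits(P, "pair_label_set"))
  mode <- match.arg(mode)
  k <- assert_count(k, "k")
  assert_prob(test_frac, "test_frac")
  ipos <- which(P$label == "positive")
  ineg <- which(P$label == "negative")
  need <- if (mode == "cv") k else 2L
  if (length(ipos) < need || length(ineg) < need)
    stop(sprintf("need at least %d positives and %d negatives", need, need))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  n_bal <- min(length(ipos), length(ineg))
  ipos <- if (length(ipos) > n_bal) sort(sample(ipos, n_bal)) else ipos
  ineg <- if (length(ineg) > n_bal) sort(sample(ineg, n_bal)) else ineg
  P$fold <- NA_integer_
  assign_folds <- function(idx, nf, frac = NULL) {
    n <- length(idx)
    f <- if (is.null(frac)) {
      rep(seq_len(nf), length.out = n)[sample.int(n)]
    } else {
      n_test <- round(frac * n)
      sample(c(rep(2L, n_test), rep(1L, n - n_test)))
    }
    f
  }
  if (mode == "cv") {
    P$fold[ipos] <- assign_folds(ipos, k)
    P$fold[ineg] <- assign_folds(ineg, k)
  } else {
    P$fold[ipos] <- assign_folds(ipos, 2L, test_frac)
    P$fold[ineg] <- assign_folds(ineg, 2L, test_frac)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  P
}

#' Write pair labels to TSV
#'
#' @param P a `pair_label_set`.
#' @param path output file path.
#' @export
write_pair_labels <- function(P, path) {
  utils::write.table(as.data.frame(P), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
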