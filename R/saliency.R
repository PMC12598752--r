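# Gradient saliency: which input positions drive a pair's predicted score.

#' Saliency profile for one predicted pair
#'
#' Computes the absolute gradient of the predicted interaction score with
#' respect to the assembled input rows of the two proteins and averages
#' the two gradient magnitudes, yielding one profile over the input axis
#' (CF-MS block followed by the sequence block).
#'
#' @param model a trained `cfnet_model`.
#' @param pair length-2 vector of protein ids or row indices.
#' @param X optional input matrix overriding the model's stored one.
#' @return An object of class `saliency_profile`: list with `values`
#'   (length `input_len`, non-negative), `cfms_region` and `seq_region`
#'   index vectors, and `padding_mask` flagging padded CF-MS positions.
#' @export
saliency_map <- function(model, pair, X = model$X) {
  stopifnot(inherits(model, "cfnet_model"))
  if (is.null(X)) stop("no input matrix available; supply X")
  if (is.null(model$training_log) || nrow(model$training_log) == 0)
    stop("model has not been trained")
  idx <- pairs_to_index(matrix(pair, ncol = 2), rownames(X))
  Xp <- X[c(idx[1], idx[2]), , drop = FALSE]
  fwd <- nn_forward(model$params, Xp, matrix(c(1L, 2L), ncol = 2))
  s <- fwd$scores
  bwd <- nn_backward(model$params, fwd, dU3 = s * (1 - s),
                     need_input_grad = TRUE, need_param_grads = FALSE)
  vals <- (abs(bwd$dX[1, ]) + abs(bwd$dX[2, ])) / 2
  cfms_len <- model$layout$cfms_len
  seq_len_ <- model$layout$seq_len
  orig <- model$layout$original_fractions
  pad <- rep(FALSE, cfms_len + seq_len_)
  if (!is.na(orig) && orig < cfms_len)
    pad[(orig + 1L):cfms_len] <- TRUE
  structure(list(values = unname(vals),
                 cfms_region = seq_len(cfms_len),
                 seq_region = cfms_len + seq_len(seq_len_),
                 padding_mask = pad),
            class = "saliency_profile")
}

#' Categorize a saliency profile by input dominance
#'
#' Compares the mean saliency intensity over the un-padded CF-MS positions
#' with the mean over the sequence positions. A difference strictly above
#' `margin` is `CFMS_gt_SEQ`, strictly below `-margin` is `CFMS_lt_SEQ`,
#' anything else (boundaries included) is `CFMS_sim_SEQ`. Profiles are
#' scaled by their maximum before comparison so the margin acts on a
#' common `[0,1]` intensity scale.
#'
#' @param profile a `saliency_profile`.
#' @param margin decision band half-width (default 0.1).
#' @return One of `"CFMS_gt_SEQ"`, `"CFMS_lt_SEQ"`, `"CFMS_sim_SEQ"`.
#' @export
categorize_saliency <- function(profile, margin = 0.1) {
  stopifnot(inherits(profile, "saliency_profile"))
  v <- profile$values
  mx <- max(v)
  if (mx > 0) v <- v / mx
  cf <- profile$cfms_region[!profile$padding_mask[profile$cfms_region]]
  d <- mean(v[cf]) - mean(v[profile$seq_region])
  if (d > margin) "CFMS_gt_SEQ"
  else if (d < -margin) "CFMS_lt_SEQ"
  else "CFMS_sim_SEQ"
}

#' Aggregate saliency profiles into one normalized map
#'
#' Superimposes (elementwise sums) the profiles and min-max normalizes the
#' sum to `[0,1]`. A constant sum yields an all-zero map with a warning.
#'
#' @param profiles non-empty list of `saliency_profile` objects (typically
#'   all profiles of one category).
#' @return Numeric vector in `[0,1]` of the common profile length.
#' @export
aggregate_saliency <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles to aggregate")
  stopifnot(all(vapply(profiles, inherits, logical(1), "saliency_profile")))
  total <- Reduce(`+`, lapply(profiles, `[[`, "values"))
  rng <- range(total)
  if (diff(rng) == 0) {
    warning("constant aggregate profile; returning zeros")
    return(total * 0)
  }
  (total - rng[1]) / diff(rng)
}

#' Saliency categories for a set of pairs
#'
#' @param model a trained `cfnet_model`.
#' @param pairs two-column matrix/data.frame of protein ids or indices.
#' @param margin decision band half-width (default 0.1).
#' @param X optional input matrix.
#' @return data.frame with the pair columns, the category, and the
#'   CF-MS-minus-sequence mean intensity difference.
#' @export
saliency_categories <- function(model, pairs, margin = 0.1, X = model$X) {
  idx <- pairs_to_index(pairs, rownames(X))
  res <- lapply(seq_len(nrow(idx)), function(r) {
    p <- saliency_map(model, idx[r, ], X)
    list(cat = categorize_saliency(p, margin), profile = p)
  })
  data.frame(a = idx[, 1], b = idx[, 2],
             category = vapply(res, `[[`, character(1), "cat"))
}
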