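# Correlation-based feature ranking and feature-set materialization.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties) of the two
#' vectors.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  abort_if(length(x) != length(y) || length(x) < 3,
           "spearman_rho: vectors must have equal length >= 3")
  rx <- rank(x); ry <- rank(y)
  abort_if(stats::var(rx) == 0 || stats::var(ry) == 0,
           "undefined-correlation error: zero rank variance")
  stats::cor(rx, ry)
}

#' Phi coefficient of two binary vectors
#'
#' `phi = (n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)` from the 2x2
#' contingency table; numerically identical to the Pearson correlation of the
#' two 0/1 vectors.
#'
#' @param a,b Binary (0/1) vectors of equal length >= 4.
#' @return Phi in `[-1, 1]`.
#' @export
phi_coefficient <- function(a, b) {
  abort_if(length(a) != length(b) || length(a) < 4,
           "phi_coefficient: vectors must have equal length >= 4")
  abort_if(!is_binary(a) || !is_binary(b),
           "phi_coefficient: inputs must be binary (0/1)")
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  margins <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  abort_if(any(margins == 0),
           "undefined-correlation error: zero margin in the 2x2 table")
  (n11 * n00 - n10 * n01) / sqrt(prod(margins))
}

#' Rank features by correlation with the instability labels
#'
#' Computes, per feature, Spearman's rho between the per-squat scalar summary
#' and the binary label, and the phi coefficient between the binarized
#' summary (median split by default) and the label.  Features are ranked by
#' descending absolute coefficient.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @param summaries Optional `n x k` summary matrix overriding the dataset's
#'   stored summaries (KS -> peak |KS|, KD -> mean, SD -> scalar depth,
#'   SV -> mean, SA -> total).
#' @param binarizer Function mapping a numeric summary vector to 0/1
#'   (default: above-median split).
#' @return A `feature_ranking` data frame:
#'   `feature,rho,phi,rho_rank,phi_rank`.
#' @export
rank_features <- function(dataset, summaries = NULL,
                          binarizer = function(v) as.integer(v > stats::median(v))) {
  y <- dataset$labels
  abort_if(length(unique(y)) < 2,
           "rank_features: labels contain a single class")
  s <- summaries %||% dataset$summaries
  k <- ncol(s)
  rho <- phi <- numeric(k)
  for (j in seq_len(k)) {
    rho[j] <- spearman_rho(s[, j], y)
    phi[j] <- phi_coefficient(binarizer(s[, j]), y)
  }
  out <- data.frame(
    feature = dataset$feature_ids[seq_len(k)],
    name = colnames(s) %||% as.character(seq_len(k)),
    rho = rho, phi = phi,
    rho_rank = rank(-abs(rho), ties.method = "first"),
    phi_rank = rank(-abs(phi), ties.method = "first")
  )
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' The five benchmark feature sets
#'
#' @return Named list of feature-id vectors: `"1,2,3,4,5"`, `"1,2,3"`,
#'   `"1,3,5"`, `"4,5"`, `"2,4"`.
#' @export
default_feature_sets <- function() {
  list("1,2,3,4,5" = 1:5, "1,2,3" = 1:3, "1,3,5" = c(1L, 3L, 5L),
       "4,5" = c(4L, 5L), "2,4" = c(2L, 4L))
}

#' Subset a labeled dataset to a feature set
#'
#' Slices the tensor's channel axis, preserving channel order, labels and
#' metadata.
#'
#' @param dataset A `labeled_dataset`.
#' @param set Vector of feature ids from `{1..5}` (global ids, regardless of
#'   previous subsetting), or a comma-joined string like `"1,3,5"`.
#' @return The channel-sliced `labeled_dataset`.
#' @export
make_set <- function(dataset, set) {
  if (is.character(set)) {
    set <- as.integer(strsplit(set, ",")[[1]])
  }
  set <- as.integer(set)
  abort_if(length(set) == 0 || anyDuplicated(set) > 0,
           "make_set: feature ids must be non-empty and unique")
  pos <- match(set, dataset$feature_ids)
  abort_if(anyNA(pos), "make_set: unknown feature id(s) ",
           paste(set[is.na(pos)], collapse = ", "),
           " (available: ", paste(dataset$feature_ids, collapse = ", "), ")")
  dataset$x <- dataset$x[, , pos, drop = FALSE]
  dataset$summaries <- dataset$summaries[, pos, drop = FALSE]
  dataset$feature_ids <- set
  dataset
}
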