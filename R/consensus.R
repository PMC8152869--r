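## Group-level consensus parcellation from a set of individual parcellations
## on a common template mask, via co-association (evidence accumulation)
## clustering — invariant to per-subject label permutations.

#' Consensus partition of a set of parcellations
#'
#' Builds the co-association matrix (the fraction of subjects placing each
#' voxel pair in the same nucleus) and clusters \code{1 - co-association}
#' with average-linkage agglomeration cut at \code{k}. Because co-association
#' only asks "same label or not", the result is invariant to arbitrary
#' per-subject label permutations.
#'
#' @param parcellations List (length >= 2) of parcellation objects or label
#'   arrays on an identical mask.
#' @param k Number of consensus clusters (default: number of labels in the
#'   first parcellation).
#' @return A \code{thalamic_parcellation} with provenance \code{"consensus"}.
#' @export
consensus_partition <- function(parcellations, k = NULL) {
  if (length(parcellations) < 2) stop("need at least 2 parcellations")
  labs <- lapply(parcellations, parcellation_labels)
  masks <- lapply(labs, function(l) l > 0)
  for (m in masks[-1])
    if (!identical(which(masks[[1]]), which(m)))
      stop("parcellations are not on an identical mask")
  idx <- which(masks[[1]])
  if (is.null(k)) k <- max(labs[[1]])
  vecs <- lapply(labs, function(l) l[idx])
  n <- length(idx)
  co <- matrix(0, n, n)
  for (v in vecs) co <- co + outer(v, v, "==")
  co <- co / length(vecs)
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  memb <- stats::cutree(hc, k = k)
  labels <- if (is.array(labs[[1]])) {
    out <- array(0L, dim(labs[[1]]))
    out[idx] <- memb
    out
  } else {
    out <- integer(length(labs[[1]]))
    out[idx] <- memb
    out
  }
  structure(list(labels = labels, assignment = memb, positions = NULL,
                 centroids = NULL, objective = numeric(0), iterations = 0L,
                 converged = TRUE, config = list(k = k),
                 hemisphere = NA_character_, provenance = "consensus"),
            class = "thalamic_parcellation")
}
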