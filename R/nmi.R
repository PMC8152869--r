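## Normalized mutual information between parcellations and the
## group-reallocation permutation test for partition dissimilarity.

#' Normalized mutual information between two partitions
#'
#' Implements the over-entropies form
#' \deqn{NMI(A,B) = \frac{-2 \sum_i \sum_j N_{ij} \log(N_{ij} N / (N_i N_j))}
#'   {\sum_i N_i \log(N_i/N) + \sum_j N_j \log(N_j/N)}}
#' on the voxel contingency table of the two partitions, with
#' \eqn{0 \log 0 = 0}. NMI is symmetric, invariant to label permutation,
#' lies in [0, 1], and equals 1 iff the partitions are identical up to
#' relabeling. When both partitions are a single cluster the denominator is
#' 0; the value is then defined as 1 (identical trivial partitions) with
#' attribute \code{"degenerate"} set.
#'
#' @param a,b Parcellation objects or label arrays/vectors on an identical
#'   mask (0 = background).
#' @return NMI in [0, 1].
#' @export
nmi <- function(a, b) {
  la <- parcellation_labels(a)
  lb <- parcellation_labels(b)
  ina <- la > 0
  inb <- lb > 0
  if (!identical(which(ina), which(inb)))
    stop("partitions are not on an identical mask")
  va <- la[ina]
  vb <- lb[inb]
  tab <- table(va, vb)
  N <- sum(tab)
  Ni <- rowSums(tab)
  Nj <- colSums(tab)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  num <- -2 * sum(xlogy(tab, tab * N / outer(Ni, Nj)))
  den <- sum(xlogy(Ni, Ni / N)) + sum(xlogy(Nj, Nj / N))
  if (den == 0) return(structure(1, degenerate = TRUE))
  num / den
}

#' Group-reallocation permutation test on consensus-partition NMI
#'
#' The observed statistic is the NMI between the consensus partitions of the
#' two groups. Under the null, subjects are randomly reallocated to two
#' groups of the original sizes (without replacement) and the consensus NMI
#' is recomputed; this is repeated \code{n_perm} times. Significance is
#' declared when the observed NMI falls outside the empirical 2.5th-97.5th
#' percentile interval of the null (two-tailed at P = 0.05), and a two-sided
#' permutation p-value around the null mean is reported with the add-one
#' convention.
#'
#' @param group1,group2 Lists of parcellation objects / label arrays on a
#'   common template mask (>= 2 subjects each).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the reallocation draws.
#' @param k Number of consensus clusters (default from the data).
#' @return Object of class \code{nmi_test}: \code{observed},
#'   \code{null_values}, \code{p.value}, \code{ci} (2.5/97.5 percentiles),
#'   \code{significant}, \code{n_perm}.
#' @export
nmi_permutation_test <- function(group1, group2, n_perm = 1000, seed = 1L,
                                 k = NULL) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 subjects")
  if (n_perm < 100)
    warning("n_perm < 100 gives unstable percentile critical values")
  all_parc <- c(group1, group2)
  n1 <- length(group1)
  n <- length(all_parc)
  observed <- nmi(consensus_partition(group1, k = k),
                  consensus_partition(group2, k = k))
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pick <- sample.int(n, n1)
    nmi(consensus_partition(all_parc[pick], k = k),
        consensus_partition(all_parc[-pick], k = k))
  }, numeric(1)))
  ci <- stats::quantile(null_values, c(0.025, 0.975), names = FALSE, type = 7)
  center <- mean(null_values)
  p <- (1 + sum(abs(null_values - center) >= abs(observed - center))) /
    (n_perm + 1)
  structure(list(observed = observed, null_values = null_values,
                 p.value = p, ci = ci,
                 significant = observed < ci[1] || observed > ci[2],
                 n_perm = n_perm, seed = seed),
            class = "nmi_test")
}

#' @export
print.nmi_test <- function(x, ...) {
  cat("Group-reallocation permutation test on consensus NMI\n")
  cat(sprintf("  observed NMI = %.4f, null 95%% interval [%.4f, %.4f]\n",
              x$observed, x$ci[1], x$ci[2]))
  cat(sprintf("  p = %.4g (%d permutations)%s\n", x$p.value, x$n_perm,
              if (x$significant) " *" else ""))
  invisible(x)
}

## Evaluate expr with a temporary RNG state seeded by `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
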