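# Spacer diversity: the diverse / non-diverse / short trichotomy.

#' Cluster the spacers of one array
#'
#' Greedy incremental clustering (as in [cluster_repeats()]) at the spacer
#' identity threshold; spacers sharing more than `threshold` identity fall
#' into one cluster.
#'
#' @param spacers Character vector of spacer sequences.
#' @param threshold Identity threshold (default 0.70).
#' @return Integer membership vector (cluster index per spacer); the number
#'   of clusters is `max()` of it (0 for no spacers).
#' @export
cluster_spacers <- function(spacers, threshold = 0.70) {
  if (!length(spacers)) return(integer())
  .greedy_cluster(as.character(spacers), threshold)$membership
}

#' Spacer diversity call for an array
#'
#' An array is `DIVERSE` when its spacers fall into at least `ceiling(n/2)`
#' clusters at 70% identity, with a minimum of two clusters (a pair of
#' identical spacers is never diverse). Non-diverse arrays with at most two
#' spacers are `SHORT`; larger non-diverse arrays are `NOT_DIVERSE`.
#' `redundant_spacers` counts spacers sitting in multi-member clusters beyond
#' the first, i.e. `n_spacers - n_spacer_clusters`.
#'
#' @param array A [crispr_array()] or a character vector of spacers.
#' @param threshold Spacer identity threshold.
#' @return A list of class `diversity_call`: `n_spacers`,
#'   `n_spacer_clusters`, `status` (`DIVERSE`/`NOT_DIVERSE`/`SHORT`),
#'   `redundant_spacers`.
#' @export
is_diverse <- function(array, threshold = 0.70) {
  spacers <- if (inherits(array, "crispr_array")) array$spacers$seq
             else as.character(array)
  n <- length(spacers)
  if (n == 0L) {
    return(structure(list(n_spacers = 0L, n_spacer_clusters = 0L,
                          status = "SHORT", redundant_spacers = 0L),
                     class = "diversity_call"))
  }
  membership <- cluster_spacers(spacers, threshold)
  k <- max(membership)
  status <- if (k >= max(2L, ceiling(n / 2))) "DIVERSE"
            else if (n <= 2L) "SHORT"
            else "NOT_DIVERSE"
  structure(list(n_spacers = n, n_spacer_clusters = k, status = status,
                 redundant_spacers = n - k),
            class = "diversity_call")
}

#' @export
print.diversity_call <- function(x, ...) {
  cat(sprintf("<diversity_call> %s  %d spacers in %d clusters (%d redundant)\n",
              x$status, x$n_spacers, x$n_spacer_clusters,
              x$redundant_spacers))
  invisible(x)
}
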