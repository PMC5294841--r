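# Greedy incremental clustering of consensus repeats (CD-HIT-EST style) and
# comparison of repeats against external collections.

# Shared greedy engine: sequences are visited longest-first (ties by input
# order); each joins the first existing cluster whose representative it
# matches at >= threshold, else founds a new cluster. Returns an integer
# membership vector (cluster index per input) plus the representatives.
.greedy_cluster <- function(seqs, threshold, both_strands = FALSE) {
  n <- length(seqs)
  membership <- integer(n)
  reps <- character()
  ord <- order(-nchar(seqs), seq_len(n))
  for (i in ord) {
    assigned <- 0L
    if (length(reps)) {
      ident <- .identity_many(seqs[i], reps)
      if (both_strands)
        ident <- pmax(ident, .identity_many(revcomp(seqs[i]), reps))
      hit <- which(ident >= threshold)
      if (length(hit)) assigned <- hit[1]
    }
    if (!assigned) {
      reps <- c(reps, seqs[i])
      assigned <- length(reps)
    }
    membership[i] <- assigned
  }
  list(membership = membership, representatives = reps)
}

#' Cluster consensus repeats across genomes
#'
#' Greedy incremental clustering at `threshold` identity (identity denominator
#' = shorter sequence, as in CD-HIT): sequences are processed longest-first,
#' each joining the first cluster whose representative it matches, else
#' founding its own. Reverse-complement matching is off by default; repeats on
#' opposite strands form distinct clusters unless `both_strands = TRUE`.
#'
#' @param consensuses Character vector of consensus repeats; names (e.g.
#'   array ids) are carried into the cluster members.
#' @param threshold Identity threshold in (0, 1].
#' @param both_strands Also match the reverse complement.
#' @param min_members Member count from which a cluster is labelled a cluster
#'   rather than a singleton.
#' @return A list of `repeat_cluster` objects: `cluster_id`,
#'   `representative`, `members` (names or indices), `is_singleton`.
#' @export
cluster_repeats <- function(consensuses, threshold = 0.90,
                            both_strands = FALSE, min_members = 2L) {
  if (!length(consensuses)) return(list())
  ids <- names(consensuses)
  if (is.null(ids)) ids <- as.character(seq_along(consensuses))
  g <- .greedy_cluster(as.character(consensuses), threshold, both_strands)
  lapply(seq_along(g$representatives), function(ci) {
    members <- ids[g$membership == ci]
    structure(list(cluster_id = sprintf("cluster%04d", ci),
                   representative = g$representatives[ci],
                   members = members,
                   is_singleton = length(members) < min_members),
              class = "repeat_cluster")
  })
}

#' @export
print.repeat_cluster <- function(x, ...) {
  cat(sprintf("<repeat_cluster> %s  %d member(s)%s  rep %s\n", x$cluster_id,
              length(x$members), if (x$is_singleton) " (singleton)" else "",
              x$representative))
  invisible(x)
}

#' Compare a repeat against an external collection
#'
#' Screens a query repeat against a collection of repeat sequences (e.g. an
#' external CRISPR repeat database) and reports the first member matching at
#' `identity` over at least `coverage` of the query length, using the best
#' local alignment. Used to flag entries of external collections that match
#' curated false-CRISPR repeats.
#'
#' @param query_repeat Query sequence.
#' @param collection Character vector of collection sequences (names carried
#'   into the report), or a FASTA path.
#' @param identity,coverage Thresholds; defaults follow the 90%/90% rule.
#' @return A list `(member, identity, coverage)` for the first hit, or `NULL`.
#' @export
compare_to_collection <- function(query_repeat, collection,
                                  identity = 0.90, coverage = 0.90) {
  if (is.character(collection) && length(collection) == 1L &&
      file.exists(collection)) {
    set <- Biostrings::readDNAStringSet(collection)
    collection <- stats::setNames(as.character(set),
                                  sub("\\s.*$", "", names(set)))
  }
  ids <- names(collection)
  if (is.null(ids)) ids <- as.character(seq_along(collection))
  qlen <- nchar(query_repeat)
  for (i in seq_along(collection)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = toupper(query_repeat), subject = toupper(collection[[i]]),
      type = "local", substitutionMatrix = .IDENTITY_SUBMAT,
      gapOpening = 4, gapExtension = 2)
    pr <- Biostrings::pattern(aln)
    aligned_q <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
    if (length(aligned_q) == 0L || aligned_q <= 0L) next
    idn <- .aln_matches(aln) / aligned_q
    cov <- aligned_q / qlen
    if (idn >= identity && cov >= coverage)
      return(list(member = ids[i], identity = idn, coverage = cov))
  }
  NULL
}
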