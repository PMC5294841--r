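#' Construct a CRISPR array object
#'
#' An ordered repeat-spacer structure on one genome record. Repeats and
#' spacers strictly alternate, are non-overlapping and ascending, and every
#' sequence equals the genome slice at its coordinates (1-based inclusive).
#'
#' @param genome_id Identifier of the carrying genome record.
#' @param repeats data.frame with columns `start`, `end`, `seq`, `partial`
#'   (logical; `TRUE` marks a partial terminal repeat).
#' @param spacers data.frame with columns `start`, `end`, `seq` (zero rows
#'   allowed for a two-repeat fragment under non-default parameters).
#' @param consensus Consensus repeat; computed with [consensus_repeat()] from
#'   the full-length repeats when `NULL`.
#' @param notes Optional character vector of annotations (e.g. an oversized
#'   merge gap retained as an insertion).
#' @return A list of class `crispr_array`.
#' @export
crispr_array <- function(genome_id, repeats, spacers, consensus = NULL,
                         notes = character()) {
  stopifnot(is.data.frame(repeats), nrow(repeats) >= 1L)
  if (is.null(repeats$partial)) repeats$partial <- FALSE
  if (is.null(spacers))
    spacers <- data.frame(start = integer(), end = integer(),
                          seq = character(), stringsAsFactors = FALSE)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  spacers <- spacers[order(spacers$start), , drop = FALSE]
  ivs <- rbind(repeats[c("start", "end")], spacers[c("start", "end")])
  ivs <- ivs[order(ivs$start), , drop = FALSE]
  if (any(ivs$start > ivs$end) ||
      (nrow(ivs) > 1L && any(ivs$start[-1] <= ivs$end[-nrow(ivs)])))
    stop("repeats and spacers must be non-overlapping and ascending")
  if (is.null(consensus)) {
    full <- repeats$seq[!repeats$partial]
    if (!length(full)) full <- repeats$seq
    consensus <- consensus_repeat(full)
  }
  structure(list(
    genome_id = genome_id,
    start = min(repeats$start, if (nrow(spacers)) spacers$start),
    end = max(repeats$end, if (nrow(spacers)) spacers$end),
    repeats = repeats,
    spacers = spacers,
    consensus_repeat = consensus,
    partial_terminal = c(`5` = isTRUE(repeats$partial[1]),
                         `3` = isTRUE(repeats$partial[nrow(repeats)])),
    notes = notes), class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s:%d-%d  %d repeats / %d spacers  consensus %s\n",
              x$genome_id, x$start, x$end, nrow(x$repeats), nrow(x$spacers),
              x$consensus_repeat))
  invisible(x)
}

#' Consensus repeat of an array
#'
#' Per-column majority base over the length-aligned repeat copies. Copies are
#' aligned end-gap-free to the modal-length copy; copies deviating more than
#' 20% from the modal length are excluded from the vote. Column ties are
#' broken by the first-occurring base among the tied candidates.
#'
#' @param repeats Character vector of repeat sequences (partial terminal
#'   copies should already be excluded).
#' @return The consensus string.
#' @export
consensus_repeat <- function(repeats) {
  if (!length(repeats)) stop("consensus of zero repeats")
  lens <- nchar(repeats)
  tab <- table(lens)
  modal <- as.integer(names(tab)[which.max(tab)])
  keep <- abs(lens - modal) <= 0.2 * modal
  reps <- repeats[keep]
  lens <- lens[keep]
  ref <- reps[lens == modal][1]
  refc <- .seq_chars(ref)
  mat <- matrix(NA_character_, nrow = length(reps), ncol = modal)
  for (i in seq_along(reps)) {
    ch <- .seq_chars(reps[i])
    L <- length(ch)
    if (L == modal) {
      mat[i, ] <- ch
    } else if (L < modal) {
      offs <- 0:(modal - L)
      sc <- vapply(offs, function(o) sum(ch == refc[(o + 1):(o + L)]), 0L)
      o <- offs[which.max(sc)]
      mat[i, (o + 1):(o + L)] <- ch
    } else {
      offs <- 0:(L - modal)
      sc <- vapply(offs, function(o) sum(ch[(o + 1):(o + modal)] == refc), 0L)
      o <- offs[which.max(sc)]
      mat[i, ] <- ch[(o + 1):(o + modal)]
    }
  }
  letters5 <- c("A", "C", "G", "T", "N")
  cons <- character(modal)
  for (j in seq_len(modal)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    counts <- tabulate(match(col, letters5), 5L)
    top <- letters5[counts == max(counts)]
    cons[j] <- if (length(top) == 1L) top else col[col %in% top][1]
  }
  paste(cons, collapse = "")
}

# Internal invariant check used by tests and the pipeline.
.validate_array <- function(array, genome) {
  stopifnot(inherits(array, "crispr_array"))
  slices <- function(df) {
    if (!nrow(df)) return(TRUE)
    all(substring(genome$seq, df$start, df$end) == df$seq)
  }
  ok <- slices(array$repeats) && slices(array$spacers) &&
    array$start >= 1L && array$end <= genome$length
  n_full <- nrow(array$repeats)
  ok && n_full == nrow(array$spacers) + 1L
}
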