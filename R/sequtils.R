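# Low-level sequence helpers shared across modules.

# Structured debug logging for the auditable decision classes (merging,
# rescue, classification); enabled with options(crisprsieve.verbose = TRUE).
.log_debug <- function(...) {
  if (isTRUE(getOption("crisprsieve.verbose", FALSE)))
    message("[crisprsieve] ", sprintf(...))
}

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Reverse complement of a nucleotide string
#'
#' Operates on `{A,C,G,T,N}` strings; `N` maps to `N`.
#'
#' @param seq Nucleotide string.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) {
           paste(rev(.seq_chars(s)), collapse = "")
         }, "", USE.NAMES = FALSE))
}

# Substitution matrix over {A,C,G,T,N}: +1 identical base, -1 otherwise.
# N mismatches everything, including N, so matches never cross N runs.
.IDENTITY_SUBMAT <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  m[cbind(1:4, 1:4)] <- 1
  m
})

.global_alignment <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "global",
    substitutionMatrix = .IDENTITY_SUBMAT,
    gapOpening = 4, gapExtension = 2)
}

# Identical aligned non-N bases per alignment (vectorised over the pattern
# set). nmatch() would count N==N, which the N policy forbids.
.aln_matches <- function(aln) {
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")
  mapply(function(p, s) sum(p == s & p != "N" & p != "-"), pat, sub,
         USE.NAMES = FALSE)
}

#' Pairwise sequence identity
#'
#' Identity between two nucleotide sequences: identical aligned bases in the
#' best global alignment divided by the length of the shorter sequence (the
#' CD-HIT convention). Symmetric; `N` counts as a mismatch against every
#' base including `N`.
#'
#' @param a,b Nucleotide strings.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity on an empty sequence")
  aln <- .global_alignment(toupper(a), toupper(b))
  .aln_matches(aln) / min(nchar(a), nchar(b))
}

# Identity of one query against many subjects at once (greedy clustering
# inner loop). Returns a numeric vector parallel to `subjects`.
.identity_many <- function(query, subjects) {
  if (!length(subjects)) return(numeric())
  aln <- .global_alignment(Biostrings::DNAStringSet(subjects), query)
  .aln_matches(aln) / pmin(nchar(query), nchar(subjects))
}

# Minimum mismatch count over all ungapped end-free offsets of a against b.
# Unaligned overhang beyond the overlap counts as mismatches, so the total
# is mismatches-in-overlap + (max(len) - overlap); for equal lengths at
# offset 0 this is the Hamming distance.
.endfree_mismatches <- function(a, b) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  la <- length(ca); lb <- length(cb)
  best <- max(la, lb) # zero overlap
  for (off in seq(-(la - 1L), lb - 1L)) {
    i0 <- max(1L, 1L - off)          # first a-position in overlap
    j0 <- i0 + off
    w <- min(la - i0, lb - j0) + 1L
    if (w < 1L) next
    mism <- sum(ca[i0:(i0 + w - 1L)] != cb[j0:(j0 + w - 1L)]) +
      sum(ca[i0:(i0 + w - 1L)] == "N" & cb[j0:(j0 + w - 1L)] == "N")
    d <- mism + (max(la, lb) - w)
    if (d < best) best <- d
  }
  best
}

# Mononucleotide frequencies over A,C,G,T (N excluded from the denominator).
.base_freqs <- function(seq) {
  ch <- .seq_chars(seq)
  ch <- ch[ch != "N"]
  if (!length(ch)) return(c(A = 0, C = 0, G = 0, T = 0))
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  as.vector(tab) / length(ch) -> f
  names(f) <- c("A", "C", "G", "T")
  f
}

# Shannon entropy (bits) of the mononucleotide composition.
.mono_entropy <- function(seq) {
  f <- .base_freqs(seq)
  f <- f[f > 0]
  if (!length(f)) return(0)
  -sum(f * log2(f))
}
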