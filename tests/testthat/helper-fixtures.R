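# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A genome string with an explicit repeat-spacer array embedded in random
# flanks; returns the sequence plus the exact coordinates of every part.
embed_array <- function(repeat_seq, spacers, flank = 2000L,
                        copies = NULL, gc = 0.5) {
  if (is.null(copies))
    copies <- rep(repeat_seq, length(spacers) + 1L)
  parts <- character()
  for (i in seq_along(copies)) {
    parts <- c(parts, copies[i])
    if (i <= length(spacers)) parts <- c(parts, spacers[i])
  }
  body <- paste(parts, collapse = "")
  left <- rand_seq(flank, gc)
  right <- rand_seq(flank, gc)
  w <- nchar(repeat_seq)
  rep_starts <- integer(length(copies))
  at <- flank
  for (i in seq_along(copies)) {
    rep_starts[i] <- at + 1L
    at <- at + nchar(copies[i])
    if (i <= length(spacers)) at <- at + nchar(spacers[i])
  }
  list(seq = paste0(left, body, right),
       start = flank + 1L, end = flank + nchar(body),
       rep_starts = rep_starts, width = w)
}

# Mutate `k` distinct positions of a sequence to a different base.
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# Four toy spacers, mutually dissimilar (checked once in the diversity
# tests before use).
toy_spacers <- function() {
  set.seed(4242)
  vapply(1:4, function(i) rand_seq(32), "")
}

# Cas-hit rows, validated loci and coordinate-pinned arrays used by the
# locus and acceptance tests.
mk_hits <- function(families, starts, genome_id = "g1", gene_len = 600L) {
  data.frame(genome_id = genome_id, gene_start = starts,
             gene_end = starts + gene_len - 1L, strand = "+",
             family = families, score = 100, source = "table",
             stringsAsFactors = FALSE)
}

mk_locus <- function(families, start = 1000L) {
  starts <- start + (seq_along(families) - 1L) * 700L
  cand <- list(genome_id = "g1", start = min(starts),
               end = max(starts) + 599L,
               genes = mk_hits(families, starts))
  validate_locus(cand)
}

mk_array_at <- function(start, end, genome_id = "g1") {
  w <- 25L
  reps <- data.frame(start = c(start, end - w + 1L),
                     end = c(start + w - 1L, end),
                     seq = strrep("A", w), partial = FALSE)
  sp <- data.frame(start = start + w, end = end - w,
                   seq = strrep("C", end - start + 1L - 2L * w))
  crispr_array(genome_id, reps, sp)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
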