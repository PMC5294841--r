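# Synthetic genomes with planted elements and full ground truth, so every
# pipeline stage can be benchmarked without external data.

.random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- .seq_chars(seq)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Plant a CRISPR repeat-spacer array
#'
#' Builds the sequence of an array with `n_spacers + 1` repeat copies.
#' Spacer lengths follow the repeat length within +-5 bp. Copies are mutated
#' independently at `mutation_rate` per base. Spacer content per
#' `diversity_mode`: `diverse` draws i.i.d. random spacers, `duplicated`
#' draws distinct spacers but repeats one of them once, `constant` uses a
#' single spacer throughout.
#'
#' @param repeat_len Repeat length (21--47 bp).
#' @param n_spacers Number of spacers.
#' @param diversity_mode `"diverse"`, `"duplicated"` or `"constant"`.
#' @param mutation_rate Per-base substitution rate applied to each repeat
#'   copy.
#' @param gc Background GC content for the random parts.
#' @return A list (`kind = "CRISPR"`): `seq`, `repeat_seq`, `spacers`,
#'   `repeat_offsets` (0-based starts within `seq`), `intended_diversity`.
#' @export
plant_crispr <- function(repeat_len = 25L, n_spacers = 6L,
                         diversity_mode = c("diverse", "duplicated",
                                            "constant"),
                         mutation_rate = 0, gc = 0.5) {
  diversity_mode <- match.arg(diversity_mode)
  stopifnot(repeat_len >= 21L, repeat_len <= 47L, n_spacers >= 1L)
  rep_seq <- .random_seq(repeat_len, gc)
  sp_lens <- repeat_len + sample(-5:5, n_spacers, replace = TRUE)
  sp_lens <- pmax(sp_lens, 18L)
  spacers <- switch(diversity_mode,
    diverse = vapply(sp_lens, .random_seq, "", gc = gc),
    constant = rep(.random_seq(sp_lens[1], gc), n_spacers),
    duplicated = {
      sp <- vapply(sp_lens, .random_seq, "", gc = gc)
      if (n_spacers >= 2L) {
        at <- if (n_spacers == 2L) 2L else sample(2:n_spacers, 1L)
        sp[at] <- sp[1]
      }
      sp
    })
  copies <- vapply(seq_len(n_spacers + 1L), function(i) {
    .mutate_seq(rep_seq, mutation_rate)
  }, "")
  parts <- character(0)
  offsets <- integer(0)
  at <- 0L
  for (i in seq_len(n_spacers + 1L)) {
    offsets <- c(offsets, at)
    parts <- c(parts, copies[i])
    at <- at + repeat_len
    if (i <= n_spacers) {
      parts <- c(parts, spacers[i])
      at <- at + nchar(spacers[i])
    }
  }
  intended <- switch(diversity_mode,
                     diverse = "DIVERSE",
                     constant = if (n_spacers <= 2L) "SHORT" else "NOT_DIVERSE",
                     duplicated = if (n_spacers <= 2L) "SHORT" else "DIVERSE")
  list(kind = "CRISPR", seq = paste(parts, collapse = ""),
       repeat_seq = rep_seq, spacers = spacers, repeat_offsets = offsets,
       intended_diversity = intended)
}

#' Plant a STAR-like element
#'
#' Direct repeats each embedding one instantiation of the STAR signature
#' motif (sampled uniformly over the bracket combinations and both strands),
#' separated by identical linkers -- the repeat-spacer mimicry that gets
#' STAR elements reported as CRISPRs.
#'
#' @param n_copies Number of repeat units.
#' @param unit_len Repeat unit length (>= 14 to hold the motif).
#' @param linker_len Linker length between units.
#' @param gc GC content of the non-motif sequence; STAR elements are GC-rich
#'   so the default leans that way.
#' @return A list (`kind = "STAR"`): `seq`, `unit`, `linker`, `motif`.
#' @export
plant_star <- function(n_copies = 5L, unit_len = 40L, linker_len = 30L,
                       gc = 0.6) {
  stopifnot(unit_len >= 14L, n_copies >= 2L)
  motif <- sample(star_motif_instances(), 1L)
  if (sample(c(TRUE, FALSE), 1L)) motif <- revcomp(motif)
  off <- sample.int(unit_len - 14L + 1L, 1L) - 1L
  unit <- paste0(.random_seq(off, gc), motif,
                 .random_seq(unit_len - 14L - off, gc))
  linker <- .random_seq(linker_len, gc)
  seq <- paste0(paste(rep(paste0(unit, linker), n_copies - 1L),
                      collapse = ""), unit)
  list(kind = "STAR", seq = seq, unit = unit, linker = linker,
       motif = motif)
}

#' Plant a tandem repeat
#'
#' Head-to-tail exact copies of a random unit. The default unit length range
#' mimics the CRISPR-mimicking tandem repeats: each copy long enough to be
#' split by an array detector into a conserved "repeat" part and a
#' spacer-sized remainder.
#'
#' @param unit_len Unit length in bp (default drawn from 66--100).
#' @param copies Number of copies (>= 2).
#' @param gc GC content.
#' @return A list (`kind = "TANDEM"`): `seq`, `unit`, `copies`.
#' @export
plant_tandem <- function(unit_len = NULL, copies = 8L, gc = 0.5) {
  if (is.null(unit_len)) unit_len <- sample(66:100, 1L)
  stopifnot(copies >= 2L, unit_len >= 1L)
  unit <- .random_seq(unit_len, gc)
  list(kind = "TANDEM", seq = paste(rep(unit, copies), collapse = ""),
       unit = unit, copies = copies)
}

#' Plant a simple (low-complexity) repeat
#'
#' A mononucleotide run with light substitution noise, mimicking the A-rich
#' and short-unit low-complexity regions reported as CRISPRs.
#'
#' @param base Run base.
#' @param length Run length in bp.
#' @param noise Per-base substitution rate (default 5%).
#' @return A list (`kind = "SIMPLE"`): `seq`, `base`.
#' @export
plant_simple <- function(base = "A", length = 290L, noise = 0.05) {
  seq <- .mutate_seq(strrep(base, length), noise)
  list(kind = "SIMPLE", seq = seq, base = base)
}

# Gene complements used for planted cas loci. Each stub gene is 900 bp with
# 50 bp intergenic gaps; sequence content is random (the annotation table,
# not the sequence, carries the gene calls).
.CAS_LOCUS_GENES <- list(
  I = c("cas3", "cse1", "cse2", "cas7", "cas5", "cas1", "cas2"),
  II = c("cas9", "cas1", "cas2", "csn2"),
  III = c("cas10", "csm2", "csm3", "csm4", "csm5", "cas1", "cas2"),
  IV = c("csf1", "csf2", "csf3"),
  V = c("cpf1", "cas1", "cas2"))

#' Plant a cas locus
#'
#' Coordinate stubs for the gene complement of one CRISPR-Cas type, emitted
#' as random sequence plus annotation rows (relative coordinates).
#'
#' @param type `"I"` to `"V"`.
#' @param families Override the gene complement.
#' @param gene_len,gap_len Stub gene and intergenic lengths in bp.
#' @param gc GC content.
#' @return A list (`kind = "CAS_LOCUS"`): `seq`, `genes` (data.frame with
#'   0-based `offset_start`, `offset_end`, `strand`, `family`), `type`.
#' @export
plant_cas_locus <- function(type = "I", families = NULL, gene_len = 900L,
                            gap_len = 50L, gc = 0.5) {
  if (is.null(families)) {
    families <- .CAS_LOCUS_GENES[[type]]
    if (is.null(families)) stop("unknown cas locus type: ", type)
  }
  ng <- length(families)
  starts <- (seq_len(ng) - 1L) * (gene_len + gap_len)
  total <- ng * gene_len + (ng - 1L) * gap_len
  genes <- data.frame(offset_start = starts,
                      offset_end = starts + gene_len - 1L,
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      family = families, stringsAsFactors = FALSE)
  list(kind = "CAS_LOCUS", seq = .random_seq(total, gc), genes = genes,
       type = type)
}

#' Generate a synthetic genome with planted elements and ground truth
#'
#' Plants the requested elements into i.i.d. random background of the given
#' GC content. Elements are separated by at least twice the longest element
#' length of background, so no planted element interferes with another. A
#' CRISPR element may carry a companion cas locus at a fixed distance
#' downstream, forming a complete CRISPR-Cas system. Fully reproducible for
#' a fixed seed.
#'
#' @param spec A list: `id` (record id, default `"synth"`), `gc` (default
#'   0.5), optional `length` (minimum genome length; an error is raised if
#'   the planted footprint exceeds it), and `elements`, a list of element
#'   descriptors. Each descriptor is a list with `kind` in `"CRISPR"`,
#'   `"TANDEM"`, `"STAR"`, `"SIMPLE"`, `"CAS_LOCUS"` plus arguments for the
#'   corresponding `plant_*()` function; a CRISPR descriptor may add
#'   `cas_type` and `cas_distance` (default 200) to plant a companion locus.
#' @param seed Integer seed fixing all randomness.
#' @return A list: `genome` ([genome_record()]), `truth` (data.frame of
#'   planted elements with 1-based coordinates and labels), `cas` (cas-hit
#'   data.frame as from [read_cas_table()]).
#' @export
generate_genome <- function(spec, seed) {
  set.seed(seed)
  id <- spec$id %||% "synth"
  gc <- spec$gc %||% 0.5
  elements <- spec$elements %||% list()
  planted <- lapply(elements, function(el) {
    kind <- el$kind
    el$kind <- NULL
    companion <- NULL
    if (kind == "CRISPR" && !is.null(el$cas_type)) {
      companion <- list(type = el$cas_type,
                        distance = el$cas_distance %||% 200L)
      el$cas_type <- NULL
      el$cas_distance <- NULL
    }
    obj <- switch(kind,
                  CRISPR = do.call(plant_crispr, c(el, list(gc = gc))),
                  TANDEM = do.call(plant_tandem, c(el, list(gc = gc))),
                  STAR = do.call(plant_star, el),
                  SIMPLE = do.call(plant_simple, el),
                  CAS_LOCUS = do.call(plant_cas_locus, c(el, list(gc = gc))),
                  stop("unknown element kind: ", kind))
    if (!is.null(companion)) {
      companion$locus <- plant_cas_locus(companion$type, gc = gc)
      obj$companion <- companion
    }
    obj
  })
  # an element block includes any companion cas locus; blocks are separated
  # by background wide enough that no element falls inside the co-location
  # window of another block's cas genes
  block_len <- vapply(planted, function(p) {
    nchar(p$seq) + if (is.null(p$companion)) 0L else
      p$companion$distance - 1L + nchar(p$companion$locus$seq)
  }, 0L)
  sep <- max(2L * max(c(1L, block_len)),
             (spec$window_bp %||% 10000L) + 500L)
  parts <- character()
  truth <- list()
  cas <- .empty_cas_hits()
  at <- 0L
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    at <<- at + nchar(s)
  }
  add(.random_seq(sep, gc))
  for (p in planted) {
    start <- at + 1L
    add(p$seq)
    truth[[length(truth) + 1L]] <- data.frame(
      kind = p$kind, start = start, end = at,
      detail = switch(p$kind,
                      CRISPR = p$repeat_seq,
                      STAR = p$motif,
                      TANDEM = p$unit,
                      SIMPLE = p$base,
                      CAS_LOCUS = p$type),
      diversity = if (p$kind == "CRISPR") p$intended_diversity else NA,
      stringsAsFactors = FALSE)
    if (p$kind == "CAS_LOCUS") {
      cas <- rbind(cas, data.frame(
        genome_id = id, gene_start = start + p$genes$offset_start,
        gene_end = start + p$genes$offset_end, strand = p$genes$strand,
        family = p$genes$family, score = 100, source = "table",
        stringsAsFactors = FALSE))
    }
    if (!is.null(p$companion)) {
      add(.random_seq(p$companion$distance - 1L, gc))
      locus <- p$companion$locus
      lstart <- at + 1L
      add(locus$seq)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "CAS_LOCUS", start = lstart, end = at,
        detail = locus$type, diversity = NA, stringsAsFactors = FALSE)
      cas <- rbind(cas, data.frame(
        genome_id = id, gene_start = lstart + locus$genes$offset_start,
        gene_end = lstart + locus$genes$offset_end,
        strand = locus$genes$strand, family = locus$genes$family,
        score = 100, source = "table", stringsAsFactors = FALSE))
    }
    add(.random_seq(sep, gc))
  }
  seq <- paste(parts, collapse = "")
  if (!is.null(spec$length)) {
    if (nchar(seq) > spec$length)
      stop("planted elements exceed the requested genome length (",
           nchar(seq), " > ", spec$length, ")")
    if (nchar(seq) < spec$length)
      seq <- paste0(seq, .random_seq(spec$length - nchar(seq), gc))
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), start = integer(), end = integer(),
               detail = character(), diversity = character())
  list(genome = genome_record(id, seq), truth = truth, cas = cas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
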