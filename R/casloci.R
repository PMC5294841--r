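# Cas locus grouping, validation, typing, CRISPR/cas distances and
# co-location classification.

# Core genes: universal adaptation genes plus main interference components.
.CORE_FAMILIES <- c("cas1", "cas2", "cas5", "cas7", "cas8", "cas10",
                    "csf1", "cas9", "cpf1")

# Strip subtype suffixes so that e.g. cas8c counts as cas8 for the core rule.
.family_base <- function(family) {
  family <- tolower(family)
  vapply(family, function(f) {
    r <- regmatches(f, regexpr("^(cas[0-9]+|csf[0-9]|cpf1|csn2)", f))
    if (length(r)) r else f
  }, "", USE.NAMES = FALSE)
}

#' Default signature table: Cas family to CRISPR-Cas type
#'
#' Maps Cas family labels to the main type(s) they are diagnostic for: the
#' type signature genes (cas3 for I, cas9 for II, cas10 for III, csf1 for IV,
#' cpf1 for V) plus type-specific module subunits. Shipped as an editable TSV
#' (`signature_families.tsv` in the package `extdata`); users can load their
#' own with [read_signature_table()].
#'
#' @return A data.frame with columns `family`, `type`.
#' @export
default_signature_table <- function() {
  path <- system.file("extdata", "signature_families.tsv",
                      package = "crisprsieve", mustWork = TRUE)
  read_signature_table(path)
}

#' Read a signature table from TSV
#'
#' @param path TSV with columns `family` and `type` (one row per
#'   family/type pair; a family may map to several types).
#' @return A data.frame with lower-cased `family` and upper-cased `type`.
#' @export
read_signature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("family", "type") %in% names(tab)))
    stop("signature table needs columns 'family' and 'type': ", path)
  tab$family <- tolower(tab$family)
  tab$type <- toupper(tab$type)
  if (any(tab$family == "cpf1" & tab$type != "V"))
    stop("cpf1 must map to type V only")
  tab
}

#' Chain cas gene hits into candidate loci
#'
#' Consecutive hits on one genome record whose inter-gene distance
#' (`start2 - end1`) is at most `gap_bp` are chained into one candidate
#' locus spanning min start to max end.
#'
#' @param hits Cas-hit data.frame (one genome record), as from
#'   [read_cas_table()].
#' @param gap_bp Maximum intergenic gap in bp.
#' @return A list of candidate loci: `genome_id`, `start`, `end`, `genes`
#'   (the hit rows).
#' @export
group_cas_genes <- function(hits, gap_bp = 1000L) {
  if (!nrow(hits)) return(list())
  if (length(unique(hits$genome_id)) > 1L)
    stop("group_cas_genes expects hits from a single genome record")
  hits <- hits[order(hits$gene_start), , drop = FALSE]
  gap <- c(0L, hits$gene_start[-1] - hits$gene_end[-nrow(hits)])
  grp <- cumsum(gap > gap_bp)
  lapply(split(seq_len(nrow(hits)), grp), function(idx) {
    g <- hits[idx, , drop = FALSE]
    list(genome_id = g$genome_id[1], start = min(g$gene_start),
         end = max(g$gene_end), genes = g)
  })
}

#' Validate a candidate cas locus
#'
#' A valid locus contains at least `min_locus_genes` cas genes, at least one
#' of which is a universal adaptation gene (cas1/cas2) or a main interference
#' component (cas5, cas7, cas8, cas10, csf1, cas9, cpf1). Family matching is
#' case-insensitive and tolerant of subtype suffixes (cas8c counts as cas8).
#'
#' @param candidate A candidate from [group_cas_genes()].
#' @param config A [sieve_config()].
#' @return A list of class `cas_locus` on acceptance; otherwise a list of
#'   class `locus_rejection` with a `reason` field.
#' @export
validate_locus <- function(candidate, config = sieve_config()) {
  genes <- candidate$genes
  if (nrow(genes) < config$min_locus_genes) {
    return(structure(list(candidate = candidate,
                          reason = "fewer_than_min_genes"),
                     class = "locus_rejection"))
  }
  base <- .family_base(genes$family)
  if (!any(base %in% .CORE_FAMILIES)) {
    return(structure(list(candidate = candidate, reason = "no_core_gene"),
                     class = "locus_rejection"))
  }
  structure(list(genome_id = candidate$genome_id, start = candidate$start,
                 end = candidate$end, genes = genes,
                 type_call = "UNTYPED", confident = FALSE, ambiguous = FALSE,
                 has_cas1_cas2 = all(c("cas1", "cas2") %in% base)),
            class = "cas_locus")
}

#' @export
print.cas_locus <- function(x, ...) {
  cat(sprintf("<cas_locus> %s:%d-%d  %d genes  type %s%s\n", x$genome_id,
              x$start, x$end, nrow(x$genes), x$type_call,
              if (x$confident) " (confident)" else ""))
  invisible(x)
}

#' Assign a CRISPR-Cas type to a locus
#'
#' The candidate type is the one with most signature genes present in the
#' locus; the call is confident when that count reaches
#' `min_signature_genes`. cpf1 alone assigns a confident type V (the single
#' reported type-V signature gene). Loci with no signature gene are
#' `UNTYPED`; a tie between types yields `UNTYPED` with the ambiguity flag
#' set.
#'
#' @param locus A `cas_locus` from [validate_locus()].
#' @param table Signature table (family/type data.frame).
#' @param min_signature_genes Count needed for a confident call.
#' @return The locus with `type_call`, `confident` and `ambiguous` filled in.
#' @export
assign_type <- function(locus, table = default_signature_table(),
                        min_signature_genes = 3L) {
  stopifnot(inherits(locus, "cas_locus"))
  fams <- tolower(locus$genes$family)
  if ("cpf1" %in% .family_base(fams)) {
    locus$type_call <- "V"
    locus$confident <- TRUE
    return(locus)
  }
  counts <- vapply(c("I", "II", "III", "IV", "V"), function(tp) {
    sum(fams %in% table$family[table$type == tp])
  }, 0L)
  if (all(counts == 0L)) {
    locus$type_call <- "UNTYPED"
    return(locus)
  }
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    locus$type_call <- "UNTYPED"
    locus$ambiguous <- TRUE
    return(locus)
  }
  locus$type_call <- top
  locus$confident <- counts[[top]] >= min_signature_genes
  locus
}

# Inter-interval distance between [a1,a2] and [b1,b2]: 0 when they overlap,
# else the start-to-end difference of the later interval. With a circle
# length, the shorter way around is taken.
.interval_distance <- function(a1, a2, b1, b2, circle_len = NULL) {
  if (a1 <= b2 && b1 <= a2) return(0L)
  d <- if (b1 > a2) b1 - a2 else a1 - b2
  if (!is.null(circle_len)) {
    wrap <- if (b1 > a2) circle_len - b2 + a1 else circle_len - a2 + b1
    d <- min(d, max(wrap, 0L))
  }
  d
}

#' Distance between a CRISPR array and its nearest cas gene in a locus
#'
#' Minimum, over the locus genes, of the inter-interval distance
#' (`start2 - end1` between the later and the earlier interval; 0 when the
#' intervals overlap), in 1-based inclusive coordinates. On a circular
#' replicon (`circular = TRUE` with the replicon length supplied) the
#' shorter way around the circle is taken.
#'
#' @param array A [crispr_array()].
#' @param locus A `cas_locus`.
#' @param genome_length Replicon length in bp (needed for `circular`).
#' @param circular Treat the replicon as circular.
#' @return Distance in bp.
#' @export
crispr_cas_distance <- function(array, locus, genome_length = NULL,
                                circular = FALSE) {
  if (array$genome_id != locus$genome_id)
    stop("array and locus are on different genome records")
  circle <- if (circular && !is.null(genome_length)) genome_length else NULL
  min(vapply(seq_len(nrow(locus$genes)), function(i) {
    .interval_distance(array$start, array$end,
                       locus$genes$gene_start[i], locus$genes$gene_end[i],
                       circle)
  }, 0L))
}

#' Classify CRISPR/cas co-location for one genome (assembly)
#'
#' Each validated locus and each array is labelled `CO_LOCATED` (partner
#' within `window_bp` on the same record), `ISOLATED_REMOTE` (a partner
#' exists in the genome but beyond the window or on another record of the
#' same assembly), or `ORPHAN` (no partner anywhere in the genome).
#'
#' @param arrays List of [crispr_array()] of one assembly.
#' @param loci List of `cas_locus` of the same assembly.
#' @param config A [sieve_config()]; its `circular` flag enables
#'   wrap-around distances when `genome_lengths` is given.
#' @param genome_lengths Optional named vector of replicon lengths, for
#'   circular distance computation.
#' @return A list with data.frames `arrays` (`idx`, `label`, `nearest_bp`),
#'   `loci` (`idx`, `label`, `nearest_bp`) and `pairs` (`array_idx`,
#'   `locus_idx`, `bp`; same-record pairs only).
#' @export
classify_colocation <- function(arrays, loci, config = sieve_config(),
                                genome_lengths = NULL) {
  na <- length(arrays); nl <- length(loci)
  pairs <- data.frame(array_idx = integer(), locus_idx = integer(),
                      bp = numeric())
  if (na && nl) {
    for (i in seq_len(na)) for (j in seq_len(nl)) {
      if (arrays[[i]]$genome_id != loci[[j]]$genome_id) next
      glen <- if (!is.null(genome_lengths))
        genome_lengths[[arrays[[i]]$genome_id]] else NULL
      pairs <- rbind(pairs, data.frame(
        array_idx = i, locus_idx = j,
        bp = crispr_cas_distance(arrays[[i]], loci[[j]], glen,
                                 config$circular)))
    }
  }
  label_for <- function(has_partner, nearest) {
    if (!has_partner) "ORPHAN"
    else if (is.finite(nearest) && nearest <= config$window_bp) "CO_LOCATED"
    else "ISOLATED_REMOTE"
  }
  arr_near <- vapply(seq_len(na), function(i) {
    d <- pairs$bp[pairs$array_idx == i]
    if (length(d)) min(d) else Inf
  }, 0)
  loc_near <- vapply(seq_len(nl), function(j) {
    d <- pairs$bp[pairs$locus_idx == j]
    if (length(d)) min(d) else Inf
  }, 0)
  list(
    arrays = data.frame(
      idx = seq_len(na),
      label = vapply(seq_len(na), function(i) label_for(nl > 0, arr_near[i]), ""),
      nearest_bp = arr_near),
    loci = data.frame(
      idx = seq_len(nl),
      label = vapply(seq_len(nl), function(j) label_for(na > 0, loc_near[j]), ""),
      nearest_bp = loc_near),
    pairs = pairs)
}

#' Adaptation-module matrix over a set of annotated genomes
#'
#' For each typed locus: is a CRISPR co-located (within the window), does the
#' locus neighbourhood carry the cas1-cas2 adaptation pair, and -- only when
#' the nearby pair is absent -- does a remote cas1-cas2 pair exist elsewhere
#' in the genome. Counts per type over the categories
#' `{CRISPR +/-} x {nearby pair +, remote pair +, remote pair -}`.
#'
#' @param annotations A list with one element per assembly: `loci` (list of
#'   typed `cas_locus`), `colocation` (from [classify_colocation()]) and
#'   `hits` (all cas hits of the assembly).
#' @return A data.frame with columns `type`, `crispr`, `nearby_pair`,
#'   `remote_pair`, `n`; per type the `n` column sums to the number of typed
#'   loci of that type.
#' @export
adaptation_matrix <- function(annotations) {
  rows <- list()
  for (ann in annotations) {
    loci <- ann$loci
    if (!length(loci)) next
    coloc <- ann$colocation$loci
    base_all <- .family_base(ann$hits$family)
    for (j in seq_along(loci)) {
      locus <- loci[[j]]
      if (locus$type_call == "UNTYPED") next
      crispr <- if (coloc$label[j] == "CO_LOCATED") "+" else "-"
      base_locus <- .family_base(locus$genes$family)
      nearby <- all(c("cas1", "cas2") %in% base_locus)
      if (nearby) {
        remote <- ""  # not checked when a nearby pair exists
      } else {
        in_locus <- ann$hits$genome_id == locus$genome_id &
          ann$hits$gene_start >= locus$start & ann$hits$gene_end <= locus$end
        outside <- base_all[!in_locus]
        remote <- if (all(c("cas1", "cas2") %in% outside)) "+" else "-"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        type = locus$type_call, crispr = crispr,
        nearby_pair = if (nearby) "+" else "-", remote_pair = remote,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(), crispr = character(),
                      nearby_pair = character(), remote_pair = character(),
                      n = integer()))
  }
  all_rows <- do.call(rbind, rows)
  stats::aggregate(list(n = rep(1L, nrow(all_rows))),
                   all_rows[c("type", "crispr", "nearby_pair", "remote_pair")],
                   FUN = sum)
}

#' Compare CRISPR-cas distance distributions between system types
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every pair of
#' distance lists, with per-list medians.
#'
#' @param dist_lists Named list (>= 2 elements) of numeric distance vectors.
#' @return A list with `medians` (named numeric) and `tests` (data.frame
#'   `a`, `b`, `p_value`).
#' @export
compare_distance_distributions <- function(dist_lists) {
  if (length(dist_lists) < 2L)
    stop("need at least two distance lists")
  if (any(!lengths(dist_lists)))
    stop("empty distance list")
  nms <- names(dist_lists)
  if (is.null(nms)) nms <- as.character(seq_along(dist_lists))
  medians <- vapply(dist_lists, stats::median, 0)
  names(medians) <- nms
  combs <- utils::combn(seq_along(dist_lists), 2)
  tests <- data.frame(a = nms[combs[1, ]], b = nms[combs[2, ]],
                      p_value = apply(combs, 2, function(ij) {
                        suppressWarnings(stats::wilcox.test(
                          dist_lists[[ij[1]]], dist_lists[[ij[2]]],
                          alternative = "two.sided"))$p.value
                      }), stringsAsFactors = FALSE)
  list(medians = medians, tests = tests)
}
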