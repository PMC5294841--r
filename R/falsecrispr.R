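# Separation of real CRISPRs from CRISPR-mimicking elements, and
# classification of the false ones into tandem repeats, STAR-like elements,
# simple repeats and unknown.

# STAR signature: T[G/A/T]TGTTG[G/T]GGCCC[C/A], one allowed base set per
# motif position. Built programmatically so the reverse-complement pattern
# cannot drift out of sync.
.STAR_SETS <- list("T", c("G", "A", "T"), "T", "G", "T", "T", "G",
                   c("G", "T"), "G", "G", "C", "C", "C", c("C", "A"))

.sets_regex <- function(sets) {
  paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

.sets_revcomp <- function(sets) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(lapply(sets, function(s) unname(comp[s])))
}

#' Enumerate all instantiations of the STAR signature motif
#'
#' @return Character vector of the concrete 14-mers matching
#'   `T[G/A/T]TGTTG[G/T]GGCCC[C/A]` (12 strings).
#' @export
star_motif_instances <- function() {
  grid <- expand.grid(.STAR_SETS, stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = "")
}

#' Scan a sequence for the STAR signature motif
#'
#' Matches the 14-position degenerate STAR signature on both strands
#' (reverse-complement hits are reported at their forward-strand start).
#' Overlapping hits are all reported.
#'
#' @param sequence Nucleotide string.
#' @return A data.frame with columns `start` (1-based) and `strand`.
#' @export
match_star <- function(sequence) {
  sequence <- toupper(sequence)
  scan1 <- function(pattern, strand) {
    m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
    pos <- as.integer(m)
    pos <- pos[pos > 0]
    if (!length(pos)) return(NULL)
    data.frame(start = pos, strand = strand, stringsAsFactors = FALSE)
  }
  out <- rbind(scan1(.sets_regex(.STAR_SETS), "+"),
               scan1(.sets_regex(.sets_revcomp(.STAR_SETS)), "-"))
  if (is.null(out))
    out <- data.frame(start = integer(), strand = character())
  out[order(out$start), , drop = FALSE]
}

#' Detect a tandem repeat in a region
#'
#' Tandem Repeat Finder style scorer: candidate periods come from the
#' distance histogram of repeated k-mers (short periods are always tried);
#' for each candidate period the region is aligned against cyclic copies of
#' each candidate unit by local wraparound dynamic programming with weights
#' match +2 / mismatch -7 / indel -7. The alignment start inside the unit is
#' free, so the score is invariant under unit rotation. A call is positive
#' when the best score reaches `min_score`, the aligned segment covers
#' `min_coverage` of the region, and at least two unit copies are covered.
#'
#' @param region Nucleotide string (array span, optionally with flanks).
#' @param min_score Minimum alignment score (default 50).
#' @param min_coverage Minimum covered fraction of the region (default 0.8).
#' @param periods Optional integer vector overriding period candidates.
#' @param max_phases Cap on distinct unit phases evaluated per period.
#' @return A list of class `tandem_call` (`period`, `unit`, `copies`,
#'   `coverage`, `score`, `start`, `end`) or `NULL`.
#' @export
detect_tandem <- function(region, min_score = 50, min_coverage = 0.8,
                          periods = NULL, max_phases = 64L) {
  region <- toupper(region)
  n <- nchar(region)
  if (n < 2L) return(NULL)
  if (is.null(periods)) {
    periods <- .tandem_period_candidates(region)
  }
  periods <- sort(unique(periods[periods >= 1L & periods <= n %/% 2L]))
  if (!length(periods)) return(NULL)
  best <- NULL
  for (p in periods) {
    phases <- seq_len(min(p, n - p + 1L, max_phases))
    units <- unique(substring(region, phases, phases + p - 1L))
    for (u in units) {
      a <- wdp_align(region, u)
      if (is.null(best) || a$score > best$score) {
        best <- list(period = p, unit = u, score = a$score,
                     start = a$start, end = a$end)
      }
    }
  }
  covered <- best$end - best$start + 1L
  if (covered < 1L) return(NULL)
  call <- structure(list(period = best$period, unit = best$unit,
                         copies = covered / best$period,
                         coverage = covered / n,
                         score = best$score,
                         start = best$start, end = best$end),
                    class = "tandem_call")
  if (call$score >= min_score && call$coverage >= min_coverage &&
      call$copies >= 2)
    call
  else
    NULL
}

# Period candidates: distances between consecutive occurrences of identical
# 4-mers, most frequent first (capped), plus all short periods.
.tandem_period_candidates <- function(region, k = 4L, cap = 24L) {
  n <- nchar(region)
  short <- 1:8
  if (n <= k) return(short)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(region, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  d <- unlist(lapply(occ, function(x) if (length(x) > 1L) diff(x)), use.names = FALSE)
  d <- d[d <= n %/% 2L]
  if (!length(d)) return(short)
  tab <- sort(table(d), decreasing = TRUE)
  c(short, as.integer(names(tab))[seq_len(min(cap, length(tab)))])
}

#' @export
print.tandem_call <- function(x, ...) {
  cat(sprintf("<tandem_call> period %d  %.1f copies  coverage %.2f  score %g\n",
              x$period, x$copies, x$coverage, x$score))
  invisible(x)
}

#' Detect a simple / low-complexity repeat in a region
#'
#' Positive when (a) a single nucleotide reaches `mono_frac` of the region,
#' (b) a tandem unit of at most `max_unit` bp covers at least 80% of the
#' region, or (c) the Shannon entropy of the mononucleotide composition
#' drops to `entropy_max` bits. The mononucleotide criterion is checked
#' first (a homopolymer run is better described by its base bias than as a
#' period-1 tandem); the triggering criterion is recorded.
#'
#' @param region Nucleotide string.
#' @param max_unit Maximum simple-repeat unit length (default 6).
#' @param mono_frac Mononucleotide frequency trigger (default 0.40).
#' @param entropy_max Entropy trigger in bits (default 1.5).
#' @param min_score Score floor passed to [detect_tandem()].
#' @return A list of class `simple_call` (`trigger`, plus `unit`, `copies`
#'   for trigger `"tandem_unit"`, `base`, `frac` for `"mono_frac"`,
#'   `entropy` for `"entropy"`) or `NULL`.
#' @export
detect_simple <- function(region, max_unit = 6L, mono_frac = 0.40,
                          entropy_max = 1.5, min_score = 50) {
  region <- toupper(region)
  f <- .base_freqs(region)
  if (max(f) >= mono_frac) {
    return(structure(list(trigger = "mono_frac",
                          base = names(f)[which.max(f)], frac = max(f)),
                     class = "simple_call"))
  }
  tc <- detect_tandem(region, min_score = min_score, min_coverage = 0.8,
                      periods = seq_len(max_unit))
  if (!is.null(tc)) {
    return(structure(list(trigger = "tandem_unit", unit = tc$unit,
                          copies = tc$copies, coverage = tc$coverage),
                     class = "simple_call"))
  }
  h <- .mono_entropy(region)
  if (h <= entropy_max) {
    return(structure(list(trigger = "entropy", entropy = h),
                     class = "simple_call"))
  }
  NULL
}

#' Rescue distance of a candidate repeat against real repeats
#'
#' Minimum mismatch count between the candidate and any real CRISPR repeat,
#' under the best ungapped end-free alignment; unaligned overhang and the
#' length difference count as mismatches (Hamming distance for equal-length
#' sequences). A candidate within `rescue_mismatch_limit` mismatches of a
#' real repeat is considered a real CRISPR repeat.
#'
#' @param candidate_repeat Candidate consensus repeat.
#' @param real_repeats Character vector of real consensus repeats (possibly
#'   empty).
#' @return Minimum mismatch count, or `Inf` for an empty real set.
#' @export
rescue_distance <- function(candidate_repeat, real_repeats) {
  if (!length(real_repeats)) return(Inf)
  min(vapply(real_repeats, function(r) {
    .endfree_mismatches(toupper(candidate_repeat), toupper(r))
  }, 0))
}

#' Partition repeat clusters into real and candidate-false
#'
#' A cluster is real when at least one member array is co-located with a
#' valid cas locus; all members inherit the real label. The remaining
#' clusters carry their evidence class per member (cas genes far in the
#' genome vs absent from it).
#'
#' @param clusters List of `repeat_cluster` (members named by array id).
#' @param array_info data.frame with columns `array_id` and `colocation`
#'   (`CO_LOCATED` / `ISOLATED_REMOTE` / `ORPHAN` per array).
#' @return A list with `real` and `candidate` (lists of clusters) and
#'   `real_repeats` (representatives plus member consensuses of real
#'   clusters, if `array_info` has a `consensus` column).
#' @export
find_real_clusters <- function(clusters, array_info) {
  is_real <- vapply(clusters, function(cl) {
    lab <- array_info$colocation[match(cl$members, array_info$array_id)]
    any(lab == "CO_LOCATED", na.rm = TRUE)
  }, TRUE)
  real <- clusters[is_real]
  real_repeats <- vapply(real, `[[`, "", "representative")
  if (!is.null(array_info$consensus)) {
    member_ids <- unlist(lapply(real, `[[`, "members"))
    real_repeats <- unique(c(real_repeats,
                             array_info$consensus[
                               match(member_ids, array_info$array_id)]))
  }
  list(real = real, candidate = clusters[!is_real],
       real_repeats = unname(real_repeats))
}

#' Classify one putative array
#'
#' The sieve's final verdict. An array is `REAL` when its repeat cluster has
#' a cas-co-located member or its consensus lies within the rescue mismatch
#' limit of a real repeat (with `strict_diversity`, rescue is withheld from
#' cas-absent, non-diverse clusters). False elements cascade through the
#' configured detector precedence (default STAR, then TANDEM, then SIMPLE);
#' a tandem call whose unit is short enough to be a simple repeat
#' (`simple_max_unit`) is left to the simple detector. Evidence fields are
#' populated for every outcome.
#'
#' @param array A [crispr_array()].
#' @param region The array's genomic sequence (span slice).
#' @param cluster_real Logical: does the array's cluster contain a
#'   cas-co-located member.
#' @param real_repeats Character vector of real consensus repeats.
#' @param colocation The array's own co-location label.
#' @param diversity The array's `diversity_call`.
#' @param config A [sieve_config()].
#' @return A list of class `element_classification`: `label` (`REAL`,
#'   `TANDEM`, `STAR`, `SIMPLE`, `UNKNOWN`) and `evidence`.
#' @export
classify_element <- function(array, region, cluster_real, real_repeats,
                             colocation, diversity,
                             config = sieve_config()) {
  rd <- rescue_distance(array$consensus_repeat, real_repeats)
  evidence <- list(
    cas_near = colocation == "CO_LOCATED",
    cas_far_in_genome = colocation == "ISOLATED_REMOTE",
    cas_absent = colocation == "ORPHAN",
    diversity_status = diversity$status,
    rescue_distance = rd,
    tandem_call = NULL, star_hits = NA_integer_, simple_call = NULL)
  rescued <- rd < config$rescue_mismatch_limit
  if (config$strict_diversity && evidence$cas_absent &&
      diversity$status != "DIVERSE" && !cluster_real)
    rescued <- FALSE
  if (cluster_real || rescued) {
    .log_debug("classify %s:%d-%d -> REAL (%s; rescue %g)",
               array$genome_id, array$start, array$end,
               if (cluster_real) "cluster cas-near" else "mismatch rescue",
               rd)
    return(structure(list(label = "REAL", evidence = evidence),
                     class = "element_classification"))
  }
  star <- match_star(region)
  if (!nrow(star)) star <- match_star(array$consensus_repeat)
  evidence$star_hits <- nrow(star)
  tc <- detect_tandem(region, min_score = config$tandem_min_score,
                      min_coverage = config$tandem_min_coverage)
  evidence$tandem_call <- tc
  sc <- detect_simple(region, max_unit = config$simple_max_unit,
                      mono_frac = config$mono_frac,
                      entropy_max = config$entropy_max,
                      min_score = config$tandem_min_score)
  evidence$simple_call <- sc
  label <- "UNKNOWN"
  for (det in config$precedence) {
    # a tandem unit that is itself low-complexity (short, or dominated by
    # one base) is a simple repeat, not a tandem repeat
    hit <- switch(det,
                  STAR = nrow(star) > 0L,
                  TANDEM = !is.null(tc) &&
                    tc$period > config$simple_max_unit &&
                    .mono_entropy(tc$unit) > config$entropy_max,
                  SIMPLE = !is.null(sc))
    if (hit) { label <- det; break }
  }
  .log_debug("classify %s:%d-%d -> %s (star %d, tandem %s, rescue %g)",
             array$genome_id, array$start, array$end, label,
             nrow(star), if (is.null(tc)) "none" else tc$period, rd)
  structure(list(label = label, evidence = evidence),
            class = "element_classification")
}
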