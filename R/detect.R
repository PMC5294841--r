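# CRT-style CRISPR array detection: exact seed k-mers recurring at
# admissible spacings are chained, then extended column-by-column across all
# copies while the copies keep agreeing.

# All maximal chains of seed positions whose consecutive gaps lie in
# [pmin, pmax]. Enumerates branches by depth-first search; when the position
# list is dense (low-complexity regions) the branch count explodes, so past
# `cap` chains we fall back to greedy nearest-successor chaining, which is
# deterministic and keeps one chain per start.
.seed_chains <- function(pos, pmin, pmax, min_count, cap = 256L) {
  pos <- sort(pos)
  np <- length(pos)
  succ <- lapply(seq_len(np), function(i) {
    which(pos - pos[i] >= pmin & pos - pos[i] <= pmax)
  })
  has_pred <- logical(np)
  for (i in seq_len(np)) has_pred[succ[[i]]] <- TRUE
  chains <- list()
  overflow <- FALSE
  dfs <- function(path) {
    if (overflow) return()
    nxt <- succ[[path[length(path)]]]
    if (!length(nxt)) {
      if (length(path) >= min_count) {
        if (length(chains) >= cap) { overflow <<- TRUE; return() }
        chains[[length(chains) + 1L]] <<- pos[path]
      }
      return()
    }
    for (q in nxt) dfs(c(path, q))
  }
  for (i in which(!has_pred)) dfs(i)
  if (overflow) {
    # greedy fallback: nearest admissible successor, each position used once
    chains <- list()
    used <- logical(np)
    for (i in seq_len(np)) {
      if (used[i]) next
      path <- i
      used[i] <- TRUE
      repeat {
        nxt <- succ[[path[length(path)]]]
        nxt <- nxt[!used[nxt]]
        if (!length(nxt)) break
        used[nxt[1]] <- TRUE
        path <- c(path, nxt[1])
      }
      if (length(path) >= min_count)
        chains[[length(chains) + 1L]] <- pos[path]
    }
  }
  chains
}

# Extend a seed chain into repeat windows. `starts` are seed start positions
# (one per copy, same offset in every copy), `k` the seed length. Extension
# adds one column at a time on the side where at least 75% of copies match
# the column majority, until the repeat-length cap, the spacer floor, or the
# sequence boundary stops it. Returns candidate list(s) after validating
# per-copy mismatch fractions and spacer bounds (violations split the chain).
.extend_seed_chain <- function(chars, starts, params) {
  n <- length(chars)
  k <- params$seed_kmer
  m <- length(starts)
  d <- diff(starts)
  width_cap <- min(params$max_repeat_len,
                   if (length(d)) min(d) - params$min_spacer_len else Inf)
  if (width_cap < params$min_repeat_len) return(list())
  l <- 0L; r <- 0L
  bases <- c("A", "C", "G", "T")
  col_agree <- function(idx) {
    if (idx[1] < 1L || idx[length(idx)] > n) return(-1)
    counts <- tabulate(match(chars[idx], bases), 4L)
    if (!sum(counts)) return(-1)
    max(counts) / m
  }
  repeat {
    if (k + l + r >= width_cap) break
    la <- col_agree(starts - l - 1L)
    ra <- col_agree(starts + k + r)
    pick <- if (ra >= la && ra >= 0.75) "r" else if (la >= 0.75) "l" else ""
    if (pick == "") break
    if (pick == "r") r <- r + 1L else l <- l + 1L
  }
  width <- k + l + r
  if (width < params$min_repeat_len) return(list())
  rep_starts <- starts - l
  .chain_candidates(chars, rep_starts, width, params)
}

# Validate copy fidelity and spacer bounds; split the chain at violations
# and keep sub-chains with enough copies.
.chain_candidates <- function(chars, rep_starts, width, params) {
  m <- length(rep_starts)
  seqs <- vapply(rep_starts, function(s) {
    paste(chars[s:(s + width - 1L)], collapse = "")
  }, "")
  cons <- consensus_repeat(seqs)
  consc <- .seq_chars(cons)
  ok_copy <- vapply(seq_len(m), function(i) {
    ch <- .seq_chars(seqs[i])
    mism <- sum(ch != consc | ch == "N")
    mism <= params$max_repeat_mismatch_frac * width
  }, TRUE)
  gaps <- diff(rep_starts) - width
  ok_gap <- gaps >= params$min_spacer_len & gaps <= params$max_spacer_len
  # break points: after copy i if gap i invalid; copies failing fidelity
  # are dropped entirely
  runs <- list()
  cur <- integer()
  for (i in seq_len(m)) {
    if (!ok_copy[i]) {
      if (length(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- integer()
      next
    }
    cur <- c(cur, i)
    if (i < m && !ok_gap[i]) {
      runs[[length(runs) + 1L]] <- cur
      cur <- integer()
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(x) length(x) >= params$min_repeat_count, runs)
  lapply(runs, function(idx) {
    list(starts = rep_starts[idx], width = width)
  })
}

# Keep-the-best resolution of overlapping candidates: more repeats, then
# longer span, then smaller start.
.resolve_overlaps <- function(cands) {
  if (!length(cands)) return(cands)
  starts <- vapply(cands, function(c) c$starts[1], 0)
  ends <- vapply(cands, function(c) c$starts[length(c$starts)] + c$width - 1L, 0)
  nreps <- vapply(cands, function(c) length(c$starts), 0L)
  span <- ends - starts
  ord <- order(-nreps, -span, starts)
  kept <- integer()
  for (i in ord) {
    clash <- any(starts[kept] <= ends[i] & ends[kept] >= starts[i])
    if (!clash) kept <- c(kept, i)
  }
  cands[kept[order(starts[kept])]]
}

.candidate_to_array <- function(genome, cand) {
  w <- cand$width
  rs <- cand$starts
  repeats <- data.frame(start = rs, end = rs + w - 1L,
                        seq = substring(genome$seq, rs, rs + w - 1L),
                        partial = FALSE, stringsAsFactors = FALSE)
  if (length(rs) > 1L) {
    ss <- rs[-length(rs)] + w
    se <- rs[-1] - 1L
    spacers <- data.frame(start = ss, end = se,
                          seq = substring(genome$seq, ss, se),
                          stringsAsFactors = FALSE)
  } else {
    spacers <- NULL
  }
  crispr_array(genome$id, repeats, spacers)
}

#' Find CRISPR-like repeat-spacer arrays in a genome
#'
#' CRT-style scan: exact `seed_kmer` words recurring at spacings compatible
#' with one repeat plus one spacer are chained, each chain is extended across
#' all copies while at least 75% of copies agree on the flanking column, and
#' the result is validated against the repeat/spacer length bounds and the
#' per-copy mismatch tolerance. Overlapping candidates are resolved in favour
#' of more repeats, then longer span, then smaller start. Deterministic for a
#' fixed input and parameter set.
#'
#' @param genome A [genome_record()].
#' @param params A [detector_params()] object.
#' @return A list of [crispr_array()] objects sorted by start (possibly
#'   empty).
#' @export
find_arrays <- function(genome, params = detector_params()) {
  stopifnot(inherits(genome, "genome_record"))
  n <- genome$length
  footprint <- params$min_repeat_count * params$min_repeat_len +
    (params$min_repeat_count - 1L) * params$min_spacer_len
  if (n < footprint) return(list())
  k <- params$seed_kmer
  pmin <- params$min_repeat_len + params$min_spacer_len
  pmax <- params$max_repeat_len + params$max_spacer_len
  starts <- seq_len(n - k + 1L)
  kmers <- substring(genome$seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  occ <- split(starts[keep], kmers[keep])
  occ <- occ[lengths(occ) >= params$min_repeat_count]
  chars <- .seq_chars(genome$seq)
  cands <- list()
  for (pos in occ) {
    for (chain in .seed_chains(pos, pmin, pmax, params$min_repeat_count)) {
      for (cand in .extend_seed_chain(chars, chain, params))
        cands[[length(cands) + 1L]] <- cand
    }
  }
  cands <- .resolve_overlaps(cands)
  lapply(cands, function(c) .candidate_to_array(genome, c))
}

#' Extend partial terminal repeats of an array
#'
#' CRT reports only full repeat copies; a truncated copy of the consensus
#' often sits one spacer beyond either end of the reported array. If at least
#' `partial_min_match` of the consensus matches immediately beyond a terminal
#' repeat (after a spacer-length gap, at the array-level mismatch rate), the
#' boundary is extended over the partial copy and the corresponding terminal
#' flag is set.
#'
#' @param array A [crispr_array()].
#' @param genome The carrying [genome_record()].
#' @param params A [detector_params()] object.
#' @return The (possibly extended) array.
#' @export
extend_partial_repeats <- function(array, genome, params = detector_params()) {
  cons <- array$consensus_repeat
  L <- nchar(cons)
  consc <- .seq_chars(cons)
  chars <- .seq_chars(genome$seq)
  tmin <- ceiling(params$partial_min_match * L)
  med_sp <- if (nrow(array$spacers))
    stats::median(array$spacers$end - array$spacers$start + 1L) else
    params$min_spacer_len
  # For each admissible spacer gap, score partial lengths t by
  # matches - 3*mismatches (so random continuation beyond the true partial
  # is penalised) and keep the best-scoring candidate that matches at least
  # partial_min_match of the consensus within the mismatch tolerance.
  scan_side <- function(side) {
    best <- NULL
    for (g in params$min_spacer_len:params$max_spacer_len) {
      if (side == "3") {
        s0 <- array$end + g + 1L
        tmax <- min(L, genome$length - s0 + 1L)
        if (tmax < tmin) next
        seg <- chars[s0:(s0 + tmax - 1L)]
        ref <- consc[1:tmax]           # truncated at the repeat's end
      } else {
        e0 <- array$start - g - 1L
        tmax <- min(L, e0)
        if (tmax < tmin) next
        seg <- rev(chars[(e0 - tmax + 1L):e0])
        ref <- rev(consc)[1:tmax]      # truncated at the repeat's start
      }
      m_cum <- cumsum(seg == ref & seg != "N")
      for (t in tmin:tmax) {
        mism <- t - m_cum[t]
        if (mism > params$max_repeat_mismatch_frac * t) next
        if (m_cum[t] < tmin) next
        score <- m_cum[t] - 3L * mism
        cand <- list(gap = g, t = t, score = score)
        if (is.null(best) || score > best$score ||
            (score == best$score &&
             abs(g - med_sp) < abs(best$gap - med_sp)))
          best <- cand
      }
    }
    if (is.null(best)) return(NULL)
    if (side == "3") {
      best$start <- array$end + best$gap + 1L
      best$end <- best$start + best$t - 1L
    } else {
      best$end <- array$start - best$gap - 1L
      best$start <- best$end - best$t + 1L
    }
    best
  }
  for (side in c("5", "3")) {
    if (array$partial_terminal[[side]]) next
    hit <- scan_side(side)
    if (is.null(hit)) next
    if (side == "3") {
      sp <- data.frame(start = array$end + 1L, end = hit$start - 1L,
                       seq = substring(genome$seq, array$end + 1L,
                                       hit$start - 1L),
                       stringsAsFactors = FALSE)
    } else {
      sp <- data.frame(start = hit$end + 1L, end = array$start - 1L,
                       seq = substring(genome$seq, hit$end + 1L,
                                       array$start - 1L),
                       stringsAsFactors = FALSE)
    }
    rep_row <- data.frame(start = hit$start, end = hit$end,
                          seq = substring(genome$seq, hit$start, hit$end),
                          partial = hit$t < L, stringsAsFactors = FALSE)
    array <- crispr_array(array$genome_id,
                          rbind(array$repeats, rep_row),
                          rbind(array$spacers, sp),
                          consensus = array$consensus_repeat,
                          notes = array$notes)
  }
  array
}

#' Merge adjacent arrays that belong to one locus
#'
#' A long CRISPR is sometimes split by the detector at a degenerate repeat or
#' an oversized spacer. Arrays separated by at most `merge_gap_bp`
#' (inter-interval distance, `start2 - end1`) whose consensus repeats share
#' at least `repeat_cluster_identity` are unioned; the gap becomes a spacer
#' when its length is spacer-compatible, otherwise it is retained as an
#' annotated insertion. Applied to transitive closure; idempotent.
#'
#' @param arrays List of [crispr_array()] on one genome, any order.
#' @param genome The carrying [genome_record()].
#' @param config A [sieve_config()].
#' @return A sorted list of merged arrays.
#' @export
merge_arrays <- function(arrays, genome, config = sieve_config()) {
  if (length(arrays) <= 1L) return(arrays)
  arrays <- arrays[order(vapply(arrays, `[[`, 0, "start"))]
  repeat {
    merged <- FALSE
    out <- list(arrays[[1]])
    for (i in seq_along(arrays)[-1]) {
      cur <- out[[length(out)]]
      nxt <- arrays[[i]]
      gap <- nxt$start - cur$end
      if (gap <= config$merge_gap_bp && gap >= 1L &&
          pairwise_identity(cur$consensus_repeat, nxt$consensus_repeat) >=
            config$repeat_cluster_identity) {
        out[[length(out)]] <- .merge_pair(cur, nxt, genome, config)
        merged <- TRUE
      } else {
        out[[length(out) + 1L]] <- nxt
      }
    }
    arrays <- out
    if (!merged) break
  }
  arrays
}

.merge_pair <- function(a, b, genome, config) {
  .log_debug("merge %s:%d-%d + %d-%d (gap %d)", a$genome_id, a$start,
             a$end, b$start, b$end, b$start - a$end)
  gap_len <- b$start - a$end - 1L
  notes <- c(a$notes, b$notes)
  spacers <- rbind(a$spacers, b$spacers)
  if (gap_len >= 1L) {
    gap <- data.frame(start = a$end + 1L, end = b$start - 1L,
                      seq = substring(genome$seq, a$end + 1L, b$start - 1L),
                      stringsAsFactors = FALSE)
    det <- config$detector
    if (gap_len < det$min_spacer_len || gap_len > det$max_spacer_len)
      notes <- c(notes, sprintf("merge_gap_insertion:%d", gap_len))
    spacers <- rbind(spacers, gap)
  } else {
    notes <- c(notes, "merge_gap_empty")
  }
  crispr_array(a$genome_id, rbind(a$repeats, b$repeats), spacers,
               notes = notes)
}
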