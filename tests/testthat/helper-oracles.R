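# Independent oracle implementations, written as straight-line loops from
# the documented rules, used to cross-check the package's optimised code
# paths.

# ---- array detection oracle --------------------------------------------

oracle_consensus <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2, function(col) {
    counts <- c(A = sum(col == "A"), C = sum(col == "C"),
                G = sum(col == "G"), T = sum(col == "T"),
                N = sum(col == "N"))
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) top else col[col %in% top][1]
  }), collapse = "")
}

oracle_extend_chain <- function(chars, starts, params) {
  n <- length(chars)
  k <- params$seed_kmer
  m <- length(starts)
  gaps <- diff(starts)
  cap <- min(params$max_repeat_len,
             if (length(gaps)) min(gaps) - params$min_spacer_len else Inf)
  if (cap < params$min_repeat_len) return(list())
  agree <- function(idx) {
    if (min(idx) < 1 || max(idx) > n) return(-1)
    col <- chars[idx]
    counts <- c(sum(col == "A"), sum(col == "C"),
                sum(col == "G"), sum(col == "T"))
    if (sum(counts) == 0) return(-1)
    max(counts) / m
  }
  l <- 0; r <- 0
  repeat {
    if (k + l + r >= cap) break
    la <- agree(starts - l - 1)
    ra <- agree(starts + k + r)
    if (ra >= la && ra >= 0.75) r <- r + 1
    else if (la >= 0.75) l <- l + 1
    else break
  }
  width <- k + l + r
  if (width < params$min_repeat_len) return(list())
  rs <- starts - l
  seqs <- vapply(rs, function(p) paste(chars[p:(p + width - 1)], collapse = ""), "")
  cons <- strsplit(oracle_consensus(seqs), "")[[1]]
  ok_copy <- logical(m)
  for (i in 1:m) {
    ch <- strsplit(seqs[i], "")[[1]]
    ok_copy[i] <- sum(ch != cons | ch == "N") <=
      params$max_repeat_mismatch_frac * width
  }
  g2 <- diff(rs) - width
  ok_gap <- g2 >= params$min_spacer_len & g2 <= params$max_spacer_len
  runs <- list(); cur <- integer()
  for (i in 1:m) {
    if (!ok_copy[i]) {
      if (length(cur)) runs[[length(runs) + 1]] <- cur
      cur <- integer(); next
    }
    cur <- c(cur, i)
    if (i < m && !ok_gap[i]) { runs[[length(runs) + 1]] <- cur; cur <- integer() }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  out <- list()
  for (idx in runs) {
    if (length(idx) >= params$min_repeat_count)
      out[[length(out) + 1]] <- list(starts = rs[idx], width = width)
  }
  out
}

# Exhaustive seed-chain enumeration plus extension; returns a data.frame of
# array spans after overlap resolution.
oracle_find_arrays <- function(genome, params = detector_params()) {
  s <- genome$seq; n <- nchar(s)
  k <- params$seed_kmer
  minc <- params$min_repeat_count
  empty <- data.frame(start = integer(), end = integer(),
                      n_repeats = integer())
  footprint <- minc * params$min_repeat_len +
    (minc - 1) * params$min_spacer_len
  if (n < footprint) return(empty)
  chars <- strsplit(s, "")[[1]]
  pmin <- params$min_repeat_len + params$min_spacer_len
  pmax <- params$max_repeat_len + params$max_spacer_len
  km <- substring(s, 1:(n - k + 1), k:n)
  tab <- table(km)
  recurring <- names(tab)[tab >= minc]
  cands <- list()
  for (w in recurring) {
    if (grepl("N", w, fixed = TRUE)) next
    pos <- which(km == w)
    chains <- list()
    grow <- function(path) {
      last <- path[length(path)]
      nxt <- pos[pos - last >= pmin & pos - last <= pmax]
      if (!length(nxt)) {
        if (length(path) >= minc) chains[[length(chains) + 1]] <<- path
        return(invisible(NULL))
      }
      for (q in nxt) grow(c(path, q))
    }
    roots <- pos[vapply(pos, function(p)
      !any(p - pos >= pmin & p - pos <= pmax), TRUE)]
    for (r in roots) grow(r)
    for (chain in chains)
      cands <- c(cands, oracle_extend_chain(chars, chain, params))
  }
  if (!length(cands)) return(empty)
  starts <- vapply(cands, function(c) c$starts[1], 0)
  ends <- vapply(cands, function(c) c$starts[length(c$starts)] + c$width - 1, 0)
  nreps <- vapply(cands, function(c) length(c$starts), 0)
  ord <- order(-nreps, -(ends - starts), starts)
  kept <- integer()
  for (i in ord) {
    if (!any(starts[kept] <= ends[i] & ends[kept] >= starts[i]))
      kept <- c(kept, i)
  }
  kept <- kept[order(starts[kept])]
  data.frame(start = starts[kept], end = ends[kept],
             n_repeats = nreps[kept])
}

array_spans <- function(arrays) {
  data.frame(start = vapply(arrays, `[[`, 0, "start"),
             end = vapply(arrays, `[[`, 0, "end"),
             n_repeats = vapply(arrays, function(a) nrow(a$repeats), 0))
}

# ---- wraparound alignment oracle ---------------------------------------

# Score-only local wraparound DP, row-vectorised; insertion sweeps done
# twice per row to close the cyclic dependency.
oracle_wdp_score <- function(region, unit, match = 2, mismatch = -7,
                             indel = -7) {
  sc <- strsplit(region, "")[[1]]
  uc <- strsplit(unit, "")[[1]]
  n <- length(sc); p <- length(uc)
  prev <- rep(0, p)
  best <- 0
  for (i in 1:n) {
    sub <- ifelse(uc == sc[i] & sc[i] != "N", match, mismatch)
    diag <- c(prev[p], prev[-p]) + sub
    cur <- pmax(0, diag, prev + indel)
    for (pass in 1:2) {
      for (j in 1:p) {
        jm <- if (j == 1) p else j - 1
        v <- cur[jm] + indel
        if (v > cur[j]) cur[j] <- v
      }
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# Exhaustive best tandem score: every period up to n/2, every distinct
# window of that length anywhere in the region as the unit.
oracle_best_tandem_score <- function(region) {
  n <- nchar(region)
  best <- 0
  for (p in 1:(n %/% 2)) {
    units <- unique(substring(region, 1:(n - p + 1), p:n))
    for (u in units) {
      sc <- oracle_wdp_score(region, u)
      if (sc > best) best <- sc
    }
  }
  best
}

# ---- greedy clustering oracle ------------------------------------------

oracle_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- character()
  membership <- integer(length(seqs))
  for (i in ord) {
    placed <- 0
    for (ci in seq_along(reps)) {
      if (pairwise_identity(seqs[i], reps[ci]) >= threshold) {
        placed <- ci; break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[i])
      placed <- length(reps)
    }
    membership[i] <- placed
  }
  membership
}
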