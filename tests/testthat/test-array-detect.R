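test_that("consensus is the per-column majority with first-occurring tie-break", {
  expect_equal(consensus_repeat(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(consensus_repeat(c("ACGT", "ACGA", "ACGT")), "ACGT")
  expect_equal(consensus_repeat(c("ACGT", "ACGA")), "ACGT")
  expect_error(consensus_repeat(character()), "zero")
  # unequal lengths: a copy within 20% of the modal length still votes
  expect_equal(consensus_repeat(c("ACGTACGTACGTACGTACGTACGTA",
                                  "ACGTACGTACGTACGTACGTACGTA",
                                  "ACGTACGTACGTACGTACGTACG")),
               "ACGTACGTACGTACGTACGTACGTA")
})

test_that("a planted repeat-spacer array is recovered exactly", {
  set.seed(101)
  rep_seq <- rand_seq(25)
  spacers <- vapply(1:3, function(i) rand_seq(32), "")
  emb <- embed_array(rep_seq, spacers)
  genome <- genome_record("g1", emb$seq)
  arrays <- find_arrays(genome)
  expect_length(arrays, 1L)
  a <- arrays[[1]]
  expect_equal(nrow(a$repeats), 4L)
  expect_equal(nrow(a$spacers), 3L)
  expect_equal(a$consensus_repeat, rep_seq)
  expect_lte(abs(a$start - emb$start), 2L)
  expect_lte(abs(a$end - emb$end), 2L)
  expect_true(crisprsieve:::.validate_array(a, genome))
  # every repeat/spacer equals its genome slice
  expect_equal(substring(genome$seq, a$repeats$start, a$repeats$end),
               a$repeats$seq)
  expect_equal(substring(genome$seq, a$spacers$start, a$spacers$end),
               a$spacers$seq)
})

test_that("a copy with 8% mismatches stays in the array", {
  set.seed(102)
  rep_seq <- rand_seq(25)
  spacers <- vapply(1:3, function(i) rand_seq(32), "")
  copies <- rep(rep_seq, 4)
  copies[3] <- mutate_at(rep_seq, c(3L, 20L)) # leaves positions 4..19 intact
  emb <- embed_array(rep_seq, spacers, copies = copies)
  arrays <- find_arrays(genome_record("g1", emb$seq))
  expect_length(arrays, 1L)
  expect_equal(nrow(arrays[[1]]$repeats), 4L)
})

test_that("random sequence yields no arrays (oracle-checked)", {
  set.seed(103)
  genome <- genome_record("r1", rand_seq(1000))
  expect_length(find_arrays(genome), 0L)
  expect_equal(nrow(oracle_find_arrays(genome)), 0L)
})

test_that("detector equals exhaustive enumeration on short random genomes", {
  for (s in 1:20) {
    set.seed(2000 + s)
    genome <- genome_record(sprintf("r%02d", s), rand_seq(2000))
    got <- array_spans(find_arrays(genome))
    want <- oracle_find_arrays(genome)
    expect_equal(got, want, info = sprintf("seed %d", 2000 + s))
  }
})

test_that("partial terminal repeats are annexed when long enough", {
  set.seed(104)
  rep_seq <- rand_seq(25)
  spacers <- vapply(1:3, function(i) rand_seq(32), "")
  core <- embed_array(rep_seq, spacers, flank = 0)
  partial <- substring(rep_seq, 1, 15)             # 15/25 >= 0.5
  tail_sp <- rand_seq(30)
  # guard bases: everything following the partial disagrees with the
  # consensus continuation, pinning the extension at exactly 15 bp
  guard <- paste(vapply(16:25, function(i) {
    setdiff(c("A", "C", "G", "T"),
            substring(rep_seq, i, i))[1]
  }, ""), collapse = "")
  seq <- paste0(rand_seq(800), core$seq, tail_sp, partial, guard,
                rand_seq(800))
  genome <- genome_record("g1", seq)
  found <- find_arrays(genome)
  expect_length(found, 1L)
  ext <- extend_partial_repeats(found[[1]], genome)
  expect_true(ext$partial_terminal[["3"]])
  expect_equal(ext$end, found[[1]]$end + 30L + 15L)
  expect_equal(nrow(ext$repeats), 5L)
  expect_equal(nrow(ext$spacers), 4L)
  expect_true(crisprsieve:::.validate_array(ext, genome))

  # 8/25 < 0.5 of the consensus: no extension
  seq2 <- paste0(rand_seq(800), core$seq, tail_sp,
                 substring(rep_seq, 1, 8), rand_seq(800))
  genome2 <- genome_record("g2", seq2)
  found2 <- find_arrays(genome2)
  ext2 <- extend_partial_repeats(found2[[1]], genome2)
  expect_equal(ext2$end, found2[[1]]$end)

  # no flanking similarity at all: identity
  set.seed(105)
  emb3 <- embed_array(rep_seq, spacers)
  genome3 <- genome_record("g3", emb3$seq)
  found3 <- find_arrays(genome3)
  ext3 <- extend_partial_repeats(found3[[1]], genome3)
  expect_equal(ext3$start, found3[[1]]$start)
  expect_equal(ext3$end, found3[[1]]$end)
})

make_two_array_genome <- function(rep_a, rep_b, gap_bp, seed) {
  # gap_bp is the inter-interval distance start2 - end1
  set.seed(seed)
  spac <- function(k) vapply(seq_len(k), function(i) rand_seq(32), "")
  a <- embed_array(rep_a, spac(3), flank = 0)
  b <- embed_array(rep_b, spac(2), flank = 0)
  seq <- paste0(rand_seq(900), a$seq, rand_seq(gap_bp - 1L), b$seq,
                rand_seq(900))
  genome_record("g1", seq)
}

test_that("arrays merge at <=200 bp with similar repeats, else stay apart", {
  set.seed(106)
  rep_seq <- rand_seq(25)
  cfg <- sieve_config()

  g_close <- make_two_array_genome(rep_seq, rep_seq, 150L, 1061)
  arrays <- find_arrays(g_close)
  expect_length(arrays, 2L)
  merged <- merge_arrays(arrays, g_close, cfg)
  expect_length(merged, 1L)
  expect_equal(nrow(merged[[1]]$repeats), 7L)
  expect_equal(nrow(merged[[1]]$spacers), 6L)
  expect_true(crisprsieve:::.validate_array(merged[[1]], g_close))
  # the 149 bp gap exceeds the spacer bound and is annotated
  expect_true(any(grepl("merge_gap_insertion", merged[[1]]$notes)))
  # idempotent
  expect_length(merge_arrays(merged, g_close, cfg), 1L)

  g_far <- make_two_array_genome(rep_seq, rep_seq, 201L, 1062)
  expect_length(merge_arrays(find_arrays(g_far), g_far, cfg), 2L)

  set.seed(107)
  other <- rand_seq(25) # unrelated consensus, identity well below 0.9
  stopifnot(pairwise_identity(rep_seq, other) < 0.7)
  g_diff <- make_two_array_genome(rep_seq, other, 150L, 1063)
  expect_length(merge_arrays(find_arrays(g_diff), g_diff, cfg), 2L)
})

test_that("merge boundary sits exactly at the configured gap", {
  # constructed arrays with exact coordinates, so the inter-array distance
  # (start2 - end1) is controlled to the base
  set.seed(108)
  rep_seq <- rand_seq(25)
  cfg <- sieve_config()
  build_pair <- function(gap_bp) {
    spac <- function(k) vapply(seq_len(k), function(i) rand_seq(32), "")
    a <- embed_array(rep_seq, spac(3), flank = 0)
    b <- embed_array(rep_seq, spac(2), flank = 0)
    seq <- paste0(rand_seq(200), a$seq, rand_seq(gap_bp - 1L), b$seq,
                  rand_seq(200))
    genome <- genome_record("g", seq)
    mk <- function(emb, off) {
      rs <- emb$rep_starts + off
      repeats <- data.frame(start = rs, end = rs + emb$width - 1L,
                            seq = substring(seq, rs, rs + emb$width - 1L),
                            partial = FALSE)
      ss <- rs[-length(rs)] + emb$width
      se <- rs[-1] - 1L
      crispr_array("g", repeats,
                   data.frame(start = ss, end = se,
                              seq = substring(seq, ss, se)))
    }
    list(genome = genome,
         arrays = list(mk(a, 200L), mk(b, 200L + nchar(a$seq) + gap_bp - 1L)))
  }
  p200 <- build_pair(200L)
  expect_length(merge_arrays(p200$arrays, p200$genome, cfg), 1L)
  p201 <- build_pair(201L)
  expect_length(merge_arrays(p201$arrays, p201$genome, cfg), 2L)
})

test_that("detection is reverse-complement consistent", {
  set.seed(109)
  rep_seq <- rand_seq(25)
  spacers <- vapply(1:4, function(i) rand_seq(30), "")
  emb <- embed_array(rep_seq, spacers)
  genome <- genome_record("fwd", emb$seq)
  rc <- genome_record("rc", revcomp(emb$seq))
  fw <- find_arrays(genome)
  bw <- find_arrays(rc)
  expect_length(bw, length(fw))
  n <- genome$length
  expect_equal(sort(vapply(bw, `[[`, 0, "start")),
               sort(n - vapply(fw, `[[`, 0, "end") + 1L))
  expect_equal(sort(vapply(bw, `[[`, 0, "end")),
               sort(n - vapply(fw, `[[`, 0, "start") + 1L))
  expect_equal(bw[[1]]$consensus_repeat, revcomp(fw[[1]]$consensus_repeat))
})

test_that("sequences below the minimum footprint return an empty list", {
  set.seed(110)
  expect_length(find_arrays(genome_record("tiny", rand_seq(80))), 0L)
})
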