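test_that("rescue distance is the best end-free mismatch count", {
  set.seed(51)
  r <- rand_seq(30)
  expect_equal(rescue_distance(r, r), 0)
  expect_equal(rescue_distance(mutate_at(r, c(5L, 20L)), r), 2)
  seven <- mutate_at(r, c(2L, 6L, 11L, 15L, 19L, 24L, 29L))
  expect_equal(rescue_distance(seven, r), 7)
  expect_equal(rescue_distance(r, character()), Inf)
  # length difference counts as mismatches
  expect_equal(rescue_distance(substring(r, 1, 25), r), 5)
  # the minimum over the real set is taken
  expect_equal(rescue_distance(mutate_at(r, 1L), c(rand_seq(30), r)), 1)
})

test_that("real clusters propagate through shared repeats", {
  clusters <- list(
    structure(list(cluster_id = "c1", representative = "AAA",
                   members = c("a1", "a2"), is_singleton = FALSE),
              class = "repeat_cluster"),
    structure(list(cluster_id = "c2", representative = "CCC",
                   members = "a3", is_singleton = TRUE),
              class = "repeat_cluster"))
  info <- data.frame(array_id = c("a1", "a2", "a3"),
                     colocation = c("CO_LOCATED", "ORPHAN", "ORPHAN"),
                     stringsAsFactors = FALSE)
  part <- find_real_clusters(clusters, info)
  expect_equal(vapply(part$real, `[[`, "", "cluster_id"), "c1")
  expect_equal(vapply(part$candidate, `[[`, "", "cluster_id"), "c2")
  expect_true("AAA" %in% part$real_repeats)
  # empty cluster set
  empty <- find_real_clusters(list(), info)
  expect_length(empty$real, 0L)
  expect_length(empty$candidate, 0L)
})

test_that("tandem detection finds planted periods and rejects CRISPRs", {
  r10 <- strrep("ACGTA", 10)
  call <- detect_tandem(r10)
  expect_equal(call$period, 5L)
  expect_equal(call$copies, 10, tolerance = 0.02)
  expect_equal(call$coverage, 1.0)
  expect_equal(call$score, 2 * 50)

  # a CRISPR with identical repeats but random spacers is not periodic
  set.seed(52)
  rep_seq <- rand_seq(25)
  spacers <- vapply(1:3, function(i) rand_seq(32), "")
  emb <- embed_array(rep_seq, spacers, flank = 0)
  expect_null(detect_tandem(emb$seq))

  set.seed(53)
  expect_null(detect_tandem(rand_seq(300)))
})

test_that("wraparound alignment scores equal the exhaustive oracle", {
  set.seed(54)
  for (i in 1:6) {
    unit_len <- sample(12:22, 1)
    copies <- sample(3:5, 1)
    region <- strrep(rand_seq(unit_len), copies)
    region <- substring(region, 1, min(nchar(region), 90))
    call <- detect_tandem(region)
    expect_equal(call$score, oracle_best_tandem_score(region),
                 info = sprintf("case %d", i))
  }
})

test_that("the STAR motif matches all bracket choices on both strands", {
  expect_equal(match_star("TGTGTTGGGGCCCC")$start, 1L)
  expect_equal(match_star("TATGTTGTGGCCCA")$start, 1L)
  expect_equal(nrow(match_star("AAAAAAAAAAAAAA")), 0L)
  inst <- star_motif_instances()
  expect_length(inst, 12L)
  for (m in inst) {
    expect_equal(match_star(m)$strand, "+")
    expect_equal(match_star(revcomp(m))$strand, "-")
  }
  # positions inside context, overlapping-safe
  set.seed(55)
  seq <- paste0(rand_seq(50), inst[3], rand_seq(40), revcomp(inst[7]),
                rand_seq(30))
  hits <- match_star(seq)
  expect_true(all(c(51L, 105L) %in% hits$start))
})

test_that("simple repeats trigger on short units, mono bias, or entropy", {
  sc <- detect_simple(strrep("GCCGTT", 12))
  expect_equal(sc$trigger, "tandem_unit")
  expect_equal(nchar(sc$unit), 6L)
  expect_equal(sc$copies, 12, tolerance = 0.02)

  # 43% adenine, remainder balanced, no tandem structure
  set.seed(56)
  n <- 300
  ch <- sample(c(rep("A", 129), sample(c("C", "G", "T"), 171,
                                       replace = TRUE)))
  region <- paste(ch, collapse = "")
  sc2 <- detect_simple(region)
  expect_equal(sc2$trigger, "mono_frac")
  expect_equal(sc2$frac, 0.43, tolerance = 0.001)

  set.seed(57)
  expect_null(detect_simple(rand_seq(300)))
})

mk_classify_case <- function(region, consensus, cluster_real = FALSE,
                             real_repeats = character(),
                             colocation = "ORPHAN",
                             spacers = c("AAA", "CCC"),
                             config = sieve_config()) {
  w <- 25L
  reps <- data.frame(start = c(1L, nchar(region) - w + 1L),
                     end = c(w, nchar(region)),
                     seq = c(substring(region, 1, w),
                             substring(region, nchar(region) - w + 1L,
                                       nchar(region))),
                     partial = FALSE)
  arr <- structure(list(genome_id = "g", start = 1L, end = nchar(region),
                        repeats = reps, spacers = NULL,
                        consensus_repeat = consensus,
                        partial_terminal = c(`5` = FALSE, `3` = FALSE),
                        notes = character()), class = "crispr_array")
  classify_element(arr, region, cluster_real, real_repeats, colocation,
                   is_diverse(spacers), config)
}

test_that("classification cascades with rescue and precedence", {
  set.seed(58)
  real_rep <- rand_seq(25)

  # cluster-level cas evidence wins outright
  c1 <- mk_classify_case(rand_seq(200), rand_seq(25), cluster_real = TRUE)
  expect_equal(c1$label, "REAL")

  # rescue: 4 mismatches < limit 5 -> REAL; 5 -> eligible false
  near <- mutate_at(real_rep, c(2L, 8L, 14L, 20L))
  c2 <- mk_classify_case(rand_seq(200), near, real_repeats = real_rep)
  expect_equal(c2$label, "REAL")
  expect_equal(c2$evidence$rescue_distance, 4)
  at5 <- mutate_at(real_rep, c(2L, 8L, 14L, 20L, 24L))
  c3 <- mk_classify_case(rand_seq(200), at5, real_repeats = real_rep)
  expect_false(c3$label == "REAL")
  expect_equal(c3$evidence$rescue_distance, 5)

  # STAR: motif in the region, identical linkers notwithstanding
  star <- plant_star(4)
  c4 <- mk_classify_case(star$seq, rand_seq(25))
  expect_equal(c4$label, "STAR")
  expect_gte(c4$evidence$star_hits, 4L)

  # TANDEM: long-unit periodicity without the motif
  tnd <- plant_tandem(70L, 6L)
  c5 <- mk_classify_case(tnd$seq, rand_seq(25))
  expect_equal(c5$label, "TANDEM")

  # SIMPLE: mononucleotide run detected as array-like
  c6 <- mk_classify_case(strrep("A", 250), strrep("A", 25))
  expect_equal(c6$label, "SIMPLE")

  # UNKNOWN: no detector fires on plain random sequence
  c7 <- mk_classify_case(rand_seq(220), rand_seq(25))
  expect_equal(c7$label, "UNKNOWN")
})

test_that("adding cas evidence moves labels only toward REAL", {
  set.seed(59)
  star <- plant_star(4)
  before <- mk_classify_case(star$seq, rand_seq(25), cluster_real = FALSE)
  after <- mk_classify_case(star$seq, rand_seq(25), cluster_real = TRUE,
                            colocation = "CO_LOCATED")
  expect_equal(before$label, "STAR")
  expect_equal(after$label, "REAL")
})

test_that("strict diversity mode withholds rescue from cas-absent arrays", {
  set.seed(60)
  real_rep <- rand_seq(25)
  near <- mutate_at(real_rep, 3L)
  strict <- sieve_config(strict_diversity = TRUE)
  c_lenient <- mk_classify_case(rand_seq(200), near,
                                real_repeats = real_rep,
                                spacers = rep("ACGTACGTACGTACGTAC", 4))
  expect_equal(c_lenient$label, "REAL")
  c_strict <- mk_classify_case(rand_seq(200), near,
                               real_repeats = real_rep,
                               spacers = rep("ACGTACGTACGTACGTAC", 4),
                               config = strict)
  expect_false(c_strict$label == "REAL")
})
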