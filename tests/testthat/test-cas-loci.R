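test_that("cas genes chain into loci at the configured gap", {
  h <- mk_hits(c("cas1", "cas2", "cas3"), c(1000L, 1700L, 2400L))
  expect_length(group_cas_genes(h, 1000L), 1L)
  h2 <- mk_hits(c("cas1", "cas2", "cas9", "csn2"),
                c(1000L, 1700L, 8000L, 8700L))
  expect_length(group_cas_genes(h2, 1000L), 2L)
  single <- group_cas_genes(mk_hits("cas1", 1000L), 1000L)
  expect_length(single, 1L)
  expect_equal(nrow(single[[1]]$genes), 1L)
})

test_that("locus validation needs three genes and a core gene", {
  expect_s3_class(mk_locus(c("cas1", "cas2", "cas3")), "cas_locus")
  rej <- mk_locus(c("cas3", "cas4", "cas6"))
  expect_s3_class(rej, "locus_rejection")
  expect_equal(rej$reason, "no_core_gene")
  rej2 <- mk_locus(c("cas1", "cas2"))
  expect_s3_class(rej2, "locus_rejection")
  expect_equal(rej2$reason, "fewer_than_min_genes")
  # subtype suffixes still count for the core rule, case-insensitively
  expect_s3_class(mk_locus(c("Cas8c", "cas3", "cas4")), "cas_locus")
})

test_that("type assignment counts signature genes with the cpf1 exception", {
  l3 <- assign_type(mk_locus(c("cas10", "csm2", "csm3", "cas1", "cas2")))
  expect_equal(l3$type_call, "III")
  expect_true(l3$confident)

  lv <- assign_type(mk_locus(c("cpf1", "cas1", "cas2")))
  expect_equal(lv$type_call, "V")
  expect_true(lv$confident)

  l2 <- assign_type(mk_locus(c("cas9", "cas1", "cas2")))
  expect_equal(l2$type_call, "II")
  expect_false(l2$confident)

  lu <- assign_type(mk_locus(c("cas1", "cas2", "cas4")))
  expect_equal(lu$type_call, "UNTYPED")

  amb <- assign_type(mk_locus(c("cas3", "cas9", "cas1", "cas2")))
  expect_equal(amb$type_call, "UNTYPED")
  expect_true(amb$ambiguous)
})

test_that("the shipped signature table is well-formed", {
  tab <- default_signature_table()
  expect_true(all(c("family", "type") %in% names(tab)))
  expect_true(all(tab$type %in% c("I", "II", "III", "IV", "V")))
  expect_equal(tab$type[tab$family == "cpf1"], "V")
  expect_setequal(tab$family[tab$type == "I"][1:1], "cas3")
})

test_that("array-gene distance is the inter-interval distance", {
  locus <- structure(list(genome_id = "g1", start = 679L, end = 1500L,
                          genes = mk_hits("cas1", 679L, gene_len = 822L)),
                     class = "cas_locus")
  arr <- mk_array_at(100L, 500L)
  expect_equal(crispr_cas_distance(arr, locus), 179L)

  over <- structure(list(genome_id = "g1", start = 400L, end = 1200L,
                         genes = mk_hits("cas1", 400L, gene_len = 801L)),
                    class = "cas_locus")
  expect_equal(crispr_cas_distance(arr, over), 0L)

  up <- structure(list(genome_id = "g1", start = 1L, end = 80L,
                       genes = mk_hits("cas1", 1L, gene_len = 80L)),
                  class = "cas_locus")
  expect_equal(crispr_cas_distance(arr, up), 20L)

  other <- structure(list(genome_id = "g2", start = 1L, end = 80L,
                          genes = mk_hits("cas1", 1L, genome_id = "g2",
                                          gene_len = 80L)),
                     class = "cas_locus")
  expect_error(crispr_cas_distance(arr, other), "different genome")
})

test_that("co-location labels follow the 10 kb window", {
  cfg <- sieve_config()
  locus <- mk_locus(c("cas1", "cas2", "cas3"), start = 20000L)
  near <- mk_array_at(locus$start - 5000L - 400L, locus$start - 5000L)
  cl <- classify_colocation(list(near), list(locus), cfg)
  expect_equal(cl$arrays$label, "CO_LOCATED")
  expect_equal(cl$loci$label, "CO_LOCATED")
  expect_equal(cl$loci$nearest_bp, 5000)

  far <- mk_array_at(100L, 500L) # 19,500 bp from the locus
  cl2 <- classify_colocation(list(far), list(locus), cfg)
  expect_equal(cl2$loci$label, "ISOLATED_REMOTE")
  expect_equal(cl2$arrays$label, "ISOLATED_REMOTE")

  cl3 <- classify_colocation(list(), list(locus), cfg)
  expect_equal(cl3$loci$label, "ORPHAN")
  cl4 <- classify_colocation(list(near), list(), cfg)
  expect_equal(cl4$arrays$label, "ORPHAN")
})

test_that("the window boundary is inclusive at exactly 10,000 bp", {
  cfg <- sieve_config()
  locus <- mk_locus(c("cas1", "cas2", "cas3"), start = 30000L)
  at_edge <- mk_array_at(locus$start - 10000L - 400L, locus$start - 10000L)
  beyond <- mk_array_at(locus$start - 10001L - 400L, locus$start - 10001L)
  expect_equal(classify_colocation(list(at_edge), list(locus),
                                   cfg)$loci$label, "CO_LOCATED")
  expect_equal(classify_colocation(list(beyond), list(locus),
                                   cfg)$loci$label, "ISOLATED_REMOTE")
})

test_that("circular replicons take the shorter way around", {
  # array at the start, locus at the end of a 100 kb circle: 1,500 bp
  # apart across the origin, ~88 kb apart linearly
  locus <- mk_locus(c("cas1", "cas2", "cas3"), start = 97000L)
  arr <- mk_array_at(500L, 900L)
  glen <- c(g1 = 100000L)
  lin <- classify_colocation(list(arr), list(locus), sieve_config(), glen)
  expect_equal(lin$loci$label, "ISOLATED_REMOTE")
  circ <- classify_colocation(list(arr), list(locus),
                              sieve_config(circular = TRUE), glen)
  expect_equal(circ$loci$label, "CO_LOCATED")
  # last gene ends at 98,999: 100,000 - 98,999 + 500 = 1,501 across origin
  expect_equal(circ$loci$nearest_bp, 1501)
})

test_that("shrinking the window never creates co-location", {
  set.seed(41)
  locus <- mk_locus(c("cas1", "cas2", "cas3"), start = 50000L)
  for (i in 1:8) {
    d <- sample(0:30000, 1)
    arr <- mk_array_at(locus$start - d - 400L, locus$start - d)
    lab <- vapply(c(20000L, 10000L, 5000L, 1000L), function(w) {
      classify_colocation(list(arr), list(locus),
                          sieve_config(window_bp = w))$loci$label
    }, "")
    # once isolated, stays isolated as the window shrinks
    expect_false(any(lab == "CO_LOCATED" &
                       c("", lab[-length(lab)]) == "ISOLATED_REMOTE"))
    expect_false(any(lab == "ORPHAN"))
  }
})

test_that("the adaptation matrix applies the conditional remote check", {
  cfg <- sieve_config()
  run_one <- function(families, arr = NULL, extra_hits = NULL) {
    locus <- assign_type(mk_locus(families, start = 20000L))
    hits <- locus$genes
    if (!is.null(extra_hits)) hits <- rbind(hits, extra_hits)
    arrays <- if (is.null(arr)) list() else list(arr)
    cl <- classify_colocation(arrays, list(locus), cfg)
    adaptation_matrix(list(g1 = list(loci = list(locus), colocation = cl,
                                     hits = hits)))
  }
  arr <- mk_array_at(19000L, 19400L)

  # type I locus, adjacent CRISPR, cas1-cas2 inside: (CRISPR+, nearby+)
  m1 <- run_one(c("cas3", "cse1", "cse2", "cas1", "cas2"), arr)
  expect_equal(m1$n, 1L)
  expect_equal(m1$crispr, "+")
  expect_equal(m1$nearby_pair, "+")
  expect_equal(m1$remote_pair, "")

  # no nearby pair, but a remote pair elsewhere in the genome
  remote <- mk_hits(c("cas1", "cas2"), c(120000L, 120700L))
  m2 <- run_one(c("cas3", "cse1", "cse2", "cas7"), arr, remote)
  expect_equal(m2$nearby_pair, "-")
  expect_equal(m2$remote_pair, "+")

  # no cas1-cas2 anywhere
  m3 <- run_one(c("cas3", "cse1", "cse2", "cas7"), arr)
  expect_equal(m3$remote_pair, "-")

  # row sums per type equal the number of typed loci
  expect_equal(sum(m1$n), 1L)
})

test_that("distance distributions compare by rank-sum test", {
  same <- list(a = c(5, 10, 20, 40), b = c(5, 10, 20, 40))
  res <- compare_distance_distributions(same)
  expect_gt(res$tests$p_value, 0.9)
  shifted <- list(a = 1:100, b = 1001:1100)
  expect_lt(compare_distance_distributions(shifted)$tests$p_value, 1e-10)
  expect_equal(unname(compare_distance_distributions(
    list(x = c(1, 2, 3), y = c(4, 5, 6)))$medians["x"] == 2), TRUE)
  expect_error(compare_distance_distributions(list(a = 1:3)), "two")
  expect_error(compare_distance_distributions(list(a = 1:3, b = numeric())),
               "empty")
})
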