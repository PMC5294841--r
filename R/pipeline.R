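# End-to-end orchestration: detect -> extend -> merge -> cluster ->
# diversity -> cas typing -> co-location -> real/false classification ->
# summaries.

#' Canonical benchmark element set
#'
#' One complete CRISPR-Cas system (diverse-spacer array with a type I cas
#' locus 200 bp downstream) plus one tandem repeat, one STAR-like element
#' and one simple repeat, for planting into one synthetic genome.
#'
#' @param id Genome record id.
#' @return A spec list for [generate_genome()].
#' @export
benchmark_spec <- function(id = "synth") {
  list(id = id, gc = 0.5, elements = list(
    list(kind = "CRISPR", n_spacers = 6L, diversity_mode = "diverse",
         cas_type = "I", cas_distance = 200L),
    list(kind = "TANDEM"),
    list(kind = "STAR"),
    list(kind = "SIMPLE")))
}

#' Planted-truth recovery benchmark
#'
#' Generates one [benchmark_spec()] genome per seed, runs the full pipeline
#' over all of them jointly, matches every planted element to the detected
#' arrays by coordinate overlap, and reports per-kind label recall. The
#' planted kinds map to expected labels CRISPR -> REAL, TANDEM -> TANDEM,
#' STAR -> STAR, SIMPLE -> SIMPLE.
#'
#' @param seeds Integer vector; one synthetic genome per seed.
#' @param config A [sieve_config()].
#' @return A list: `result` (the `sieve_result`), `truth` (per planted
#'   element: `kind`, `detected`, `label`, `boundary_err`, `correct`) and
#'   `rates` (named recall per kind, `real_to_tandem` confusion count, and
#'   `crispr_recovered` = fraction of planted CRISPRs detected with both
#'   boundaries within 2 bp).
#' @export
benchmark_recovery <- function(seeds = 1:50, config = sieve_config()) {
  gs <- lapply(seeds, function(s)
    generate_genome(benchmark_spec(sprintf("synth%03d", s)), seed = s))
  genomes <- lapply(gs, `[[`, "genome")
  cas <- do.call(rbind, lapply(gs, `[[`, "cas"))
  res <- sieve_run(genomes, cas, config)
  rows <- list()
  for (i in seq_along(gs)) {
    tr <- gs[[i]]$truth
    tr <- tr[tr$kind != "CAS_LOCUS", , drop = FALSE]
    at <- res$array_table[res$array_table$genome_id == genomes[[i]]$id, ,
                          drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      hit <- at[at$start <= tr$end[r] & at$end >= tr$start[r], ,
                drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genomes[[i]]$id, kind = tr$kind[r],
        detected = nrow(hit) > 0L,
        label = if (nrow(hit)) hit$label[1] else NA_character_,
        boundary_err = if (nrow(hit))
          max(abs(hit$start[1] - tr$start[r]),
              abs(hit$end[1] - tr$end[r])) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  expected <- c(CRISPR = "REAL", TANDEM = "TANDEM", STAR = "STAR",
                SIMPLE = "SIMPLE")
  truth$expected <- unname(expected[truth$kind])
  truth$correct <- !is.na(truth$label) & truth$label == truth$expected
  recall <- vapply(names(expected), function(k)
    mean(truth$correct[truth$kind == k]), 0)
  crispr <- truth[truth$kind == "CRISPR", ]
  rates <- c(as.list(recall), list(
    real_to_tandem = sum(truth$kind == "CRISPR" & !is.na(truth$label) &
                           truth$label == "TANDEM"),
    crispr_recovered = mean(crispr$detected &
                              !is.na(crispr$boundary_err) &
                              crispr$boundary_err <= 2)))
  list(result = res, truth = truth, rates = rates)
}

#' Run the full screening pipeline
#'
#' Detects arrays in every genome, extends partial terminal repeats, merges
#' split arrays, clusters consensus repeats across genomes, computes spacer
#' diversity, groups and types cas loci, classifies CRISPR/cas co-location,
#' and issues the final real/false verdict per array. Deterministic for
#' fixed inputs and configuration.
#'
#' @param genomes A list of [genome_record()] or a FASTA path.
#' @param cas_hits Cas gene annotations: a data.frame (as from
#'   [read_cas_table()]), a file path, or `NULL` (all genomes treated as
#'   cas-absent).
#' @param config A [sieve_config()].
#' @param assembly Optional named character vector mapping genome record ids
#'   to assembly ids, so draft-genome contigs share remote-partner logic;
#'   default: every record is its own assembly.
#' @return A list of class `sieve_result`: `arrays` (list of
#'   [crispr_array()]), `array_table`, `clusters`, `cluster_table`, `loci`,
#'   `locus_table`, `rejections`, `adaptation` (Table-1-style matrix),
#'   `cluster_matrix` (Table-2-style matrix), `summary`, `config`.
#' @export
sieve_run <- function(genomes, cas_hits = NULL, config = sieve_config(),
                      assembly = NULL) {
  if (is.character(genomes)) genomes <- read_genome_fasta(genomes,
                                                          config$n_policy)
  if (is.character(cas_hits)) cas_hits <- read_cas_table(cas_hits)
  if (is.null(cas_hits)) cas_hits <- .empty_cas_hits()
  gids <- vapply(genomes, `[[`, "", "id")
  names(genomes) <- gids
  if (is.null(assembly)) assembly <- stats::setNames(gids, gids)
  bad <- setdiff(unique(cas_hits$genome_id), gids)
  if (length(bad))
    stop("cas hits reference unknown genome record(s): ",
         paste(bad, collapse = ", "))
  bad_coord <- cas_hits$gene_end >
    vapply(cas_hits$genome_id, function(g) genomes[[g]]$length, 0L)
  if (any(bad_coord))
    stop("cas hit beyond genome length for record ",
         cas_hits$genome_id[bad_coord][1])

  ## arrays per record
  arrays <- list()
  for (g in genomes) {
    found <- find_arrays(g, config$detector)
    found <- lapply(found, extend_partial_repeats, genome = g,
                    params = config$detector)
    found <- merge_arrays(found, g, config)
    arrays <- c(arrays, found)
  }
  array_ids <- if (length(arrays)) {
    vapply(seq_along(arrays), function(i) {
      sprintf("%s:array%02d", arrays[[i]]$genome_id,
              sum(vapply(arrays[seq_len(i)], `[[`, "", "genome_id") ==
                    arrays[[i]]$genome_id))
    }, "")
  } else character()

  ## cas loci per record
  loci <- list()
  rejections <- list()
  for (g in gids) {
    hits_g <- cas_hits[cas_hits$genome_id == g, , drop = FALSE]
    if (!nrow(hits_g)) next
    for (cand in group_cas_genes(hits_g, config$locus_gap_bp)) {
      v <- validate_locus(cand, config)
      if (inherits(v, "cas_locus")) {
        loci[[length(loci) + 1L]] <-
          assign_type(v, min_signature_genes = config$min_signature_genes)
      } else {
        rejections[[length(rejections) + 1L]] <- v
      }
    }
  }

  ## co-location per assembly
  asm_of_array <- assembly[vapply(arrays, `[[`, "", "genome_id")]
  asm_of_locus <- assembly[vapply(loci, `[[`, "", "genome_id")]
  coloc_arrays <- rep(NA_character_, length(arrays))
  coloc_loci <- rep(NA_character_, length(loci))
  near_arrays <- rep(Inf, length(arrays))
  near_loci <- rep(Inf, length(loci))
  annotations <- list()
  for (a in unique(assembly)) {
    ai <- which(asm_of_array == a)
    li <- which(asm_of_locus == a)
    glens <- stats::setNames(vapply(genomes, `[[`, 0L, "length"), gids)
    cl <- classify_colocation(arrays[ai], loci[li], config, glens)
    coloc_arrays[ai] <- cl$arrays$label
    near_arrays[ai] <- cl$arrays$nearest_bp
    coloc_loci[li] <- cl$loci$label
    near_loci[li] <- cl$loci$nearest_bp
    recs <- names(assembly)[assembly == a]
    annotations[[a]] <- list(
      loci = loci[li], colocation = cl,
      hits = cas_hits[cas_hits$genome_id %in% recs, , drop = FALSE])
  }

  ## diversity + clustering
  diversity <- lapply(arrays, is_diverse,
                      threshold = config$spacer_cluster_identity)
  consensuses <- stats::setNames(
    vapply(arrays, `[[`, "", "consensus_repeat"), array_ids)
  clusters <- cluster_repeats(consensuses,
                              threshold = config$repeat_cluster_identity,
                              both_strands = config$both_strands,
                              min_members = config$cluster_min_members)
  cluster_of <- stats::setNames(
    rep(vapply(clusters, `[[`, "", "cluster_id"),
        vapply(clusters, function(cl) length(cl$members), 0L)),
    unlist(lapply(clusters, `[[`, "members")))

  ## real/false partition and per-array classification
  array_info <- data.frame(array_id = array_ids,
                           colocation = coloc_arrays,
                           consensus = unname(consensuses),
                           stringsAsFactors = FALSE)
  partition <- find_real_clusters(clusters, array_info)
  real_cluster_ids <- vapply(partition$real, `[[`, "", "cluster_id")
  classifications <- vector("list", length(arrays))
  for (i in seq_along(arrays)) {
    arr <- arrays[[i]]
    region <- substring(genomes[[arr$genome_id]]$seq, arr$start, arr$end)
    classifications[[i]] <- classify_element(
      arr, region,
      cluster_real = cluster_of[[array_ids[i]]] %in% real_cluster_ids,
      real_repeats = partition$real_repeats,
      colocation = coloc_arrays[i],
      diversity = diversity[[i]], config = config)
  }

  array_table <- .build_array_table(arrays, array_ids, diversity, cluster_of,
                                    clusters, coloc_arrays, near_arrays,
                                    classifications)
  locus_table <- .build_locus_table(loci, coloc_loci, near_loci)
  result <- structure(list(
    arrays = stats::setNames(arrays, array_ids),
    array_table = array_table,
    clusters = clusters,
    cluster_table = .build_cluster_table(clusters),
    loci = loci,
    locus_table = locus_table,
    rejections = rejections,
    adaptation = adaptation_matrix(annotations),
    cluster_matrix = .build_cluster_matrix(clusters, array_table),
    config = config), class = "sieve_result")
  result$summary <- .build_summary(result)
  result
}

.build_array_table <- function(arrays, array_ids, diversity, cluster_of,
                               clusters, coloc, near, classifications) {
  if (!length(arrays)) {
    return(data.frame(array_id = character(), genome_id = character(),
                      start = integer(), end = integer(),
                      n_repeats = integer(), n_spacers = integer(),
                      consensus_repeat = character(), partial_5 = logical(),
                      partial_3 = logical(), n_spacer_clusters = integer(),
                      diversity_status = character(),
                      redundant_spacers = integer(), cluster_id = character(),
                      singleton = logical(), colocation = character(),
                      nearest_cas_bp = numeric(), label = character(),
                      rescue_distance = numeric(), star_hits = integer(),
                      tandem_period = integer(), simple_trigger = character(),
                      stringsAsFactors = FALSE))
  }
  singleton_of <- stats::setNames(
    vapply(clusters, `[[`, TRUE, "is_singleton"),
    vapply(clusters, `[[`, "", "cluster_id"))
  data.frame(
    array_id = array_ids,
    genome_id = vapply(arrays, `[[`, "", "genome_id"),
    start = vapply(arrays, `[[`, 0L, "start"),
    end = vapply(arrays, `[[`, 0L, "end"),
    n_repeats = vapply(arrays, function(a) nrow(a$repeats), 0L),
    n_spacers = vapply(arrays, function(a) nrow(a$spacers), 0L),
    consensus_repeat = vapply(arrays, `[[`, "", "consensus_repeat"),
    partial_5 = vapply(arrays, function(a) a$partial_terminal[["5"]], TRUE),
    partial_3 = vapply(arrays, function(a) a$partial_terminal[["3"]], TRUE),
    n_spacer_clusters = vapply(diversity, `[[`, 0L, "n_spacer_clusters"),
    diversity_status = vapply(diversity, `[[`, "", "status"),
    redundant_spacers = vapply(diversity, `[[`, 0L, "redundant_spacers"),
    cluster_id = unname(cluster_of[array_ids]),
    singleton = unname(singleton_of[cluster_of[array_ids]]),
    colocation = coloc,
    nearest_cas_bp = near,
    label = vapply(classifications, `[[`, "", "label"),
    rescue_distance = vapply(classifications, function(c)
      c$evidence$rescue_distance, 0),
    star_hits = vapply(classifications, function(c)
      as.integer(c$evidence$star_hits), 0L),
    tandem_period = vapply(classifications, function(c) {
      tc <- c$evidence$tandem_call
      if (is.null(tc)) NA_integer_ else as.integer(tc$period)
    }, 0L),
    simple_trigger = vapply(classifications, function(c) {
      sc <- c$evidence$simple_call
      if (is.null(sc)) NA_character_ else sc$trigger
    }, ""),
    stringsAsFactors = FALSE)
}

.build_locus_table <- function(loci, coloc, near) {
  if (!length(loci)) {
    return(data.frame(locus_id = character(), genome_id = character(),
                      start = integer(), end = integer(),
                      n_genes = integer(), families = character(),
                      type = character(), confident = logical(),
                      ambiguous = logical(), has_cas1_cas2 = logical(),
                      colocation = character(), nearest_array_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    locus_id = sprintf("locus%03d", seq_along(loci)),
    genome_id = vapply(loci, `[[`, "", "genome_id"),
    start = vapply(loci, `[[`, 0L, "start"),
    end = vapply(loci, `[[`, 0L, "end"),
    n_genes = vapply(loci, function(l) nrow(l$genes), 0L),
    families = vapply(loci, function(l)
      paste(l$genes$family, collapse = ","), ""),
    type = vapply(loci, `[[`, "", "type_call"),
    confident = vapply(loci, `[[`, TRUE, "confident"),
    ambiguous = vapply(loci, `[[`, TRUE, "ambiguous"),
    has_cas1_cas2 = vapply(loci, `[[`, TRUE, "has_cas1_cas2"),
    colocation = coloc,
    nearest_array_bp = near,
    stringsAsFactors = FALSE)
}

.build_cluster_table <- function(clusters) {
  data.frame(
    cluster_id = vapply(clusters, `[[`, "", "cluster_id"),
    representative = vapply(clusters, `[[`, "", "representative"),
    n_members = vapply(clusters, function(cl) length(cl$members), 0L),
    singleton = vapply(clusters, `[[`, TRUE, "is_singleton"),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

# Table-2-style matrix: clusters binned by the fraction of members
# co-located with cas genes; member arrays counted by evidence class
# (cas-near / cas-far / cas-absent) crossed with diversity (d+ / d- /
# short).
.build_cluster_matrix <- function(clusters, array_table) {
  bins <- c("singleton", sprintf("[%.1f,%.1f)", seq(0, 0.9, 0.1),
                                 seq(0.1, 1, 0.1)), "1")
  ev_levels <- c("cas_near", "cas_far", "cas_absent")
  dv_levels <- c("d+", "d-", "short")
  cols <- as.vector(outer(ev_levels, dv_levels, paste, sep = "_"))
  mat <- matrix(0L, nrow = length(bins), ncol = length(cols) + 2L,
                dimnames = list(bins, c("n_clusters", "n_crisprs", cols)))
  for (cl in clusters) {
    rows <- array_table[match(cl$members, array_table$array_id), ,
                        drop = FALSE]
    frac <- mean(rows$colocation == "CO_LOCATED")
    bin <- if (length(cl$members) == 1L) "singleton"
           else if (frac >= 1) "1"
           else bins[2L + floor(frac * 10)]
    mat[bin, "n_clusters"] <- mat[bin, "n_clusters"] + 1L
    mat[bin, "n_crisprs"] <- mat[bin, "n_crisprs"] + nrow(rows)
    ev <- c(CO_LOCATED = "cas_near", ISOLATED_REMOTE = "cas_far",
            ORPHAN = "cas_absent")[rows$colocation]
    dv <- c(DIVERSE = "d+", NOT_DIVERSE = "d-", SHORT = "short")[
      rows$diversity_status]
    for (i in seq_len(nrow(rows))) {
      col <- paste(ev[i], dv[i], sep = "_")
      mat[bin, col] <- mat[bin, col] + 1L
    }
  }
  as.data.frame(mat)
}

# Every summary count is re-derived from the tables, never tallied
# independently.
.build_summary <- function(result) {
  at <- result$array_table
  lt <- result$locus_table
  list(
    n_arrays = nrow(at),
    n_clusters = sum(!result$cluster_table$singleton),
    n_singletons = sum(result$cluster_table$singleton),
    loci_by_type = as.list(table(lt$type)),
    loci_confident = sum(lt$confident),
    colocation_counts = list(
      arrays = as.list(table(at$colocation)),
      loci = as.list(table(lt$colocation))),
    classification_counts = as.list(table(at$label)),
    diversity_counts = as.list(table(at$diversity_status)),
    thresholds = result$config[setdiff(names(result$config), "detector")],
    detector = unclass(result$config$detector),
    version = as.character(utils::packageVersion("crisprsieve")))
}

#' @export
print.sieve_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<sieve_result> %d arrays (%d clusters, %d singletons), ",
                     "%d cas loci\n"),
              s$n_arrays, s$n_clusters, s$n_singletons, nrow(x$locus_table)))
  if (nrow(x$array_table))
    print(table(x$array_table$label))
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits a GFF3 of arrays and cas loci, per-array / per-locus / per-cluster
#' TSV tables, and a JSON run summary (including the adaptation and cluster
#' matrices). All coordinates are 1-based inclusive.
#'
#' @param results A `sieve_result` from [sieve_run()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(results, dir) {
  stopifnot(inherits(results, "sieve_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- c(gff3 = file.path(dir, "annotations.gff3"),
             arrays = file.path(dir, "arrays.tsv"),
             loci = file.path(dir, "loci.tsv"),
             clusters = file.path(dir, "clusters.tsv"),
             false_repeats = file.path(dir, "false_element_repeats.fasta"),
             summary = file.path(dir, "summary.json"))
  at <- results$array_table
  lt <- results$locus_table
  feats <- NULL
  if (nrow(at)) {
    feats <- GenomicRanges::GRanges(
      seqnames = at$genome_id,
      ranges = IRanges::IRanges(at$start, at$end),
      type = "repeat_region", ID = at$array_id, label = at$label,
      cluster = at$cluster_id)
  }
  if (nrow(lt)) {
    lf <- GenomicRanges::GRanges(
      seqnames = lt$genome_id,
      ranges = IRanges::IRanges(lt$start, lt$end),
      type = "CRISPR_cas_locus", ID = lt$locus_id, label = lt$colocation,
      cluster = NA_character_)
    S4Vectors::mcols(lf)$cas_type <- lt$type
    feats <- if (is.null(feats)) lf else c(feats, lf)
  }
  if (is.null(feats)) {
    feats <- GenomicRanges::GRanges()
  }
  rtracklayer::export(feats, paths[["gff3"]], format = "gff3")
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(at, paths[["arrays"]])
  wt(lt, paths[["loci"]])
  wt(results$cluster_table, paths[["clusters"]])
  # consensus "repeats" of the false elements, one record per array
  false_rows <- at[!at$label %in% c("REAL"), , drop = FALSE]
  false_set <- Biostrings::DNAStringSet(false_rows$consensus_repeat)
  names(false_set) <- sprintf("%s|%s", false_rows$array_id,
                              false_rows$label)
  Biostrings::writeXStringSet(false_set, paths[["false_repeats"]])
  jsonlite::write_json(
    list(summary = results$summary,
         adaptation_matrix = results$adaptation,
         cluster_matrix = cbind(bin = rownames(results$cluster_matrix),
                                results$cluster_matrix)),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  invisible(paths)
}
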