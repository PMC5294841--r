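#' Detector parameters for the CRT-style array scanner
#'
#' Bounds on repeat and spacer geometry plus the seed/extension controls of
#' [find_arrays()]. Repeat lengths of 21--47 bp are the canonical range for
#' CRISPR direct repeats; the spacer bounds and mismatch tolerance are
#' configurable detector defaults.
#'
#' @param min_repeat_len,max_repeat_len Repeat length bounds in bp.
#' @param min_spacer_len,max_spacer_len Spacer length bounds in bp.
#' @param min_repeat_count Minimum number of repeat copies for an array.
#' @param seed_kmer Exact seed word size used to find repeat recurrences;
#'   must be shorter than `min_repeat_len`.
#' @param max_repeat_mismatch_frac Maximum fraction of positions at which a
#'   single repeat copy may differ from the array consensus.
#' @param partial_min_match Minimum fraction of the consensus that must match
#'   beyond a terminal spacer for a partial terminal repeat to be annexed.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(min_repeat_len = 21L,
                            max_repeat_len = 47L,
                            min_spacer_len = 18L,
                            max_spacer_len = 72L,
                            min_repeat_count = 3L,
                            seed_kmer = 8L,
                            max_repeat_mismatch_frac = 0.2,
                            partial_min_match = 0.5) {
  p <- list(min_repeat_len = as.integer(min_repeat_len),
            max_repeat_len = as.integer(max_repeat_len),
            min_spacer_len = as.integer(min_spacer_len),
            max_spacer_len = as.integer(max_spacer_len),
            min_repeat_count = as.integer(min_repeat_count),
            seed_kmer = as.integer(seed_kmer),
            max_repeat_mismatch_frac = max_repeat_mismatch_frac,
            partial_min_match = partial_min_match)
  stopifnot(p$min_repeat_len <= p$max_repeat_len,
            p$min_spacer_len <= p$max_spacer_len,
            p$seed_kmer < p$min_repeat_len,
            p$min_repeat_count >= 2L,
            p$max_repeat_mismatch_frac >= 0, p$max_repeat_mismatch_frac < 1,
            p$partial_min_match > 0, p$partial_min_match <= 1)
  structure(p, class = "detector_params")
}

#' Pipeline configuration
#'
#' Collects every threshold used across the pipeline. Defaults encode the
#' screening rules: a 10,000 bp co-location window, a 200 bp merge gap for
#' split arrays, 90% identity for repeat clustering, 70% identity for spacer
#' clustering, the >=3 cas gene / core-gene locus rule, >=3 type-consistent
#' signature genes for a confident type call, the 5-mismatch rescue against
#' real repeats, and the 90% identity / 90% coverage rule for comparing
#' repeats against external collections.
#'
#' @param window_bp CRISPR/cas co-location window in bp.
#' @param merge_gap_bp Maximum gap between arrays merged into one locus.
#' @param repeat_cluster_identity Identity threshold for consensus-repeat
#'   clustering (fraction in (0,1]).
#' @param spacer_cluster_identity Identity threshold for spacer clustering.
#' @param min_locus_genes Minimum number of cas genes in a valid locus.
#' @param min_signature_genes Signature genes needed for a confident type call.
#' @param rescue_mismatch_limit A candidate false repeat within this many
#'   mismatches of any real repeat is rescued as real.
#' @param collection_identity,collection_coverage Identity and query-coverage
#'   thresholds for [compare_to_collection()].
#' @param locus_gap_bp Maximum intergenic gap when chaining cas genes into a
#'   candidate locus.
#' @param tandem_min_score,tandem_min_coverage Minimum wraparound alignment
#'   score and region coverage for a positive tandem call.
#' @param simple_max_unit Tandem unit length (bp) at or below which a
#'   periodic element is treated as a simple repeat rather than a tandem
#'   repeat.
#' @param mono_frac Mononucleotide frequency at or above which a region is
#'   called simple.
#' @param entropy_max Shannon entropy (bits) at or below which a region is
#'   called low complexity.
#' @param precedence Order in which false-CRISPR detectors are consulted.
#' @param strict_diversity If `TRUE`, clusters that lack cas genes in their
#'   genomes and lack spacer diversity are demoted even when rescued.
#' @param both_strands If `TRUE`, repeat clustering also considers the
#'   reverse complement of each sequence.
#' @param cluster_min_members Number of members that makes a repeat cluster a
#'   "cluster" rather than a singleton.
#' @param n_policy What to do with characters outside `{A,C,G,T,N}` on
#'   ingest: `"error"` rejects the record, `"mask"` maps them to `N`.
#' @param circular Treat each replicon as circular when computing distances.
#' @param detector A [detector_params()] object.
#' @return A list of class `sieve_config`.
#' @export
sieve_config <- function(window_bp = 10000L,
                         merge_gap_bp = 200L,
                         repeat_cluster_identity = 0.90,
                         spacer_cluster_identity = 0.70,
                         min_locus_genes = 3L,
                         min_signature_genes = 3L,
                         rescue_mismatch_limit = 5L,
                         collection_identity = 0.90,
                         collection_coverage = 0.90,
                         locus_gap_bp = 1000L,
                         tandem_min_score = 50,
                         tandem_min_coverage = 0.8,
                         simple_max_unit = 6L,
                         mono_frac = 0.40,
                         entropy_max = 1.5,
                         precedence = c("STAR", "TANDEM", "SIMPLE"),
                         strict_diversity = FALSE,
                         both_strands = FALSE,
                         cluster_min_members = 2L,
                         n_policy = c("error", "mask"),
                         circular = FALSE,
                         detector = detector_params()) {
  n_policy <- match.arg(n_policy)
  cfg <- list(window_bp = as.integer(window_bp),
              merge_gap_bp = as.integer(merge_gap_bp),
              repeat_cluster_identity = repeat_cluster_identity,
              spacer_cluster_identity = spacer_cluster_identity,
              min_locus_genes = as.integer(min_locus_genes),
              min_signature_genes = as.integer(min_signature_genes),
              rescue_mismatch_limit = as.integer(rescue_mismatch_limit),
              collection_identity = collection_identity,
              collection_coverage = collection_coverage,
              locus_gap_bp = as.integer(locus_gap_bp),
              tandem_min_score = tandem_min_score,
              tandem_min_coverage = tandem_min_coverage,
              simple_max_unit = as.integer(simple_max_unit),
              mono_frac = mono_frac,
              entropy_max = entropy_max,
              precedence = match.arg(precedence, several.ok = TRUE),
              strict_diversity = isTRUE(strict_diversity),
              both_strands = isTRUE(both_strands),
              cluster_min_members = as.integer(cluster_min_members),
              n_policy = n_policy,
              circular = isTRUE(circular),
              detector = detector)
  ids <- c(cfg$repeat_cluster_identity, cfg$spacer_cluster_identity,
           cfg$collection_identity, cfg$collection_coverage)
  stopifnot(all(ids > 0), all(ids <= 1),
            cfg$window_bp >= 0, cfg$merge_gap_bp >= 0, cfg$locus_gap_bp >= 0,
            cfg$rescue_mismatch_limit >= 0,
            inherits(detector, "detector_params"))
  structure(cfg, class = "sieve_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; keys under `detector:` are forwarded to
#' [detector_params()]. Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [sieve_config()] object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  det_args <- raw$detector
  raw$detector <- NULL
  known <- names(formals(sieve_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(det_args)) {
    bad <- setdiff(names(det_args), names(formals(detector_params)))
    if (length(bad))
      stop("unknown detector key(s): ", paste(bad, collapse = ", "))
    raw$detector <- do.call(detector_params, det_args)
  }
  do.call(sieve_config, raw)
}
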