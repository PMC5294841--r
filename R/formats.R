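#' Construct a genome record
#'
#' The in-memory carrier for one replicon: an identifier and an upper-case
#' nucleotide string over `{A,C,G,T,N}`. Characters outside that alphabet are
#' either rejected or masked to `N` depending on `n_policy`.
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide string.
#' @param n_policy `"error"` or `"mask"`; see [sieve_config()].
#' @return A list of class `genome_record` with fields `id`, `seq`, `length`.
#' @export
genome_record <- function(id, seq, n_policy = c("error", "mask")) {
  n_policy <- match.arg(n_policy)
  if (!nzchar(id)) stop("genome record with empty id")
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("genome record '", id, "' has an empty sequence")
  if (grepl("[^ACGTN]", seq)) {
    if (n_policy == "error")
      stop("genome record '", id, "' contains characters outside {A,C,G,T,N}")
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' Multi-record, multi-line FASTA. Record order is preserved. Sequences are
#' upper-cased; characters outside `{A,C,G,T,N}` are handled per `n_policy`.
#'
#' @param path FASTA file.
#' @inheritParams genome_record
#' @return A list of [genome_record()] objects.
#' @export
read_genome_fasta <- function(path, n_policy = c("error", "mask")) {
  n_policy <- match.arg(n_policy)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA record with a malformed or empty header in ", path)
  if (anyDuplicated(ids))
    stop("duplicated FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mapply(function(id, s) genome_record(id, s, n_policy),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write genome records to FASTA
#'
#' @param records A list of [genome_record()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.empty_cas_hits <- function() {
  data.frame(genome_id = character(), gene_start = integer(),
             gene_end = integer(), strand = character(),
             family = character(), score = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

.validate_cas_hits <- function(hits, lines = NULL) {
  bad <- which(hits$gene_start > hits$gene_end)
  if (length(bad)) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    stop("cas gene with end < start at line ", where)
  }
  if (any(!nzchar(hits$family))) stop("cas gene with empty family label")
  hits$family <- tolower(hits$family)
  hits$strand[!hits$strand %in% c("+", "-")] <- "+"
  hits[order(hits$genome_id, hits$gene_start), , drop = FALSE]
}

#' Read cas gene annotations from a TSV or GFF3 table
#'
#' The TSV contract is tab-separated columns `genome_id`, `start`, `end`,
#' `strand`, `family`, `score` (header optional, detected from the first
#' line). A GFF3 file (detected from the extension or the `##gff-version`
#' pragma) must carry the family in a `cas_family` (or `family`) attribute.
#' Family matching downstream is case-insensitive; labels are lower-cased on
#' ingest.
#'
#' @param path Input file.
#' @return A data.frame of cas gene hits sorted by `(genome_id, gene_start)`
#'   with columns `genome_id`, `gene_start`, `gene_end`, `strand`, `family`,
#'   `score`, `source`.
#' @export
read_cas_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE) ||
      (length(first) && grepl("^##gff-version", first)))
    return(.read_cas_gff3(path))
  lns <- readLines(path)
  lns <- lns[nzchar(trimws(lns))]
  if (!length(lns)) return(.empty_cas_hits())
  has_header <- grepl("genome_id", lns[1], fixed = TRUE)
  body <- if (has_header) lns[-1] else lns
  if (!length(body)) return(.empty_cas_hits())
  line_no <- seq_along(body) + if (has_header) 1L else 0L
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("cas table row with missing column(s) at line ", line_no[nf < 6L][1])
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-numeric coordinate in cas table at line ", line_no[bad[1]])
  hits <- data.frame(genome_id = m[, 1], gene_start = start, gene_end = end,
                     strand = m[, 4], family = m[, 5], score = score,
                     source = "table", stringsAsFactors = FALSE)
  .validate_cas_hits(hits, line_no)
}

.read_cas_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  fam <- if ("cas_family" %in% names(meta)) meta$cas_family
         else if ("family" %in% names(meta)) meta$family
         else stop("GFF3 cas table lacks a cas_family attribute: ", path)
  fam <- as.character(fam)
  if (anyNA(fam) || any(!nzchar(fam)))
    stop("GFF3 cas feature without a cas_family value in ", path)
  score <- meta$score
  if (is.null(score)) score <- rep(NA_real_, length(gr))
  hits <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene_start = GenomicRanges::start(gr),
    gene_end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family = fam,
    score = as.numeric(score),
    source = "table", stringsAsFactors = FALSE)
  .validate_cas_hits(hits)
}

#' Read cas gene hits from hmmscan domain-table output
#'
#' Parses `hmmscan --domtblout` output (target = Cas family model, query =
#' protein id), keeps the best full-sequence score per protein, drops hits
#' below `min_score`, and maps protein ids to genomic coordinates through a
#' companion table with columns `protein_id`, `genome_id`, `start`, `end`,
#' `strand`. Proteins absent from the companion table are skipped with a
#' warning; the number skipped is recorded in the `skipped` attribute.
#'
#' @param path hmmscan domain table.
#' @param coords Companion coordinate table: a data.frame or a TSV path.
#' @param min_score Minimum full-sequence bit score to retain a hit.
#' @return A cas-hit data.frame as from [read_cas_table()], `source`
#'   `"hmmscan"`.
#' @export
read_hmmscan_tbl <- function(path, coords, min_score = 0) {
  if (is.character(coords))
    coords <- utils::read.delim(coords, stringsAsFactors = FALSE)
  need <- c("protein_id", "genome_id", "start", "end", "strand")
  if (!all(need %in% names(coords)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  lns <- readLines(path)
  lns <- lns[!grepl("^#", lns) & nzchar(trimws(lns))]
  if (!length(lns)) {
    out <- .empty_cas_hits()
    attr(out, "skipped") <- 0L
    return(out)
  }
  fields <- strsplit(trimws(lns), "\\s+")
  short <- lengths(fields) < 8L
  if (any(short)) stop("malformed hmmscan domain-table line: ", lns[short][1])
  tab <- data.frame(
    family = vapply(fields, `[`, "", 1L),
    protein_id = vapply(fields, `[`, "", 4L),
    score = as.numeric(vapply(fields, `[`, "", 8L)),
    stringsAsFactors = FALSE)
  # best full-sequence score per protein; ties broken by first appearance
  tab <- tab[order(tab$protein_id, -tab$score), , drop = FALSE]
  tab <- tab[!duplicated(tab$protein_id), , drop = FALSE]
  tab <- tab[tab$score >= min_score, , drop = FALSE]
  idx <- match(tab$protein_id, coords$protein_id)
  skipped <- sum(is.na(idx))
  if (skipped) {
    warning(skipped, " hmmscan hit(s) with unmappable protein id skipped")
    tab <- tab[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (!nrow(tab)) {
    out <- .empty_cas_hits()
    attr(out, "skipped") <- skipped
    return(out)
  }
  hits <- data.frame(genome_id = coords$genome_id[idx],
                     gene_start = as.integer(coords$start[idx]),
                     gene_end = as.integer(coords$end[idx]),
                     strand = as.character(coords$strand[idx]),
                     family = tab$family, score = tab$score,
                     source = "hmmscan", stringsAsFactors = FALSE)
  hits <- .validate_cas_hits(hits)
  attr(hits, "skipped") <- skipped
  hits
}
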