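# Proteome-wide homology screening against the reference catalog, plus
# ingest/export of standard 12-column tabular protein-search output.

OUTFMT6_COLS <- c("query", "subject", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Parse MAG ids from gene ids
#'
#' Gene ids are expected to follow a \code{MAGID_geneN} pattern by default.
#'
#' @param gene_ids character vector.
#' @param pattern regex with one capture group extracting the MAG id.
#' @return Character vector of MAG ids (the full gene id where the pattern
#'   does not match).
#' @export
parse_mag_id <- function(gene_ids, pattern = "^(.*)_gene[0-9]+$") {
  out <- sub(pattern, "\\1", gene_ids)
  out
}

.empty_hits <- function() {
  data.frame(query_gene_id = character(0), mag_id = character(0),
             reference_id = character(0), raw_score = numeric(0),
             bitscore = numeric(0), percent_identity = numeric(0),
             aln_length = integer(0), query_coverage = numeric(0),
             stringsAsFactors = FALSE)
}

#' Screen a MAG proteome against the reference catalog
#'
#' Aligns every protein against every catalog reference with
#' [align_local()] and retains every (gene, reference) pair whose bitscore
#' strictly exceeds \code{min_bitscore} -- all passing references per gene
#' are kept, not only the best, so downstream assignment can weigh
#' competing substrate categories.
#'
#' @param proteome named character vector of protein sequences (names =
#'   gene ids, \code{MAGID_geneN} by default).
#' @param catalog a \code{methyloscan_catalog}.
#' @param scheme a [scoring_scheme()].
#' @param min_bitscore retain hits with bitscore strictly greater than
#'   this (the archaeal screen uses 60; the bacterial mtxB-only screen
#'   uses 200).
#' @param mag_id_pattern regex passed to [parse_mag_id()].
#' @return Hit data.frame (query_gene_id, mag_id, reference_id, raw_score,
#'   bitscore, percent_identity, aln_length, query_coverage), sorted by
#'   gene then reference so output is invariant to input record order.
#' @export
screen_proteome <- function(proteome, catalog, scheme = scoring_scheme(),
                            min_bitscore = 60,
                            mag_id_pattern = "^(.*)_gene[0-9]+$") {
  stopifnot(inherits(catalog, "methyloscan_catalog"))
  if (min_bitscore < 0) stop("min_bitscore must be >= 0", call. = FALSE)
  if (length(proteome) == 0) {
    warning("empty proteome: no sequences to screen")
    return(.empty_hits())
  }
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome sequences must be named by gene id", call. = FALSE)
  for (i in seq_along(proteome))
    .validate_protein(proteome[[i]], names(proteome)[i])

  queries <- Biostrings::AAStringSet(toupper(proteome))
  hits <- vector("list", nrow(catalog$genes))
  for (j in seq_len(nrow(catalog$genes))) {
    ref <- catalog$genes[j, ]
    a <- Biostrings::pairwiseAlignment(
      queries, Biostrings::AAString(ref$sequence), type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    raw <- pmax(0, Biostrings::score(a))
    bits <- bitscore(raw, scheme)
    keep <- which(raw > 0 & bits > min_bitscore)
    if (!length(keep)) next
    ak <- a[keep]
    alned_q <- as.character(Biostrings::alignedPattern(ak))
    hits[[j]] <- data.frame(
      query_gene_id = names(proteome)[keep],
      mag_id = parse_mag_id(names(proteome)[keep], mag_id_pattern),
      reference_id = ref$id,
      raw_score = raw[keep],
      bitscore = bits[keep],
      percent_identity = Biostrings::pid(ak),
      aln_length = nchar(alned_q),
      query_coverage = nchar(gsub("-", "", alned_q)) /
        nchar(proteome[keep]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out)) return(.empty_hits())
  out <- out[order(out$query_gene_id, out$reference_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict hits to MAGs that encode an mtxB homolog
#'
#' The archaeal screen only carries forward hits from MAGs found to encode
#' a homolog of the substrate-demethylating \emph{mtxB} (or a fused
#' MtsD/F/H methyl-sulfide gene); hits from all other MAGs are dropped
#' entirely.
#'
#' @param hits bitscore-filtered hit data.frame from [screen_proteome()].
#' @param catalog the catalog the hits were screened against.
#' @return The retained hit rows.
#' @export
filter_archaeal_hits <- function(hits, catalog) {
  stopifnot(inherits(catalog, "methyloscan_catalog"))
  if (nrow(hits) == 0) return(hits)
  ref_role <- setNames(catalog$genes$role, catalog$genes$id)
  roles <- ref_role[hits$reference_id]
  keep_mags <- unique(hits$mag_id[roles %in% c("MtxB", "MtsFused")])
  hits[hits$mag_id %in% keep_mags, , drop = FALSE]
}

#' Ingest 12-column tabular protein-search output
#'
#' Reads the standard tab-separated 12-column format (query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore; no header). Raw scores are not available in this format and
#' are set to NA.
#'
#' @param path file path.
#' @param mag_id_pattern regex passed to [parse_mag_id()].
#' @return Hit data.frame carrying the canonical hit columns plus the raw
#'   12 input columns (as character, under \code{fmt6_}-prefixed names) so
#'   the file can be re-written verbatim with [write_tabular()].
#' @export
ingest_tabular <- function(path, mag_id_pattern = "^(.*)_gene[0-9]+$") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- .empty_hits()
    for (cc in OUTFMT6_COLS) out[[paste0("fmt6_", cc)]] <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop("malformed tabular search row at line ", bad[1], ": expected 12 ",
         "tab-separated columns, found ", nf[bad[1]], call. = FALSE)
  m <- do.call(rbind, fields)
  colnames(m) <- paste0("fmt6_", OUTFMT6_COLS)
  raw <- as.data.frame(m, stringsAsFactors = FALSE)
  num <- suppressWarnings(list(
    pident = as.numeric(raw$fmt6_pident),
    length = as.integer(raw$fmt6_length),
    bits = as.numeric(raw$fmt6_bitscore)))
  badnum <- which(is.na(num$pident) | is.na(num$length) | is.na(num$bits))
  if (length(badnum))
    stop("malformed tabular search row at line ", badnum[1],
         ": non-numeric pident/length/bitscore", call. = FALSE)
  out <- data.frame(
    query_gene_id = raw$fmt6_query,
    mag_id = parse_mag_id(raw$fmt6_query, mag_id_pattern),
    reference_id = raw$fmt6_subject,
    raw_score = NA_real_,
    bitscore = num$bits,
    percent_identity = num$pident,
    aln_length = num$length,
    query_coverage = NA_real_,
    stringsAsFactors = FALSE)
  cbind(out, raw)
}

#' Write hits in the 12-column tabular search format
#'
#' Hits ingested with [ingest_tabular()] round-trip verbatim; hits produced
#' by [screen_proteome()] are exported with mismatch/gapopen/coordinate
#' fields unavailable from the retained alignment summary left as 0/NA.
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_tabular <- function(hits, path) {
  raw_cols <- paste0("fmt6_", OUTFMT6_COLS)
  if (all(raw_cols %in% names(hits))) {
    lines <- do.call(paste, c(lapply(raw_cols, function(cc) hits[[cc]]),
                              sep = "\t"))
  } else {
    lines <- sprintf("%s\t%s\t%.3f\t%d\t0\t0\t1\t%d\t1\t%d\t0\t%.1f",
                     hits$query_gene_id, hits$reference_id,
                     hits$percent_identity, hits$aln_length,
                     hits$aln_length, hits$aln_length, hits$bitscore)
  }
  writeLines(as.character(lines), path)
  invisible(path)
}
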