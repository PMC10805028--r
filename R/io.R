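# Thin wrappers around Biostrings / rtracklayer for the file formats the
# pipeline consumes. Sequences are handled package-internally as plain
# named character vectors.

read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  # ids are the first whitespace-delimited token of the header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene coordinates from a GFF3 file
#'
#' Extracts one row per gene/CDS feature: \code{gene_id} (the \code{ID}
#' attribute), \code{contig}, 1-based inclusive \code{start}/\code{end},
#' and \code{strand}.
#'
#' @param path GFF3 file path.
#' @param feature_types feature types to keep.
#' @return data.frame of gene coordinates, ordered by contig then start.
#' @export
read_gene_coords <- function(path, feature_types = c("gene", "CDS")) {
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% feature_types]
  ids <- gr$ID
  if (is.null(ids)) stop("GFF3 features lack ID attributes", call. = FALSE)
  out <- data.frame(gene_id = as.character(ids),
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out[order(out$contig, out$start), , drop = FALSE]
}

write_gff3 <- function(coords, path, source = "methyloscan") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     coords$contig, source, coords$start, coords$end,
                     ifelse(coords$strand %in% c("+", "-"), coords$strand, "+"),
                     coords$gene_id))
  writeLines(lines, path)
  invisible(path)
}
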