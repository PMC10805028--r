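# Substrate-resolved gene identity assignment: best-hit calls with a
# cross-category bitscore margin (an automated surrogate for manual tree
# inspection), operon synteny evidence, and pyrrolysine (Pyl) amber-codon
# readthrough detection for mttB-family genes.

.catalog_lookup <- function(catalog, ids, field) {
  setNames(catalog$genes[[field]], catalog$genes$id)[ids]
}

#' Assign a substrate-resolved identity to one gene
#'
#' The gene takes the role and substrate category of its best-bitscore
#' reference (ties broken lexicographically by reference id). The substrate
#' call is kept only when no reference from a \emph{different},
#' non-ambiguous substrate category scores within \code{margin_threshold}
#' bits of the best hit; otherwise the gene is recorded as substrate
#' ambiguous (methylotrophy-relevant but substrate-nonspecific). Genes
#' whose best reference is a RamX activase are always substrate ambiguous:
#' activases are promiscuous across corrinoid proteins.
#'
#' @param hits_for_gene hit rows for a single gene.
#' @param catalog the reference catalog.
#' @param margin_threshold bits; default 10.
#' @return One-row data.frame: gene_id, mag_id, role, substrate, subtype,
#'   best_reference_id, best_bitscore, margin_bits, syntenic (FALSE until
#'   [detect_operons()] runs), pyl_status ("not_applicable" until
#'   [detect_pyl()] / [refine_mttb_substrate()] run).
#' @export
assign_identity <- function(hits_for_gene, catalog, margin_threshold = 10) {
  if (is.null(hits_for_gene) || nrow(hits_for_gene) == 0)
    stop("cannot assign an identity from an empty hit list", call. = FALSE)
  if (length(unique(hits_for_gene$query_gene_id)) != 1L)
    stop("assign_identity expects hits for exactly one gene", call. = FALSE)
  h <- hits_for_gene
  h$role <- .catalog_lookup(catalog, h$reference_id, "role")
  h$category <- .catalog_lookup(catalog, h$reference_id, "substrate_category")
  h$subtype <- .catalog_lookup(catalog, h$reference_id, "substrate_subtype")
  if (anyNA(h$role))
    stop("hit reference id(s) absent from catalog: ",
         paste(unique(h$reference_id[is.na(h$role)]), collapse = ", "),
         call. = FALSE)
  h <- h[order(-h$bitscore, h$reference_id), , drop = FALSE]
  best <- h[1, ]

  # margin to the best-scoring competitor from a different, non-ambiguous
  # substrate category
  comp <- h$category != best$category & h$category != "ambiguous"
  margin <- if (any(comp)) best$bitscore - max(h$bitscore[comp]) else Inf

  if (best$role == "RamX") {
    substrate <- "ambiguous"
    subtype <- ""
  } else if (best$category == "ambiguous" || margin < margin_threshold) {
    substrate <- "ambiguous"
    subtype <- ""
  } else {
    substrate <- best$category
    subtype <- best$subtype
  }
  data.frame(gene_id = best$query_gene_id, mag_id = best$mag_id,
             role = best$role, substrate = substrate, subtype = subtype,
             best_reference_id = best$reference_id,
             best_bitscore = best$bitscore, margin_bits = margin,
             syntenic = FALSE, pyl_status = "not_applicable",
             stringsAsFactors = FALSE)
}

#' Assign identities to all genes in a hit table
#'
#' @param hits hit data.frame (already bitscore/MAG filtered).
#' @param catalog the reference catalog.
#' @param margin_threshold bits; see [assign_identity()].
#' @return Assignment data.frame, one row per gene, sorted by MAG then gene.
#' @export
assign_all <- function(hits, catalog, margin_threshold = 10) {
  if (nrow(hits) == 0)
    return(assign_empty())
  parts <- lapply(split(hits, hits$query_gene_id), assign_identity,
                  catalog = catalog, margin_threshold = margin_threshold)
  out <- do.call(rbind, parts)
  out <- out[order(out$mag_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

assign_empty <- function() {
  data.frame(gene_id = character(0), mag_id = character(0),
             role = character(0), substrate = character(0),
             subtype = character(0), best_reference_id = character(0),
             best_bitscore = numeric(0), margin_bits = numeric(0),
             syntenic = logical(0), pyl_status = character(0),
             stringsAsFactors = FALSE)
}

#' Detect syntenic methyltransferase-system operons
#'
#' mtxBCA/ramX genes are frequently co-encoded. Assigned genes on the same
#' contig separated by at most \code{max_intergenic} intervening
#' (unassigned) genes are clustered; clusters spanning at least two
#' distinct system roles are reported as operon evidence and their members
#' flagged syntenic. The intervening-gene count is taken over the
#' contig-wide gene order (strand-agnostic), so the result is invariant to
#' reversing contig coordinates.
#'
#' @param assignments assignment data.frame from [assign_all()].
#' @param gene_coords gene coordinate data.frame from [read_gene_coords()]
#'   covering every gene on the contigs (assigned or not).
#' @param max_intergenic maximum intervening genes within a cluster.
#' @return List with \code{operons} (data.frame: mag_id, contig,
#'   member_gene_ids and roles_present as ";"-joined strings,
#'   max_intergenic) and \code{assignments} (input with \code{syntenic}
#'   updated).
#' @export
detect_operons <- function(assignments, gene_coords, max_intergenic = 2L) {
  missing_genes <- setdiff(assignments$gene_id, gene_coords$gene_id)
  if (length(missing_genes))
    stop("assigned gene(s) missing from the gene coordinates: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  ops <- list()
  assignments$syntenic <- FALSE
  for (ctg in unique(gene_coords$contig)) {
    genes_on <- gene_coords[gene_coords$contig == ctg, , drop = FALSE]
    genes_on <- genes_on[order(genes_on$start), , drop = FALSE]
    rank <- setNames(seq_len(nrow(genes_on)), genes_on$gene_id)
    asg <- assignments[assignments$gene_id %in% genes_on$gene_id, , drop = FALSE]
    if (nrow(asg) < 2) next
    asg <- asg[order(rank[asg$gene_id]), , drop = FALSE]
    gaps <- diff(rank[asg$gene_id]) - 1L
    cluster <- cumsum(c(0L, gaps > max_intergenic))
    for (cl in split(seq_len(nrow(asg)), cluster)) {
      if (length(cl) < 2) next
      members <- asg[cl, , drop = FALSE]
      roles <- unique(members$role)
      if (length(roles) < 2) next
      ops[[length(ops) + 1L]] <- data.frame(
        mag_id = members$mag_id[1], contig = ctg,
        member_gene_ids = paste(members$gene_id, collapse = ";"),
        roles_present = paste(sort(roles), collapse = ";"),
        max_intergenic = max_intergenic, stringsAsFactors = FALSE)
      assignments$syntenic[assignments$gene_id %in% members$gene_id] <- TRUE
    }
  }
  operons <- if (length(ops)) do.call(rbind, ops) else
    data.frame(mag_id = character(0), contig = character(0),
               member_gene_ids = character(0), roles_present = character(0),
               max_intergenic = integer(0), stringsAsFactors = FALSE)
  list(operons = operons, assignments = assignments)
}

#' Detect pyrrolysine (Pyl) amber-codon readthrough in a CDS
#'
#' Pyl-containing mttB-family genes are annotated as truncated because the
#' in-frame amber (TAG) codon encoding pyrrolysine is read as a stop by
#' standard gene callers. A gene is called \code{pyl} when (i) the called
#' protein is shorter than \code{min_truncation} times the reference
#' length, (ii) the terminating codon is TAG, and (iii) in-frame
#' translation past the TAG continues for at least
#' \code{min_readthrough_aa} codons before the next stop. Full-length-like
#' genes, or genes terminating in TAA/TGA, are \code{non_pyl} (the
#' non-Pyl MttB class, specific for quaternary amines). When fewer than
#' \code{min_readthrough_aa} codons of downstream context are available the
#' status is computed from truncation and stop identity alone and flagged
#' low-confidence.
#'
#' @param cds_nt nucleotide string: the annotated CDS (including its stop
#'   codon) with any available downstream context appended.
#' @param cds_length length in nt of the annotated CDS within
#'   \code{cds_nt}; defaults to the whole string (no context).
#' @param reference_length_aa protein length of the matched reference.
#' @param min_truncation called/reference length fraction below which a
#'   gene counts as truncated (default 0.7).
#' @param min_readthrough_aa minimum codons of clean readthrough past the
#'   amber codon (default 30).
#' @return List: \code{status} ("pyl" or "non_pyl") and
#'   \code{low_confidence} (TRUE when context was insufficient or an
#'   ambiguous nucleotide was seen in the examined frame).
#' @export
detect_pyl <- function(cds_nt, cds_length = nchar(cds_nt),
                       reference_length_aa, min_truncation = 0.7,
                       min_readthrough_aa = 30L) {
  cds_nt <- toupper(cds_nt)
  if (cds_length %% 3 != 0)
    stop("annotated CDS length must be divisible by 3", call. = FALSE)
  if (cds_length < 6) stop("CDS too short", call. = FALSE)
  low_conf <- FALSE
  if (grepl("[^ACGT]", substr(cds_nt, 1, cds_length))) low_conf <- TRUE

  called_len_aa <- cds_length / 3 - 1
  stop_codon <- substr(cds_nt, cds_length - 2, cds_length)
  truncated <- called_len_aa < min_truncation * reference_length_aa

  if (!truncated || stop_codon %in% c("TAA", "TGA"))
    return(list(status = "non_pyl", low_confidence = low_conf))
  if (stop_codon != "TAG") {
    # truncated but terminating codon is not a recognizable stop (e.g.
    # ambiguous): fall back to truncation evidence alone
    return(list(status = "pyl", low_confidence = TRUE))
  }

  downstream <- substring(cds_nt, cds_length + 1)
  n_codons <- floor(nchar(downstream) / 3)
  if (n_codons < min_readthrough_aa) {
    # insufficient context: truncation + TAG alone, low confidence
    return(list(status = "pyl", low_confidence = TRUE))
  }
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(downstream, starts, starts + 2L)
  if (any(grepl("[^ACGT]", codons))) low_conf <- TRUE
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  readthrough <- if (any(is_stop)) which(is_stop)[1] - 1L else n_codons
  if (readthrough >= min_readthrough_aa)
    list(status = "pyl", low_confidence = low_conf)
  else
    list(status = "non_pyl", low_confidence = low_conf)
}

#' Refine an mttB-family assignment with its Pyl status
#'
#' Pyl-containing MttB proteins demethylate tri-, di- and monomethylamine;
#' homologs lacking the pyrrolysine residue are specific for quaternary
#' methylated amines (e.g. glycine betaine, choline). Both remain in the
#' methyl_N substrate category.
#'
#' @param assignment one-row assignment whose role is MtxB and whose
#'   subtype is an mttB-family gene.
#' @param pyl_status "pyl" or "non_pyl" (from [detect_pyl()]).
#' @return The assignment with subtype and pyl_status updated.
#' @export
refine_mttb_substrate <- function(assignment, pyl_status) {
  if (nrow(assignment) != 1L)
    stop("refine_mttb_substrate expects a single assignment row", call. = FALSE)
  if (assignment$role != "MtxB" || !grepl("mttB", assignment$subtype,
                                          ignore.case = TRUE))
    stop("refine_mttb_substrate applies only to mttB-family MtxB ",
         "assignments (got role ", assignment$role, ", subtype '",
         assignment$subtype, "')", call. = FALSE)
  if (!pyl_status %in% c("pyl", "non_pyl"))
    stop("pyl_status must be 'pyl' or 'non_pyl'", call. = FALSE)
  assignment$subtype <- if (pyl_status == "pyl")
    "Pyl-MttB (tri/di/monomethylamine)" else "non-Pyl MttB (quaternary amine)"
  assignment$substrate <- "methyl_N"
  assignment$pyl_status <- pyl_status
  assignment
}
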