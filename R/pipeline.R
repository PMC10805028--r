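# End-to-end driver: screen -> filter -> assign -> synteny -> Pyl
# refinement -> physiology calls, plus the activity rollup used on
# simulated (or real) count data.

#' Run the annotation pipeline on a community
#'
#' Screens every MAG proteome against the reference catalog, applies the
#' domain-specific hit filters (archaeal: bitscore > 60 restricted to MAGs
#' encoding an mtxB homolog; bacterial: mtxB-only hits at bitscore > 200),
#' assigns substrate-resolved identities with the cross-category bit
#' margin, attaches operon synteny evidence, resolves Pyl vs non-Pyl mttB
#' from nucleotide CDS, and produces the per-MAG physiology table.
#'
#' @param community a \code{methyloscan_community} (or any list exposing
#'   \code{proteome}, \code{cds}, \code{cds_length}, \code{gene_coords},
#'   \code{annotations}, \code{taxonomy}).
#' @param catalog reference catalog.
#' @param scheme a [scoring_scheme()].
#' @param archaeal_min_bitscore,bacterial_min_bitscore bitscore cutoffs
#'   (strict >) for the archaeal and bacterial screens.
#' @param margin_threshold cross-category margin in bits.
#' @param max_intergenic operon clustering gap.
#' @param cfg a [marker_config()].
#' @return List: \code{hits}, \code{assignments}, \code{operons},
#'   \code{physiology}, \code{traces}.
#' @export
run_pipeline <- function(community,
                         catalog = default_catalog(include_fused = TRUE),
                         scheme = scoring_scheme(),
                         archaeal_min_bitscore = 60,
                         bacterial_min_bitscore = 200,
                         margin_threshold = 10, max_intergenic = 2L,
                         cfg = marker_config()) {
  hits <- screen_proteome(community$proteome, catalog, scheme,
                          min_bitscore = min(archaeal_min_bitscore,
                                             bacterial_min_bitscore))
  domain <- setNames(.gtdb_domain(community$taxonomy$gtdb),
                     community$taxonomy$mag_id)
  hit_domain <- domain[hits$mag_id]
  arch <- hits[hit_domain %in% "archaeal" &
                 hits$bitscore > archaeal_min_bitscore, , drop = FALSE]
  arch <- filter_archaeal_hits(arch, catalog)
  ref_role <- setNames(catalog$genes$role, catalog$genes$id)
  bact <- hits[hit_domain %in% "bacterial" &
                 hits$bitscore > bacterial_min_bitscore &
                 ref_role[hits$reference_id] == "MtxB", , drop = FALSE]
  kept <- rbind(arch, bact)

  assignments <- assign_all(kept, catalog, margin_threshold)
  op <- detect_operons(assignments, community$gene_coords, max_intergenic)
  assignments <- op$assignments

  ref_len <- setNames(nchar(catalog$genes$sequence), catalog$genes$id)
  mttb <- which(assignments$role == "MtxB" &
                  grepl("mttB", assignments$subtype, ignore.case = TRUE))
  for (i in mttb) {
    g <- assignments$gene_id[i]
    if (!g %in% names(community$cds)) next
    st <- detect_pyl(community$cds[[g]], community$cds_length[[g]],
                     reference_length_aa =
                       ref_len[[assignments$best_reference_id[i]]])
    assignments[i, ] <- refine_mttb_substrate(assignments[i, , drop = FALSE],
                                              st$status)
  }

  cls <- classify_mags(assignments, community$annotations,
                       community$taxonomy, cfg)
  list(hits = hits, assignments = assignments, operons = op$operons,
       physiology = cls$physiology, traces = cls$traces)
}

#' Active-methylotroph table from expression data
#'
#' Applies [classify_active_methylotroph()] to every methylotrophic MAG in
#' a physiology table.
#'
#' @param getmm_mat geTMM matrix over all genes.
#' @param assignments assignment table from [run_pipeline()].
#' @param physiology physiology table from [run_pipeline()].
#' @param groups sample-to-group mapping for \code{getmm_mat} columns.
#' @param operons operon table from [run_pipeline()] (optional).
#' @return data.frame (mag_id, active) over methylotrophic MAGs.
#' @export
active_methylotrophs <- function(getmm_mat, assignments, physiology, groups,
                                 operons = NULL) {
  mags <- physiology$mag_id[physiology$is_methylotroph]
  act <- vapply(mags, function(m) {
    asg <- assignments[assignments$mag_id == m, , drop = FALSE]
    gid <- intersect(asg$gene_id, rownames(getmm_mat))
    if (!length(gid)) return(FALSE)
    asg <- asg[asg$gene_id %in% gid, , drop = FALSE]
    opm <- if (!is.null(operons))
      operons[operons$mag_id == m, , drop = FALSE]
    classify_active_methylotroph(getmm_mat[gid, , drop = FALSE], asg,
                                 groups = groups, operons_mag = opm)$active
  }, logical(1))
  data.frame(mag_id = mags, active = unname(act), stringsAsFactors = FALSE)
}
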