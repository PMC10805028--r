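# Rule-based per-MAG physiology calls: methanogen typing from marker gene
# complements, methylotrophy verdicts from methyltransferase-system
# completeness, substrate profiles, and obligate/facultative lifestyle.

#' Marker gene configuration for methanogen pathway typing
#'
#' Methanogens are recognized by joint presence of the methyl-coenzyme M
#' reductase (Mcr) and heterodisulfide reductase (Hdr) complexes; the
#' hydrogenotrophic and acetoclastic pathways by their indicator gene sets.
#' The default sets (and presence thresholds, the minimum fraction of set
#' members annotated) are package choices kept deliberately swappable:
#' hydrogenotrophic = formylmethanofuran dehydrogenase (fwd/fmd) +
#' methylene-H4MPT dehydrogenase (mtd) + methylene-H4MPT reductase (mer) +
#' F420/energy-converting hydrogenases (frh/ech); acetoclastic = the
#' acetate kinase/phosphotransacetylase pair or the CO
#' dehydrogenase/acetyl-CoA decarbonylase (cdh) complex.
#'
#' @param mcr,hdr core methanogen complex gene symbols.
#' @param mcr_threshold,hdr_threshold presence thresholds in (0, 1].
#' @param hydrogenotrophic hydrogenotrophic indicator symbols.
#' @param hydrogenotrophic_threshold presence threshold.
#' @param acetoclastic_pair symbols that must \emph{all} be present
#'   (ackA + pta route).
#' @param acetoclastic_complex cdh complex symbols (alternative route).
#' @param acetoclastic_threshold presence threshold for the complex route.
#' @return A list of class \code{methyloscan_markers}.
#' @export
marker_config <- function(mcr = c("mcrA", "mcrB", "mcrG"),
                          mcr_threshold = 2 / 3,
                          hdr = c("hdrA", "hdrB", "hdrC", "hdrD", "hdrE"),
                          hdr_threshold = 0.4,
                          hydrogenotrophic = c("fwdA", "fwdB", "fmdA", "fmdB",
                                               "mtd", "mer", "frhA", "frhB",
                                               "echA", "echB"),
                          hydrogenotrophic_threshold = 0.3,
                          acetoclastic_pair = c("ackA", "pta"),
                          acetoclastic_complex = c("cdhA", "cdhB", "cdhC",
                                                   "cdhD", "cdhE"),
                          acetoclastic_threshold = 0.6) {
  sets <- list(mcr = mcr, hdr = hdr, hydrogenotrophic = hydrogenotrophic,
               acetoclastic_pair = acetoclastic_pair,
               acetoclastic_complex = acetoclastic_complex)
  if (any(!lengths(sets))) stop("marker gene sets must be non-empty", call. = FALSE)
  thr <- c(mcr_threshold, hdr_threshold, hydrogenotrophic_threshold,
           acetoclastic_threshold)
  if (any(thr <= 0 | thr > 1)) stop("thresholds must lie in (0, 1]", call. = FALSE)
  structure(c(sets, list(mcr_threshold = mcr_threshold,
                         hdr_threshold = hdr_threshold,
                         hydrogenotrophic_threshold = hydrogenotrophic_threshold,
                         acetoclastic_threshold = acetoclastic_threshold)),
            class = "methyloscan_markers")
}

.set_fraction <- function(set, symbols) mean(set %in% symbols)

#' Classify a MAG as a methanogen and type its pathways
#'
#' @param annotations data.frame (mag_id, gene_id, gene_symbol), e.g. a
#'   DRAM-style annotation table read as TSV.
#' @param mag_id MAG to classify.
#' @param cfg a [marker_config()].
#' @return List: \code{is_methanogen} (Mcr and Hdr complexes both meet
#'   their presence thresholds), \code{pathways} (subset of
#'   "hydrogenotrophic"/"acetoclastic"; empty for non-methanogens — the
#'   methylotrophic pathway is added by [classify_mags()] from the
#'   methyltransferase-system evidence), \code{trace} (fired rules).
#' @export
classify_methanogen <- function(annotations, mag_id, cfg = marker_config()) {
  if (!mag_id %in% annotations$mag_id)
    stop("MAG '", mag_id, "' absent from the annotation table", call. = FALSE)
  symbols <- unique(annotations$gene_symbol[annotations$mag_id == mag_id])
  trace <- character(0)
  f_mcr <- .set_fraction(cfg$mcr, symbols)
  f_hdr <- .set_fraction(cfg$hdr, symbols)
  is_methanogen <- f_mcr >= cfg$mcr_threshold && f_hdr >= cfg$hdr_threshold
  trace <- c(trace, sprintf(
    "methanogen=%s: mcr %.2f (>=%.2f: %s), hdr %.2f (>=%.2f: %s)",
    is_methanogen, f_mcr, cfg$mcr_threshold, f_mcr >= cfg$mcr_threshold,
    f_hdr, cfg$hdr_threshold, f_hdr >= cfg$hdr_threshold))
  pathways <- character(0)
  if (is_methanogen) {
    f_h <- .set_fraction(cfg$hydrogenotrophic, symbols)
    if (f_h >= cfg$hydrogenotrophic_threshold) {
      pathways <- c(pathways, "hydrogenotrophic")
      trace <- c(trace, sprintf("hydrogenotrophic markers %.2f >= %.2f",
                                f_h, cfg$hydrogenotrophic_threshold))
    }
    pair_ok <- all(cfg$acetoclastic_pair %in% symbols)
    f_cdh <- .set_fraction(cfg$acetoclastic_complex, symbols)
    if (pair_ok || f_cdh >= cfg$acetoclastic_threshold) {
      pathways <- c(pathways, "acetoclastic")
      trace <- c(trace, sprintf(
        "acetoclastic: ackA+pta %s | cdh complex %.2f >= %.2f: %s",
        pair_ok, f_cdh, cfg$acetoclastic_threshold,
        f_cdh >= cfg$acetoclastic_threshold))
    }
  }
  list(is_methanogen = is_methanogen, pathways = pathways, trace = trace)
}

.is_mts_single <- function(assignments) {
  assignments$role == "MtsFused" |
    tolower(assignments$subtype) %in% c("mtsa", "mtsb")
}

#' Call methylotrophy for one MAG from its gene assignments
#'
#' Archaeal MAGs are defined as methylotrophic only when they encode at
#' least two of the three core methyltransferase-system members (MtxB,
#' MtxC, MtxA), one of which must be the substrate-demethylating mtxB; for
#' methyl-sulfide metabolism a single tri-functional MtsD/F/H gene, or
#' either of mtsA/mtsB, suffices. Bacterial MAGs are called on mtxB alone
#' (the best single marker gene), matching the bacterial screening design
#' in which only mtxB references are queried at a stricter bitscore.
#'
#' @param assignments assignment rows for one MAG.
#' @param domain "archaeal" or "bacterial".
#' @param mts_require_both require both mtsA and mtsB for the two-part
#'   methyl-sulfide route (default FALSE: either one suffices).
#' @return List: \code{is_methylotroph}, \code{trace} (fired rules).
#' @export
call_methylotrophy <- function(assignments, domain = c("archaeal", "bacterial"),
                               mts_require_both = FALSE) {
  domain <- match.arg(domain)
  trace <- character(0)
  if (nrow(assignments) == 0)
    return(list(is_methylotroph = FALSE, trace = "no methylotrophy genes"))
  roles <- unique(assignments$role)
  if (domain == "bacterial") {
    verdict <- "MtxB" %in% roles
    trace <- sprintf("bacterial rule: mtxB homolog present = %s", verdict)
    return(list(is_methylotroph = verdict, trace = trace))
  }
  core <- sum(c("MtxB", "MtxC", "MtxA") %in% roles)
  core_route <- core >= 2 && "MtxB" %in% roles
  if (core_route)
    trace <- c(trace, sprintf(
      "core completeness: %d of MtxB/MtxC/MtxA present incl. mtxB", core))
  fused <- any(assignments$role == "MtsFused")
  if (fused)
    trace <- c(trace, "methyl-S route: tri-functional MtsD/F/H gene present")
  st <- tolower(assignments$subtype)
  mts_two <- if (mts_require_both)
    all(c("mtsa", "mtsb") %in% st) else any(st %in% c("mtsa", "mtsb"))
  if (mts_two)
    trace <- c(trace, "methyl-S route: mtsA/mtsB present")
  verdict <- core_route || fused || mts_two
  if (!verdict)
    trace <- c(trace, sprintf(
      "not methylotrophic: roles present {%s} fail completeness rules",
      paste(sort(roles), collapse = ",")))
  list(is_methylotroph = verdict, trace = trace)
}

#' Substrate profile of a MAG
#'
#' Union of substrate categories over non-ambiguous substrate-demethylating
#' assignments (role MtxB, fused MtsD/F/H genes, and the two-part
#' methyl-sulfide mtsA/mtsB). RamX activases and substrate-ambiguous
#' MtxA/MtxC genes are never used to infer substrate specificity.
#'
#' @param assignments assignment rows for one MAG.
#' @return Character vector: subset of methyl_N/methyl_O/methyl_S (sorted).
#' @export
substrate_profile <- function(assignments) {
  if (nrow(assignments) == 0) return(character(0))
  use <- (assignments$role %in% c("MtxB", "MtsFused") |
            .is_mts_single(assignments)) &
    assignments$substrate != "ambiguous" &
    assignments$role != "RamX"
  sort(unique(assignments$substrate[use]))
}

#' Lifestyle of a methanogen
#'
#' @param pathways the MAG's methanogenic pathway set (subset of
#'   hydrogenotrophic/acetoclastic/methylotrophic).
#' @param is_methanogen must be TRUE; lifestyle is undefined otherwise.
#' @return "obligate_methylotroph" when methylotrophy is the only encoded
#'   pathway, "facultative_methylotroph" when methylotrophy co-occurs with
#'   at least one other pathway, "non_methylotroph" otherwise.
#' @export
classify_lifestyle <- function(pathways, is_methanogen = TRUE) {
  if (!is_methanogen)
    stop("lifestyle classification applies only to methanogens", call. = FALSE)
  if (!"methylotrophic" %in% pathways) return("non_methylotroph")
  if (length(pathways) == 1L) "obligate_methylotroph"
  else "facultative_methylotroph"
}

.gtdb_domain <- function(gtdb) {
  ifelse(grepl("d__Archaea", gtdb), "archaeal",
         ifelse(grepl("d__Bacteria", gtdb), "bacterial", NA_character_))
}

.gtdb_order <- function(gtdb) {
  out <- rep(NA_character_, length(gtdb))
  hit <- grepl("o__", gtdb)
  out[hit] <- sub("^.*o__([^;]*).*$", "\\1", gtdb[hit])
  out
}

#' Per-MAG physiology summary
#'
#' Combines methanogen marker typing, the methylotrophy verdict, the
#' substrate profile, and lifestyle into one table with a complete rule
#' trace per MAG. The MAG universe is the taxonomy table; MAGs without
#' methylotrophy gene assignments are still classified (as
#' non-methylotrophs).
#'
#' @param assignments assignment data.frame (all MAGs).
#' @param annotations annotation data.frame (mag_id, gene_id, gene_symbol).
#' @param taxonomy data.frame (mag_id, gtdb) with GTDB-style strings
#'   ("d__Archaea;...;o__Methanobacteriales;...").
#' @param cfg a [marker_config()].
#' @return List: \code{physiology} data.frame (mag_id, domain, order,
#'   is_methanogen, pathways ";"-joined, is_methylotroph,
#'   substrate_profile ";"-joined, lifestyle) and \code{traces} (named list
#'   of fired-rule character vectors, JSON-serializable).
#' @export
classify_mags <- function(assignments, annotations, taxonomy,
                          cfg = marker_config()) {
  stopifnot(all(c("mag_id", "gtdb") %in% names(taxonomy)))
  rows <- vector("list", nrow(taxonomy))
  traces <- list()
  for (i in seq_len(nrow(taxonomy))) {
    mag <- taxonomy$mag_id[i]
    domain <- .gtdb_domain(taxonomy$gtdb[i])
    ord <- .gtdb_order(taxonomy$gtdb[i])
    asg <- assignments[assignments$mag_id == mag, , drop = FALSE]
    mg <- classify_methanogen(annotations, mag, cfg)
    ml <- call_methylotrophy(asg, domain = if (is.na(domain)) "archaeal" else domain)
    pathways <- mg$pathways
    if (mg$is_methanogen && ml$is_methylotroph)
      pathways <- c(pathways, "methylotrophic")
    profile <- substrate_profile(asg)
    lifestyle <- if (mg$is_methanogen)
      classify_lifestyle(pathways, TRUE) else NA_character_
    trace <- c(mg$trace, ml$trace,
               sprintf("substrate profile: {%s}", paste(profile, collapse = ",")),
               sprintf("lifestyle: %s", lifestyle))
    rows[[i]] <- data.frame(
      mag_id = mag, domain = domain, order = ord,
      is_methanogen = mg$is_methanogen,
      pathways = paste(sort(pathways), collapse = ";"),
      is_methylotroph = ml$is_methylotroph,
      substrate_profile = paste(profile, collapse = ";"),
      lifestyle = lifestyle, stringsAsFactors = FALSE)
    traces[[mag]] <- trace
  }
  physiology <- do.call(rbind, rows)
  rownames(physiology) <- NULL
  list(physiology = physiology, traces = traces)
}

#' Write rule traces as JSON
#' @param traces named list from [classify_mags()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_rule_traces <- function(traces, path) {
  jsonlite::write_json(traces, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
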