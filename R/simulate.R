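# Synthetic community generator: fully labeled MAG proteomes with planted
# methyltransferase operons, decoy corrinoid-binding proteins, Pyl amber
# codons, methanogenesis marker annotations, negative-binomial count
# matrices with designed activity, and depth tables with designed relative
# abundances. Every downstream stage is testable against the planted truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

#' Mutate a protein to a target identity
#'
#' Substitutes \code{round((1 - target_identity) * L)} positions, sampling
#' each replacement residue with probability proportional to its BLOSUM62
#' exchangeability with the original (\code{exp(score / 2)}, original
#' excluded), so derived sequences look like diverged homologs rather than
#' random noise. Errors when the sequence is too short for the realized
#' identity to land within 2 percent of the target.
#'
#' @param protein amino-acid string.
#' @param target_identity fraction in (0.2, 1].
#' @param seed optional integer seed (local to this call).
#' @return Mutated protein string with attribute \code{realized_identity}.
#' @export
mutate_protein <- function(protein, target_identity, seed = NULL) {
  if (target_identity <= 0.2 || target_identity > 1)
    stop("target identity must lie in (0.2, 1]", call. = FALSE)
  with_seed(seed, {
    aa <- strsplit(protein, "")[[1]]
    L <- length(aa)
    n_sub <- round((1 - target_identity) * L)
    realized <- (L - n_sub) / L
    if (abs(realized - target_identity) > 0.02)
      stop("sequence too short to realize identity ", target_identity,
           " within 2%", call. = FALSE)
    if (n_sub > 0) {
      m <- blosum62_x0()[AA20, AA20]
      pos <- sample(L, n_sub)
      for (p in pos) {
        w <- exp(m[aa[p], ] / 2)
        w[aa[p]] <- 0
        aa[p] <- sample(AA20, 1, prob = w)
      }
    }
    structure(paste(aa, collapse = ""), realized_identity = realized)
  })
}

#' Back-translate a protein under the standard genetic code
#'
#' Synonymous codons are chosen uniformly at random (codon bias is not
#' modeled; no downstream operation depends on it).
#'
#' @param protein amino-acid string (no X).
#' @param seed optional integer seed.
#' @return Nucleotide string of length \code{3 * nchar(protein)} (no stop
#'   codon appended).
#' @export
back_translate <- function(protein, seed = NULL) {
  with_seed(seed, {
    gc <- Biostrings::GENETIC_CODE
    aa <- strsplit(protein, "")[[1]]
    codons <- vapply(aa, function(a) {
      cands <- names(gc)[gc == a]
      if (!length(cands)) stop("cannot back-translate residue '", a, "'",
                               call. = FALSE)
      if (length(cands) == 1) cands else sample(cands, 1)
    }, character(1))
    paste(codons, collapse = "")
  })
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Derive a planted gene from a reference protein
#'
#' Mutates the reference to the target identity and back-translates it.
#' For Pyl genes an in-frame amber (TAG) codon is placed at
#' \code{pyl_fraction} of the protein: the "called" protein (what a
#' standard gene caller reports) is the part upstream of the amber codon,
#' the annotated CDS ends at the TAG, and the remainder of the gene plus
#' its true stop becomes downstream context, exactly the situation
#' [detect_pyl()] is designed to recognize.
#'
#' @param ref_protein reference amino-acid string.
#' @param target_identity fraction in (0.2, 1].
#' @param seed optional integer seed.
#' @param pyl_fraction NULL for an ordinary gene, else the codon fraction
#'   at which the amber codon is inserted.
#' @param context_nt random downstream context appended after the gene's
#'   true stop (default 120).
#' @return List: \code{protein} (called protein), \code{full_protein},
#'   \code{cds_with_context} (annotated CDS incl. stop + downstream),
#'   \code{cds_length} (annotated CDS length in nt), \code{pyl} (logical).
#' @export
mutate_reference <- function(ref_protein, target_identity, seed = NULL,
                             pyl_fraction = NULL, context_nt = 120L) {
  with_seed(seed, {
    full <- mutate_protein(ref_protein, target_identity)
    L <- nchar(full)
    if (is.null(pyl_fraction)) {
      cds <- paste0(back_translate(full), "TAA")
      return(list(protein = unclass(full), full_protein = unclass(full),
                  cds_with_context = paste0(cds, random_dna(context_nt)),
                  cds_length = nchar(cds), pyl = FALSE))
    }
    k <- max(2L, floor(pyl_fraction * L))
    if (k >= L - 1) stop("pyl_fraction leaves no readthrough", call. = FALSE)
    called <- substr(full, 1, k - 1)
    downstream_aa <- substr(full, k + 1, L)
    cds <- paste0(back_translate(called), "TAG")
    context <- paste0(back_translate(downstream_aa), "TAA",
                      random_dna(context_nt))
    list(protein = called, full_protein = unclass(full),
         cds_with_context = paste0(cds, context),
         cds_length = nchar(cds), pyl = TRUE)
  })
}

# ---- community design ---------------------------------------------------

.HABITATS <- c("palsa", "bog", "fen")
.DEPTHS <- c("surface", "middle", "deep")

# Gene plans per archetype. Each planted gene: reference id to mutate from,
# whether it joins the MAG's syntenic operon, and Pyl handling.
.archetypes <- function() {
  list(
    Methanomassiliicoccales_A = list(
      order = "Methanomassiliicoccales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC"),
      pathways = "methylotrophic", methylotroph = TRUE,
      operon = c("mttB_pyl_1", "mttC_1", "mtbA_1", "ramA_1"),
      standalone = "mtsD_1", pyl_genes = "mttB_pyl_1",
      substrates = c("methyl_N", "methyl_S")),
    Methanomassiliicoccales_B = list(
      order = "Methanomassiliicoccales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC"),
      pathways = "methylotrophic", methylotroph = TRUE,
      operon = c("mttB_pyl_2", "mttC_2", "mtbA_2", "ramA_2"),
      standalone = c("mtaB_1", "mtaC_1"), pyl_genes = "mttB_pyl_2",
      substrates = c("methyl_N", "methyl_O")),
    Methanomassiliicoccales_C = list(
      order = "Methanomassiliicoccales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC"),
      pathways = "methylotrophic", methylotroph = TRUE,
      operon = character(0), standalone = "mtsD_1", pyl_genes = character(0),
      substrates = "methyl_S"),
    Methanobacteriales = list(
      order = "Methanobacteriales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                  "fwdA", "fwdB", "mtd", "mer", "frhA", "frhB"),
      pathways = c("hydrogenotrophic", "methylotrophic"), methylotroph = TRUE,
      operon = c("mtaB_2", "mtaC_2", "mtaA_1", "ramM_1"),
      standalone = character(0), pyl_genes = character(0),
      substrates = "methyl_O"),
    Methanosarcinales = list(
      order = "Methanosarcinales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                  "fwdA", "fwdB", "mtd", "mer", "frhA", "frhB",
                  "ackA", "pta", "cdhA", "cdhB", "cdhC"),
      pathways = c("acetoclastic", "hydrogenotrophic", "methylotrophic"),
      methylotroph = TRUE,
      operon = c("mtaB_3", "mtaC_3", "mtaA_2"),
      standalone = c("mtvB_1", "mtvC_1"), pyl_genes = character(0),
      substrates = "methyl_O"),
    Methanoflorens = list(
      order = "Methanomicrobiales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                  "fwdA", "fwdB", "mtd", "mer", "frhA", "frhB"),
      pathways = "hydrogenotrophic", methylotroph = FALSE,
      operon = character(0), standalone = character(0),
      pyl_genes = character(0), substrates = character(0)),
    Methanotrichales = list(
      order = "Methanotrichales", domain = "archaeal",
      markers = c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                  "ackA", "pta", "cdhA", "cdhB", "cdhC", "cdhD"),
      pathways = "acetoclastic", methylotroph = FALSE,
      operon = character(0), standalone = character(0),
      pyl_genes = character(0), substrates = character(0)),
    Proteobacteria = list(
      order = "Burkholderiales", domain = "bacterial",
      markers = character(0), pathways = character(0), methylotroph = TRUE,
      operon = character(0), standalone = "mttB_nonpyl_1",
      pyl_genes = character(0), substrates = "methyl_N"),
    Actinobacteriota = list(
      order = "Mycobacteriales", domain = "bacterial",
      markers = character(0), pathways = character(0), methylotroph = TRUE,
      operon = character(0), standalone = c("mttB_pyl_3", "mtaB_4"),
      pyl_genes = "mttB_pyl_3", substrates = c("methyl_N", "methyl_O")),
    Acidobacteriota = list(
      order = "Acidobacteriales", domain = "bacterial",
      markers = character(0), pathways = character(0), methylotroph = TRUE,
      operon = character(0), standalone = "mtaB_5",
      pyl_genes = character(0), substrates = "methyl_O"))
}

#' Default synthetic community design
#'
#' A 30-MAG community emulating the study's structure: obligate
#' methylotrophic Methanomassiliicoccales (methylamine operons with Pyl
#' mttB, fused methyl-sulfide genes), facultative Methanobacteriales
#' (hydrogenotrophic + methanol) and Methanosarcinales (all three pathways,
#' methanol + methoxy genes), hydrogenotrophic and acetoclastic
#' non-methylotrophs, and three methylotrophic bacteria (non-Pyl mttB
#' Proteobacteria, Pyl mttB Actinobacteriota, methanol-specific
#' Acidobacteriota). Designed relative abundances per habitat x depth group
#' sum to 1 over the community; methanogens are absent (abundance 0) from
#' palsa. A subset of methylotrophs is designated transcriptionally
#' inactive so activity-label recovery is non-trivial.
#'
#' @param seed integer seed; fully determines the design.
#' @return List of class \code{methyloscan_design}: \code{mags} (per-MAG
#'   plan and truth), \code{abundance} (MAG x group matrix, columns sum to
#'   1), \code{groups}, \code{identity_range}, \code{pyl_fraction},
#'   \code{n_decoys}, \code{decoy_identity_range}, \code{seed}.
#' @export
default_community_design <- function(seed = 1L) {
  arche <- .archetypes()
  plan <- c("Methanomassiliicoccales_A", "Methanomassiliicoccales_B",
            "Methanomassiliicoccales_C",
            rep("Methanobacteriales", 8),
            rep("Methanosarcinales", 4),
            rep("Methanoflorens", 6),
            rep("Methanoflorens", 3),
            rep("Methanotrichales", 3),
            "Proteobacteria", "Actinobacteriota", "Acidobacteriota")
  active_plan <- c(TRUE, TRUE, TRUE,                 # Methanomassiliicoccales
                   rep(c(TRUE, TRUE, TRUE, FALSE), 2),  # Methanobacteriales
                   TRUE, TRUE, TRUE, FALSE,          # Methanosarcinales
                   rep(NA, 12),                      # non-methylotrophs
                   TRUE, TRUE, TRUE)                 # bacteria
  mags <- data.frame(mag_id = sprintf("MAG%02d", seq_along(plan)),
                     archetype = plan, stringsAsFactors = FALSE)
  mags$order <- vapply(plan, function(a) arche[[a]]$order, character(1))
  mags$domain <- vapply(plan, function(a) arche[[a]]$domain, character(1))
  mags$is_methanogen <- mags$domain == "archaeal"
  mags$methylotroph <- vapply(plan, function(a) arche[[a]]$methylotroph,
                              logical(1))
  mags$pathways <- vapply(seq_along(plan), function(i) {
    p <- arche[[plan[i]]]$pathways
    if (!mags$is_methanogen[i]) return("")
    paste(sort(p), collapse = ";")
  }, character(1))
  mags$lifestyle <- ifelse(!mags$is_methanogen, NA_character_,
    ifelse(!mags$methylotroph, "non_methylotroph",
      ifelse(mags$pathways == "methylotrophic", "obligate_methylotroph",
             "facultative_methylotroph")))
  mags$substrate_profile <- vapply(plan, function(a)
    paste(sort(arche[[a]]$substrates), collapse = ";"), character(1))
  mags$active <- active_plan
  mags$gtdb <- sprintf("d__%s;p__synthetic;c__synthetic;o__%s;f__f%s;g__g%s;s__",
                       ifelse(mags$domain == "archaeal", "Archaea", "Bacteria"),
                       mags$order, mags$mag_id, mags$mag_id)

  groups <- as.vector(outer(.HABITATS, .DEPTHS, paste, sep = "_"))
  abundance <- with_seed(seed, {
    # 1 + gamma keeps every present MAG well above the count floor at the
    # default sequencing-depth factor, so designed-active labels are
    # recoverable by construction
    ab <- matrix(1 + stats::rgamma(nrow(mags) * length(groups), shape = 2),
                 nrow = nrow(mags),
                 dimnames = list(mags$mag_id, groups))
    palsa <- grepl("^palsa_", colnames(ab))
    ab[mags$is_methanogen, palsa] <- 0
    sweep(ab, 2, colSums(ab), "/")
  })

  structure(list(mags = mags, abundance = abundance, groups = groups,
                 archetypes = arche,
                 identity_range = c(0.68, 0.85), pyl_fraction = 0.6,
                 n_decoys = 2L, decoy_identity_range = c(0.30, 0.45),
                 seed = as.integer(seed)),
            class = "methyloscan_design")
}

# ---- community construction --------------------------------------------

#' Build a fully labeled synthetic community
#'
#' Realizes a design as sequence data: per-MAG proteomes with planted
#' methyltransferase genes derived from catalog references at controlled
#' identity (syntenic operon members laid out adjacently on one contig),
#' decoy proteins (random sequences plus low-identity mutants of
#' corrinoid-binding MtxC references, the documented nonspecific-hit
#' stressor), Pyl genes with in-frame amber codons and downstream
#' readthrough context, marker-gene annotations matching the planted
#' pathways, a GTDB-style taxonomy table, and gene/MAG truth labels.
#'
#' @param design a [default_community_design()].
#' @param catalog reference catalog to mutate genes from (needs the fused
#'   methyl-sulfide supplement).
#' @param seed integer seed; with the design seed, fully determines output.
#' @return List of class \code{methyloscan_community}; see Details in the
#'   package vignette. Key elements: \code{proteome}, \code{cds},
#'   \code{cds_length}, \code{gene_coords}, \code{annotations},
#'   \code{taxonomy}, \code{truth_mags}, \code{truth_genes}, \code{genes}.
#' @export
build_community <- function(design = default_community_design(),
                            catalog = default_catalog(include_fused = TRUE),
                            seed = design$seed) {
  ref_seq <- setNames(catalog$genes$sequence, catalog$genes$id)
  ref_role <- setNames(catalog$genes$role, catalog$genes$id)
  ref_cat <- setNames(catalog$genes$substrate_category, catalog$genes$id)
  ref_sub <- setNames(catalog$genes$substrate_subtype, catalog$genes$id)
  # decoy source: corrinoid-binding MtxC references, excluding mtsB -- an
  # mtsB homolog is by itself methylotrophy evidence under the methyl-S
  # rule, so a "decoy" derived from it would be a planted positive
  mtxc_refs <- catalog$genes$id[catalog$genes$role == "MtxC" &
                                  tolower(catalog$genes$substrate_subtype) !=
                                    "mtsb"]

  proteome <- character(0); cds <- character(0); cds_len <- integer(0)
  coords <- list(); ann <- list(); tg <- list(); genes <- list()

  with_seed(seed, {
    for (i in seq_len(nrow(design$mags))) {
      mag <- design$mags$mag_id[i]
      a <- design$archetypes[[design$mags$archetype[i]]]
      gene_n <- 0L
      new_gene <- function() {
        gene_n <<- gene_n + 1L
        sprintf("%s_gene%d", mag, gene_n)
      }
      # contig 1: housekeeping + markers + operon
      c1 <- sprintf("%s_contig1", mag)
      pos <- 1L
      place <- function(contig, len_nt) {
        st <- pos; pos <<- pos + len_nt + 50L
        c(st, st + len_nt - 1L)
      }
      add_marker <- function(symbol, contig) {
        g <- new_gene(); se <- place(contig, 900L)
        coords[[g]] <<- data.frame(gene_id = g, contig = contig,
                                   start = se[1], end = se[2], strand = "+",
                                   stringsAsFactors = FALSE)
        ann[[g]] <<- data.frame(mag_id = mag, gene_id = g,
                                gene_symbol = symbol, stringsAsFactors = FALSE)
        genes[[g]] <<- data.frame(gene_id = g, mag_id = mag, type = "marker",
                                  length_nt = 900L, stringsAsFactors = FALSE)
      }
      add_planted <- function(ref_id, contig, syntenic) {
        g <- new_gene()
        pyl <- ref_id %in% a$pyl_genes
        ident <- runif(1, design$identity_range[1], design$identity_range[2])
        mut <- mutate_reference(ref_seq[[ref_id]], ident,
                                pyl_fraction = if (pyl) design$pyl_fraction)
        se <- place(contig, mut$cds_length)
        proteome[g] <<- mut$protein
        cds[g] <<- mut$cds_with_context
        cds_len[g] <<- mut$cds_length
        coords[[g]] <<- data.frame(gene_id = g, contig = contig,
                                   start = se[1], end = se[2], strand = "+",
                                   stringsAsFactors = FALSE)
        ann[[g]] <<- data.frame(mag_id = mag, gene_id = g,
                                gene_symbol = sub("_[0-9]+$", "", ref_id),
                                stringsAsFactors = FALSE)
        genes[[g]] <<- data.frame(gene_id = g, mag_id = mag,
                                  type = "methylotrophy",
                                  length_nt = mut$cds_length,
                                  stringsAsFactors = FALSE)
        tg[[g]] <<- data.frame(gene_id = g, mag_id = mag, ref_id = ref_id,
                               role = ref_role[[ref_id]],
                               substrate = ref_cat[[ref_id]],
                               subtype_family = ref_sub[[ref_id]],
                               pyl = pyl, syntenic = syntenic,
                               target_identity = ident,
                               stringsAsFactors = FALSE)
      }
      add_decoy <- function(contig, mtxc_derived) {
        g <- new_gene()
        p <- if (mtxc_derived) {
          src <- sample(mtxc_refs, 1)
          unclass(mutate_protein(ref_seq[[src]],
                                 runif(1, design$decoy_identity_range[1],
                                       design$decoy_identity_range[2])))
        } else random_protein(250L)
        se <- place(contig, 3L * nchar(p) + 3L)
        proteome[g] <<- p
        coords[[g]] <<- data.frame(gene_id = g, contig = contig,
                                   start = se[1], end = se[2], strand = "+",
                                   stringsAsFactors = FALSE)
        ann[[g]] <<- data.frame(mag_id = mag, gene_id = g,
                                gene_symbol = "hypothetical",
                                stringsAsFactors = FALSE)
        genes[[g]] <<- data.frame(gene_id = g, mag_id = mag, type = "decoy",
                                  length_nt = 3L * nchar(p) + 3L,
                                  stringsAsFactors = FALSE)
      }

      add_marker("rpoB", c1)
      for (s in a$markers) add_marker(s, c1)
      for (r in a$operon) add_planted(r, c1, syntenic = TRUE)
      # contig 2: standalone planted genes separated by decoys/markers
      c2 <- sprintf("%s_contig2", mag)
      pos <- 1L
      add_marker("gyrB", c2)
      for (r in a$standalone) {
        add_planted(r, c2, syntenic = FALSE)
        add_marker("hypA", c2)  # spacer so standalones never cluster
        add_marker("hypB", c2)
        add_marker("hypC", c2)
      }
      add_decoy(c2, mtxc_derived = TRUE)
      for (k in seq_len(design$n_decoys)) add_decoy(c2, mtxc_derived = FALSE)
    }
  })

  empty_coords <- data.frame(gene_id = character(0), contig = character(0),
                             start = integer(0), end = integer(0),
                             strand = character(0), stringsAsFactors = FALSE)
  empty_truth <- data.frame(gene_id = character(0), mag_id = character(0),
                            ref_id = character(0), role = character(0),
                            substrate = character(0),
                            subtype_family = character(0), pyl = logical(0),
                            syntenic = logical(0),
                            target_identity = numeric(0),
                            stringsAsFactors = FALSE)
  rbind_or <- function(lst, fallback)
    if (length(lst)) do.call(rbind, unname(lst)) else fallback
  structure(list(
    design = design,
    proteome = proteome, cds = cds, cds_length = cds_len,
    gene_coords = rbind_or(coords, empty_coords),
    annotations = rbind_or(ann, data.frame(mag_id = character(0),
                                           gene_id = character(0),
                                           gene_symbol = character(0),
                                           stringsAsFactors = FALSE)),
    taxonomy = data.frame(mag_id = design$mags$mag_id,
                          gtdb = design$mags$gtdb, stringsAsFactors = FALSE),
    truth_mags = design$mags[, c("mag_id", "domain", "order", "is_methanogen",
                                 "pathways", "methylotroph", "lifestyle",
                                 "substrate_profile", "active")],
    truth_genes = rbind_or(tg, empty_truth),
    genes = rbind_or(genes, data.frame(gene_id = character(0),
                                       mag_id = character(0),
                                       type = character(0),
                                       length_nt = integer(0),
                                       stringsAsFactors = FALSE))),
    class = "methyloscan_community")
}

#' Write a synthetic community to disk
#'
#' Emits the file formats the pipeline consumes: \code{proteins.faa},
#' \code{cds_with_context.fna}, \code{genes.gff3}, \code{annotations.tsv},
#' \code{taxonomy.tsv}, and the truth tables
#' \code{truth_mags.tsv} / \code{truth_genes.tsv}.
#'
#' @param community a \code{methyloscan_community}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(community$proteome, file.path(dir, "proteins.faa"))
  cds_named <- setNames(community$cds,
                        sprintf("%s cds_length=%d", names(community$cds),
                                community$cds_length[names(community$cds)]))
  write_fasta(cds_named, file.path(dir, "cds_with_context.fna"))
  write_gff3(community$gene_coords, file.path(dir, "genes.gff3"))
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(community$annotations, "annotations.tsv")
  tsv(community$taxonomy, "taxonomy.tsv")
  tsv(community$truth_mags, "truth_mags.tsv")
  tsv(community$truth_genes, "truth_genes.tsv")
  invisible(dir)
}

# ---- count and depth simulation ----------------------------------------

#' Simulate metatranscriptome counts and metagenome depth tables
#'
#' Counts are negative binomial with per-gene group means proportional to
#' designed expression level x the MAG's designed relative abundance x a
#' sequencing-depth factor; methylotrophy genes of designed-inactive MAGs
#' (and decoys) have mean 0. Depth vectors are drawn so each MAG's
#' trimmed-mean coverage matches its designed abundance times a coverage
#' scale. \code{noise = "none"} replaces sampling with expectations for
#' exact-recovery checks.
#'
#' @param community a \code{methyloscan_community}.
#' @param noise "default" (negative-binomial counts, jittered depths) or
#'   "none".
#' @param n_rep replicates per habitat x depth group (field design: 3).
#' @param dispersion negative-binomial size parameter.
#' @param depth_factor sequencing-depth multiplier for count means.
#' @param expr_methylotrophy,expr_background designed expression levels for
#'   methylotrophy genes of active MAGs and for marker/housekeeping genes.
#' @param coverage_scale designed trimmed-mean coverage of a MAG with
#'   relative abundance 1.
#' @param n_positions positions per depth vector.
#' @param seed integer seed.
#' @return List: \code{counts} (genes x samples), \code{lengths} (bp),
#'   \code{sample_design} (sample, habitat, depth, replicate, group),
#'   \code{depths} (list MAG -> positions x samples matrix),
#'   \code{truth_activity} (data.frame mag_id, active).
#' @export
simulate_counts <- function(community, noise = c("default", "none"),
                            n_rep = 3L, dispersion = 3,
                            depth_factor = 12, expr_methylotrophy = 150,
                            expr_background = 60, coverage_scale = 100,
                            n_positions = 150L, seed = NULL) {
  noise <- match.arg(noise)
  design <- community$design
  mags <- design$mags
  groups <- design$groups
  samples <- as.vector(t(outer(groups, seq_len(n_rep),
                               function(g, r) paste0(g, "_r", r))))
  sample_group <- rep(groups, each = n_rep)
  gene_tab <- community$genes
  active <- setNames(mags$active, mags$mag_id)
  expr_level <- ifelse(
    gene_tab$type == "methylotrophy",
    ifelse(is.na(active[gene_tab$mag_id]) | !active[gene_tab$mag_id],
           0, expr_methylotrophy),
    ifelse(gene_tab$type == "decoy", 0, expr_background))
  mu <- outer(seq_len(nrow(gene_tab)), seq_along(samples),
              function(i, j) expr_level[i] *
                design$abundance[cbind(gene_tab$mag_id[i], sample_group[j])] *
                depth_factor)
  dimnames(mu) <- list(gene_tab$gene_id, samples)

  out <- with_seed(seed, {
    counts <- if (noise == "none") round(mu) else
      matrix(rnbinom(length(mu), mu = mu, size = dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    depths <- lapply(setNames(mags$mag_id, mags$mag_id), function(m) {
      target <- design$abundance[m, sample_group] * coverage_scale
      d <- if (noise == "none")
        matrix(rep(target, each = n_positions), nrow = n_positions)
      else
        matrix(pmax(0, rnorm(n_positions * length(samples),
                             mean = rep(target, each = n_positions),
                             sd = rep(0.05 * target + 1e-9,
                                      each = n_positions))),
               nrow = n_positions)
      colnames(d) <- samples
      d
    })
    list(counts = counts, depths = depths)
  })

  list(counts = out$counts,
       lengths = setNames(gene_tab$length_nt, gene_tab$gene_id),
       sample_design = data.frame(
         sample = samples,
         habitat = sub("_.*$", "", sample_group),
         depth = sub("_r[0-9]+$", "", sub("^[a-z]+_", "", samples)),
         replicate = as.integer(sub("^.*_r", "", samples)),
         group = sample_group, stringsAsFactors = FALSE),
       depths = out$depths,
       truth_activity = data.frame(mag_id = mags$mag_id, active = mags$active,
                                   stringsAsFactors = FALSE))
}

#' Trimmed-mean coverage table from simulated depths
#'
#' @param depths list MAG -> positions x samples depth matrix.
#' @param params a [normalization_params()].
#' @return MAG x sample trimmed-mean coverage matrix.
#' @export
coverage_table <- function(depths, params = normalization_params()) {
  out <- t(vapply(depths, function(d)
    apply(d, 2, trimmed_mean_coverage, params = params),
    numeric(ncol(depths[[1]]))))
  rownames(out) <- names(depths)
  out
}
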