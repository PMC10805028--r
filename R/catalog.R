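#' @importFrom stats rnbinom rnorm runif quantile cor setNames
#' @importFrom utils read.delim write.table data
NULL

# Enumerations shared across the package.
SYSTEM_ROLES <- c("MtxB", "MtxC", "MtxA", "RamX", "MtsFused")
SUBSTRATE_CATEGORIES <- c("methyl_N", "methyl_O", "methyl_S", "ambiguous")
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.validate_protein <- function(x, id = "<sequence>") {
  if (is.na(x) || !nzchar(x))
    stop("protein sequence for '", id, "' is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(toupper(x), "")[[1]]), c(AA20, "X"))
  if (length(bad))
    stop("protein sequence for '", id, "' contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Load a methylotrophy reference catalog
#'
#' Reads a curated set of methyltransferase-system reference proteins
#' (substrate:corrinoid methyltransferases MtxB, corrinoid-binding proteins
#' MtxC, methylcorrinoid:carrier methyltransferases MtxA, reductive
#' activases RamX, and tri-functional fused methyl-sulfide MtsD/F/H
#' homologs) from a protein FASTA plus a tab-separated metadata table with
#' columns \code{id}, \code{role}, \code{substrate_category},
#' \code{substrate_subtype} and \code{source_note}.
#'
#' FASTA record ids (first whitespace-delimited token) must match metadata
#' rows one-to-one. Reference proteins with role \code{RamX} must carry the
#' \code{ambiguous} substrate category: activases are promiscuous across
#' corrinoid proteins and are never used to infer substrate specificity.
#'
#' @param fasta_path path to the reference protein FASTA.
#' @param metadata_path path to the TSV metadata table.
#' @return An object of class \code{methyloscan_catalog}: a list with
#'   \code{genes} (metadata data.frame with a \code{sequence} column) and
#'   \code{n} (number of reference gene types).
#' @seealso [default_catalog()], [role_counts()], [write_catalog()]
#' @export
load_catalog <- function(fasta_path, metadata_path) {
  meta <- read.delim(metadata_path, colClasses = "character",
                     stringsAsFactors = FALSE)
  needed <- c("id", "role", "substrate_category", "substrate_subtype",
              "source_note")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols))
    stop("catalog metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  seqs <- read_fasta(fasta_path)

  dup <- unique(c(names(seqs)[duplicated(names(seqs))],
                  meta$id[duplicated(meta$id)]))
  if (length(dup))
    stop("duplicate reference id(s) in catalog: ",
         paste(dup, collapse = ", "), call. = FALSE)

  no_seq <- setdiff(meta$id, names(seqs))
  if (length(no_seq))
    stop("metadata row(s) without a FASTA sequence: ",
         paste(no_seq, collapse = ", "), call. = FALSE)
  no_meta <- setdiff(names(seqs), meta$id)
  if (length(no_meta))
    stop("FASTA record(s) without a metadata row: ",
         paste(no_meta, collapse = ", "), call. = FALSE)

  bad_role <- setdiff(unique(meta$role), SYSTEM_ROLES)
  if (length(bad_role))
    stop("unknown system role token(s): ", paste(bad_role, collapse = ", "),
         "; expected one of ", paste(SYSTEM_ROLES, collapse = ", "),
         call. = FALSE)
  bad_cat <- setdiff(unique(meta$substrate_category), SUBSTRATE_CATEGORIES)
  if (length(bad_cat))
    stop("unknown substrate category token(s): ",
         paste(bad_cat, collapse = ", "), call. = FALSE)

  amb <- meta$substrate_category == "ambiguous"
  if (any(amb & nzchar(meta$substrate_subtype)))
    stop("ambiguous-category reference(s) must not carry a subtype: ",
         paste(meta$id[amb & nzchar(meta$substrate_subtype)], collapse = ", "),
         call. = FALSE)
  ram <- meta$role == "RamX"
  if (any(ram & meta$substrate_category != "ambiguous"))
    stop("RamX reference(s) must carry the ambiguous substrate category: ",
         paste(meta$id[ram & meta$substrate_category != "ambiguous"],
               collapse = ", "), call. = FALSE)

  meta$sequence <- unname(seqs[meta$id])
  for (i in seq_len(nrow(meta)))
    .validate_protein(meta$sequence[i], meta$id[i])

  structure(list(genes = meta, n = nrow(meta)),
            class = "methyloscan_catalog")
}

#' Write a reference catalog back to FASTA + metadata TSV
#'
#' @param catalog a \code{methyloscan_catalog}.
#' @param fasta_path,metadata_path output paths.
#' @return Invisibly, the catalog.
#' @export
write_catalog <- function(catalog, fasta_path, metadata_path) {
  stopifnot(inherits(catalog, "methyloscan_catalog"))
  g <- catalog$genes
  write_fasta(setNames(g$sequence, g$id), fasta_path)
  write.table(g[, c("id", "role", "substrate_category", "substrate_subtype",
                    "source_note")],
              metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(catalog)
}

#' Count catalog reference types by system role
#'
#' @param catalog a \code{methyloscan_catalog}.
#' @return Named integer vector over MtxB, MtxC, MtxA, RamX, MtsFused.
#' @export
role_counts <- function(catalog) {
  stopifnot(inherits(catalog, "methyloscan_catalog"))
  out <- setNames(integer(length(SYSTEM_ROLES)), SYSTEM_ROLES)
  tab <- table(catalog$genes$role)
  out[names(tab)] <- as.integer(tab)
  out
}

#' The packaged reference catalog
#'
#' Loads the catalog shipped with the package: a synthetic stand-in with the
#' composition of the curated set used for MAG screening (20 MtxB, 16 MtxC,
#' 10 MtxA and 7 RamX reference gene types, 53 in total). The shipped
#' sequences are generated family-by-family from seeded random ancestors --
#' they reproduce the catalog's role/substrate composition and its
#' within-family sequence structure, not the actual curated proteins, and a
#' user-supplied curated FASTA + metadata table can be loaded with
#' [load_catalog()] instead. \code{include_fused = TRUE} appends three
#' tri-functional methyl-sulfide (MtsD/F/H, role \code{MtsFused}) reference
#' types shipped as a supplement so the fused-gene methyl-S route can be
#' screened.
#'
#' @param include_fused append the MtsD/F/H fused-gene supplement?
#' @return A \code{methyloscan_catalog}.
#' @export
default_catalog <- function(include_fused = FALSE) {
  core <- load_catalog(
    system.file("extdata", "synthetic_reference_catalog.faa",
                package = "methyloscan"),
    system.file("extdata", "synthetic_reference_catalog.tsv",
                package = "methyloscan"))
  if (!include_fused) return(core)
  fused <- load_catalog(
    system.file("extdata", "synthetic_reference_catalog_mts_fused.faa",
                package = "methyloscan"),
    system.file("extdata", "synthetic_reference_catalog_mts_fused.tsv",
                package = "methyloscan"))
  structure(list(genes = rbind(core$genes, fused$genes),
                 n = core$n + fused$n),
            class = "methyloscan_catalog")
}

#' @export
print.methyloscan_catalog <- function(x, ...) {
  cat("methylotrophy reference catalog:", x$n, "gene types\n")
  rc <- role_counts(x)
  cat(paste0("  ", names(rc), ": ", rc, collapse = "\n"), "\n")
  invisible(x)
}

# ---- substrate chemistry -----------------------------------------------

#' Load a substrate chemistry table
#'
#' A TSV with columns \code{name}, \code{category} and
#' \code{methyl_equivalents} (non-negative integer count of microbially
#' available methyl groups per molecule, identified by structural
#' inspection).
#'
#' @param path TSV path.
#' @return data.frame with validated columns.
#' @export
load_chem_table <- function(path) {
  chem <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "category", "methyl_equivalents")
  if (!all(needed %in% names(chem)))
    stop("chemistry table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  bad_cat <- setdiff(unique(chem$category), SUBSTRATE_CATEGORIES)
  if (length(bad_cat))
    stop("unknown substrate category in chemistry table: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  me <- chem$methyl_equivalents
  if (any(is.na(me)) || any(me < 0) || any(me != round(me)))
    stop("methyl_equivalents must be non-negative integers", call. = FALSE)
  chem$methyl_equivalents <- as.integer(me)
  chem
}

#' The packaged substrate chemistry table
#' @return data.frame (name, category, methyl_equivalents).
#' @export
default_chem_table <- function() {
  load_chem_table(system.file("extdata", "substrate_chemistry.tsv",
                              package = "methyloscan"))
}

#' Microbially available methyl groups on a substrate
#'
#' @param substrate_name compound name as it appears in the chemistry table
#'   (case-insensitive).
#' @param chem_table chemistry table; defaults to the packaged one.
#' @return Integer count of methyl groups (e.g. 1 for methanol, 3 for
#'   trimethylamine).
#' @export
methyl_equivalents <- function(substrate_name, chem_table = default_chem_table()) {
  if (length(substrate_name) != 1L || is.na(substrate_name) ||
      !nzchar(substrate_name))
    stop("substrate name must be a single non-empty string; known substrates: ",
         paste(chem_table$name, collapse = ", "), call. = FALSE)
  i <- match(tolower(substrate_name), tolower(chem_table$name))
  if (is.na(i))
    stop("unknown substrate '", substrate_name, "'; known substrates: ",
         paste(chem_table$name, collapse = ", "), call. = FALSE)
  chem_table$methyl_equivalents[i]
}

#' Relative CH4 yield between two methylotrophic substrates
#'
#' One molar equivalent of substrate \code{a} can support
#' \code{methyl_equivalents(a) / methyl_equivalents(b)} times as much CH4
#' as one molar equivalent of substrate \code{b}, since each microbially
#' available methyl group can be reduced to one CH4.
#'
#' @param a,b substrate names.
#' @param chem_table chemistry table.
#' @return Numeric ratio.
#' @export
ch4_yield_ratio <- function(a, b, chem_table = default_chem_table()) {
  ma <- methyl_equivalents(a, chem_table)
  mb <- methyl_equivalents(b, chem_table)
  if (mb == 0)
    stop("substrate '", b, "' has zero methyl equivalents; ratio undefined",
         call. = FALSE)
  ma / mb
}
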