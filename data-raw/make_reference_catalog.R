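# Generates the packaged synthetic reference catalog: a composition-faithful
# stand-in for a curated methylotrophy gene set (20 MtxB / 16 MtxC / 10 MtxA
# / 7 RamX = 53 types, plus a 3-type MtsD/F/H fused-gene supplement). Each
# subtype family is a set of seeded BLOSUM62-guided mutants of a random
# family ancestor, so within-family similarity is high and across-family
# similarity is background. Run from the package root; outputs are committed
# under inst/extdata/.

for (f in list.files("R", full.names = TRUE)) source(f)

FAMILIES <- list(
  #       prefix        role      category    subtype                         n  len
  list("mtaB",        "MtxB", "methyl_O", "mtaB methanol",                 5L, 450L),
  list("mttB_pyl",    "MtxB", "methyl_N", "mttB Pyl trimethylamine",       3L, 500L),
  list("mttB_nonpyl", "MtxB", "methyl_N", "non-Pyl mttB quaternary amine", 2L, 500L),
  list("mtbB",        "MtxB", "methyl_N", "mtbB dimethylamine",            3L, 470L),
  list("mtmB",        "MtxB", "methyl_N", "mtmB monomethylamine",          2L, 450L),
  list("mtvB",        "MtxB", "methyl_O", "methoxy mtvB",                  3L, 480L),
  list("mtsA",        "MtxB", "methyl_S", "mtsA",                          2L, 340L),
  list("mtaC",        "MtxC", "methyl_O", "mtaC methanol",                 4L, 240L),
  list("mttC",        "MtxC", "methyl_N", "mttC methylamine",              3L, 230L),
  list("mtbC",        "MtxC", "methyl_N", "mtbC methylamine",              3L, 240L),
  list("mtmC",        "MtxC", "methyl_N", "mtmC methylamine",              2L, 230L),
  list("mtvC",        "MtxC", "methyl_O", "methoxy mtvC",                  2L, 240L),
  list("mtsB",        "MtxC", "methyl_S", "mtsB",                          2L, 220L),
  list("mtaA",        "MtxA", "methyl_O", "mtaA methanol",                 4L, 330L),
  list("mtbA",        "MtxA", "methyl_N", "mtbA methylamine",              4L, 340L),
  list("mtvA",        "MtxA", "methyl_O", "methoxy mtvA",                  2L, 330L),
  list("ramA",        "RamX", "ambiguous", "",                             3L, 500L),
  list("ramM",        "RamX", "ambiguous", "",                             2L, 480L),
  list("ramS",        "RamX", "ambiguous", "",                             2L, 490L))

FUSED <- list(
  list("mtsD", "MtsFused", "methyl_S", "mtsD", 1L, 690L),
  list("mtsF", "MtsFused", "methyl_S", "mtsF", 1L, 690L),
  list("mtsH", "MtsFused", "methyl_S", "mtsH", 1L, 690L))

build <- function(fams, shared_ancestors = NULL) {
  rows <- list(); seqs <- character(0)
  ancestors <- if (is.null(shared_ancestors)) list() else shared_ancestors
  for (fam in fams) {
    prefix <- fam[[1]]; role <- fam[[2]]; cat <- fam[[3]]
    subtype <- fam[[4]]; n <- fam[[5]]; len <- fam[[6]]
    # mttB Pyl / non-Pyl homologs share one ancestor (true homolog family)
    anc_key <- if (grepl("^mttB", prefix)) "mttB" else
      if (grepl("^mts[DFH]", prefix)) "mtsDFH" else prefix
    if (is.null(ancestors[[anc_key]]))
      ancestors[[anc_key]] <- random_protein(len)
    anc <- ancestors[[anc_key]]
    for (k in seq_len(n)) {
      id <- sprintf("%s_%d", prefix, k)
      seqs[id] <- unclass(mutate_protein(anc, 0.80))
      rows[[id]] <- data.frame(
        id = id, role = role, substrate_category = cat,
        substrate_subtype = subtype,
        source_note = "synthetic stand-in: seeded BLOSUM62 mutant of a random family ancestor",
        stringsAsFactors = FALSE)
    }
  }
  list(meta = do.call(rbind, unname(rows)), seqs = seqs,
       ancestors = ancestors)
}

set.seed(20160701)
core <- build(FAMILIES)
fused <- build(FUSED, core$ancestors)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_fasta(core$seqs, "inst/extdata/synthetic_reference_catalog.faa")
write.table(core$meta, "inst/extdata/synthetic_reference_catalog.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_fasta(fused$seqs, "inst/extdata/synthetic_reference_catalog_mts_fused.faa")
write.table(fused$meta, "inst/extdata/synthetic_reference_catalog_mts_fused.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", length(core$seqs), "core +", length(fused$seqs),
    "fused reference types\n")
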