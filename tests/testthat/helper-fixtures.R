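# Small in-code fixtures shared across test files.

# a minimal valid catalog built in memory (written to temp files on demand)
toy_catalog_files <- function(entries, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  faa <- file.path(dir, "cat.faa")
  tsv <- file.path(dir, "cat.tsv")
  writeLines(unlist(lapply(seq_len(nrow(entries)), function(i)
    c(paste0(">", entries$id[i]), entries$sequence[i]))), faa)
  write.table(entries[, c("id", "role", "substrate_category",
                          "substrate_subtype", "source_note")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(faa = faa, tsv = tsv)
}

toy_entries <- function() {
  data.frame(
    id = c("mtaB_t", "mtaC_t", "ram_t"),
    role = c("MtxB", "MtxC", "RamX"),
    substrate_category = c("methyl_O", "methyl_O", "ambiguous"),
    substrate_subtype = c("mtaB methanol", "mtaC methanol", ""),
    source_note = "toy",
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "MSDNNKLVVGLDIGTTKVCAIVGEVLPDGS",
                 "MDKKQLEELKAQLIEQNRLLEEQNKELQSR"),
    stringsAsFactors = FALSE)
}

# hit-table builder for rule tests (bypasses alignment)
mk_hits <- function(gene, mag, refs, bits) {
  data.frame(query_gene_id = gene, mag_id = mag, reference_id = refs,
             raw_score = NA_real_, bitscore = bits,
             percent_identity = 80, aln_length = 100L,
             query_coverage = 0.9, stringsAsFactors = FALSE)
}

# assignment-row builder for classifier tests
mk_asg <- function(mag, role, substrate, subtype = "", gene = NULL) {
  n <- length(role)
  data.frame(
    gene_id = if (is.null(gene)) sprintf("%s_gene%d", mag, seq_len(n)) else gene,
    mag_id = mag, role = role, substrate = substrate,
    subtype = subtype, best_reference_id = "ref",
    best_bitscore = 100, margin_bits = Inf, syntenic = FALSE,
    pyl_status = "not_applicable", stringsAsFactors = FALSE)
}

# deterministic random protein over the 20 AA alphabet
rand_prot <- function(n, seed) {
  set.seed(seed)
  paste(sample(methyloscan:::AA20, n, replace = TRUE), collapse = "")
}

# a constructed mttB-like gene: full-length protein, optional amber codon
# at codon k (1-based), returns list(cds_with_context, cds_length)
constructed_pyl_gene <- function(protein, amber_at = NULL,
                                 stop_codon = "TAA", context_nt = 150,
                                 seed = 99) {
  set.seed(seed)
  nt <- back_translate(protein)
  if (is.null(amber_at)) {
    cds <- paste0(nt, stop_codon)
    ctx <- paste(sample(c("A", "C", "G", "T"), context_nt, TRUE), collapse = "")
    return(list(cds_with_context = paste0(cds, ctx), cds_length = nchar(cds)))
  }
  up <- substr(nt, 1, (amber_at - 1) * 3)
  down <- substr(nt, (amber_at) * 3 + 1, nchar(nt))
  cds <- paste0(up, stop_codon)
  list(cds_with_context = paste0(cds, down, "TAA"), cds_length = nchar(cds))
}
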