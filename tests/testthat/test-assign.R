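cat60 <- default_catalog(include_fused = TRUE)

test_that("an unopposed hit takes its reference's role and substrate", {
  a <- assign_identity(mk_hits("M_gene1", "M", "mtaB_1", 250), cat60)
  expect_equal(a$role, "MtxB")
  expect_equal(a$substrate, "methyl_O")
  expect_equal(a$subtype, "mtaB methanol")
  expect_equal(a$margin_bits, Inf)
})

test_that("cross-category margins gate the substrate call", {
  # wide margin: confident methyl_O
  h <- mk_hits("M_gene1", "M", c("mtaB_1", "mttB_pyl_1"), c(250, 100))
  a <- assign_identity(h, cat60, margin_threshold = 10)
  expect_equal(a$substrate, "methyl_O")
  expect_equal(a$margin_bits, 150)
  # narrow margin across categories: ambiguous
  h2 <- mk_hits("M_gene1", "M", c("mtaB_1", "mtbB_1"), c(105, 101))
  a2 <- assign_identity(h2, cat60, margin_threshold = 10)
  expect_equal(a2$substrate, "ambiguous")
  expect_equal(a2$subtype, "")
  # narrow margin within one category: still confident
  h3 <- mk_hits("M_gene1", "M", c("mttB_pyl_1", "mtbB_1"), c(105, 101))
  a3 <- assign_identity(h3, cat60, margin_threshold = 10)
  expect_equal(a3$substrate, "methyl_N")
})

test_that("RamX best hits are always substrate ambiguous", {
  a <- assign_identity(mk_hits("M_gene1", "M", "ramA_1", 300), cat60)
  expect_equal(a$role, "RamX")
  expect_equal(a$substrate, "ambiguous")
})

test_that("assignment is deterministic and hit-order invariant", {
  h <- mk_hits("M_gene1", "M", c("mtaB_2", "mtaB_1", "mtvB_1"),
               c(200, 200, 120))
  a1 <- assign_identity(h, cat60)
  a2 <- assign_identity(h[c(3, 1, 2), ], cat60)
  expect_identical(a1, a2)
  expect_equal(a1$best_reference_id, "mtaB_1")  # lexicographic tie-break
  expect_error(assign_identity(h[0, ], cat60), "empty")
})

test_that("operon detection clusters adjacent assigned genes", {
  coords <- data.frame(
    gene_id = sprintf("M_gene%d", 1:8),
    contig = c(rep("c1", 6), "c2", "c2"),
    start = c(100, 600, 1100, 1600, 2100, 2600, 100, 600),
    end = c(500, 1000, 1500, 2000, 2500, 3000, 500, 1000),
    strand = "+", stringsAsFactors = FALSE)
  asg <- mk_asg("M", c("MtxB", "MtxC", "MtxA", "RamX"), "methyl_O",
                gene = sprintf("M_gene%d", c(1, 2, 3, 4)))
  r <- detect_operons(asg, coords, max_intergenic = 2)
  expect_equal(nrow(r$operons), 1L)
  expect_equal(r$operons$roles_present, "MtxA;MtxB;MtxC;RamX")
  expect_true(all(r$assignments$syntenic))

  # genes on different contigs never cluster
  asg2 <- mk_asg("M", c("MtxB", "MtxC"), "methyl_O",
                 gene = c("M_gene1", "M_gene7"))
  r2 <- detect_operons(asg2, coords, max_intergenic = 2)
  expect_equal(nrow(r2$operons), 0L)
  expect_false(any(r2$assignments$syntenic))

  # 3 intervening unassigned genes exceed max_intergenic = 2
  asg3 <- mk_asg("M", c("MtxB", "MtxC"), "methyl_O",
                 gene = c("M_gene1", "M_gene5"))
  r3 <- detect_operons(asg3, coords, max_intergenic = 2)
  expect_equal(nrow(r3$operons), 0L)
  r3b <- detect_operons(asg3, coords, max_intergenic = 3)
  expect_equal(nrow(r3b$operons), 1L)

  expect_error(detect_operons(mk_asg("M", "MtxB", "methyl_O",
                                     gene = "M_gene99"), coords),
               "M_gene99")
})

test_that("operon detection is invariant to reversing contig coordinates", {
  coords <- data.frame(
    gene_id = sprintf("M_gene%d", 1:5), contig = "c1",
    start = seq(100, 2100, by = 500), end = seq(400, 2400, by = 500),
    strand = "+", stringsAsFactors = FALSE)
  rev_coords <- coords
  L <- 3000
  rev_coords$start <- L - coords$end
  rev_coords$end <- L - coords$start
  asg <- mk_asg("M", c("MtxB", "MtxC"), "methyl_O",
                gene = c("M_gene2", "M_gene4"))
  r1 <- detect_operons(asg, coords, max_intergenic = 1)
  r2 <- detect_operons(asg, rev_coords, max_intergenic = 1)
  expect_equal(nrow(r1$operons), nrow(r2$operons))
  expect_identical(sort(strsplit(r1$operons$member_gene_ids, ";")[[1]]),
                   sort(strsplit(r2$operons$member_gene_ids, ";")[[1]]))
})

test_that("amber-codon truncation with readthrough is called pyl", {
  p <- rand_prot(500, 77)
  g <- constructed_pyl_gene(p, amber_at = 150, stop_codon = "TAG")
  r <- detect_pyl(g$cds_with_context, g$cds_length, reference_length_aa = 500)
  expect_equal(r$status, "pyl")
  expect_false(r$low_confidence)

  # same construct terminating in TAA: wrong stop identity
  g2 <- constructed_pyl_gene(p, amber_at = 150, stop_codon = "TAA")
  r2 <- detect_pyl(g2$cds_with_context, g2$cds_length, 500)
  expect_equal(r2$status, "non_pyl")

  # full-length gene ending in TAA: the quaternary-amine non-Pyl class
  g3 <- constructed_pyl_gene(p)
  r3 <- detect_pyl(g3$cds_with_context, g3$cds_length, 500)
  expect_equal(r3$status, "non_pyl")
})

test_that("pyl detection handles short context and ambiguous bases", {
  p <- rand_prot(500, 78)
  g <- constructed_pyl_gene(p, amber_at = 150, stop_codon = "TAG")
  # strip downstream context below the readthrough requirement
  short <- substr(g$cds_with_context, 1, g$cds_length + 30)
  r <- detect_pyl(short, g$cds_length, 500)
  expect_equal(r$status, "pyl")
  expect_true(r$low_confidence)

  # ambiguous nucleotide inside the CDS flags low confidence, not an error
  amb <- g$cds_with_context
  substr(amb, 10, 10) <- "N"
  r2 <- detect_pyl(amb, g$cds_length, 500)
  expect_true(r2$low_confidence)

  expect_error(detect_pyl("ATGAAATT", 8, 100), "divisible")
})

test_that("pyl detection is a pure function of its inputs", {
  p <- rand_prot(300, 79)
  g <- constructed_pyl_gene(p, amber_at = 100, stop_codon = "TAG")
  r1 <- detect_pyl(g$cds_with_context, g$cds_length, 300)
  r2 <- detect_pyl(g$cds_with_context, g$cds_length, 300)
  expect_identical(r1, r2)
})

test_that("mttB refinement maps pyl status to amine specificity", {
  asg <- mk_asg("M", "MtxB", "methyl_N", subtype = "mttB Pyl trimethylamine")
  r <- refine_mttb_substrate(asg, "pyl")
  expect_match(r$subtype, "Pyl-MttB")
  expect_equal(r$substrate, "methyl_N")
  r2 <- refine_mttb_substrate(asg, "non_pyl")
  expect_match(r2$subtype, "quaternary amine")
  bad <- mk_asg("M", "MtxB", "methyl_O", subtype = "mtaB methanol")
  expect_error(refine_mttb_substrate(bad, "pyl"), "mttB")
})
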