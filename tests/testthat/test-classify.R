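mk_ann <- function(mag, symbols) {
  data.frame(mag_id = mag, gene_id = sprintf("%s_g%d", mag, seq_along(symbols)),
             gene_symbol = symbols, stringsAsFactors = FALSE)
}

test_that("methanogen typing requires Mcr and Hdr and adds marker pathways", {
  cfg <- marker_config()
  ann <- rbind(
    mk_ann("H", c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                  "fwdA", "fwdB", "mtd", "mer", "frhA", "frhB")),
    mk_ann("N", c("hdrA", "hdrB", "fwdA", "mtd")),
    mk_ann("B", c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                  "fwdA", "fwdB", "mtd", "mer", "ackA", "pta")))
  h <- classify_methanogen(ann, "H", cfg)
  expect_true(h$is_methanogen)
  expect_identical(h$pathways, "hydrogenotrophic")
  n <- classify_methanogen(ann, "N", cfg)  # no mcr genes
  expect_false(n$is_methanogen)
  expect_length(n$pathways, 0)
  b <- classify_methanogen(ann, "B", cfg)
  expect_setequal(b$pathways, c("hydrogenotrophic", "acetoclastic"))
  expect_error(classify_methanogen(ann, "MISSING", cfg), "MISSING")
})

test_that("archaeal methylotrophy needs two core members including mtxB", {
  yes <- call_methylotrophy(mk_asg("M", c("MtxB", "MtxC"), "methyl_O",
                                   c("mtaB methanol", "mtaC methanol")),
                            "archaeal")
  expect_true(yes$is_methylotroph)
  no <- call_methylotrophy(mk_asg("M", c("MtxC", "MtxA"), "methyl_O",
                                  c("mtaC methanol", "mtaA methanol")),
                           "archaeal")
  expect_false(no$is_methylotroph)
})

test_that("methyl-sulfide routes are single-gene sufficient", {
  fused <- call_methylotrophy(mk_asg("M", "MtsFused", "methyl_S", "mtsD"),
                              "archaeal")
  expect_true(fused$is_methylotroph)
  mtsa <- call_methylotrophy(mk_asg("M", "MtxB", "methyl_S", "mtsA"),
                             "archaeal")
  expect_true(mtsa$is_methylotroph)
  # under the both-required reading a lone mtsB no longer suffices
  strict <- call_methylotrophy(mk_asg("M", "MtxC", "methyl_S", "mtsB"),
                               "archaeal", mts_require_both = TRUE)
  expect_false(strict$is_methylotroph)
})

test_that("bacterial calls use the mtxB-only rule", {
  expect_true(call_methylotrophy(mk_asg("M", "MtxB", "methyl_N",
                                        "mttB Pyl trimethylamine"),
                                 "bacterial")$is_methylotroph)
  expect_false(call_methylotrophy(mk_asg("M", c("MtxC", "MtxA"), "methyl_O",
                                         c("mtaC methanol", "mtaA methanol")),
                                  "bacterial")$is_methylotroph)
})

test_that("substrate profiles exclude RamX and ambiguous genes", {
  asg <- rbind(mk_asg("M", "MtxB", "methyl_O", "mtaB methanol"),
               mk_asg("M", "RamX", "ambiguous"))
  expect_identical(substrate_profile(asg), "methyl_O")
  amb <- mk_asg("M", "MtxA", "ambiguous")
  expect_length(substrate_profile(amb), 0)
  multi <- rbind(mk_asg("M", "MtxB", "methyl_N", "Pyl-MttB (tri/di/monomethylamine)"),
                 mk_asg("M", "MtxB", "methyl_O", "mtaB methanol"))
  expect_identical(substrate_profile(multi), c("methyl_N", "methyl_O"))
})

test_that("lifestyle follows the pathway set", {
  expect_identical(classify_lifestyle("methylotrophic"),
                   "obligate_methylotroph")
  expect_identical(classify_lifestyle(c("methylotrophic", "hydrogenotrophic")),
                   "facultative_methylotroph")
  expect_identical(classify_lifestyle("hydrogenotrophic"), "non_methylotroph")
  expect_error(classify_lifestyle("methylotrophic", is_methanogen = FALSE),
               "methanogens")
})

test_that("adding genes never flips a methylotroph verdict to negative", {
  set.seed(11)
  roles <- c("MtxB", "MtxC", "MtxA", "RamX", "MtsFused")
  cats <- c("methyl_N", "methyl_O", "methyl_S", "ambiguous")
  for (k in 1:25) {
    n <- sample(1:5, 1)
    base <- mk_asg("M", sample(roles, n, TRUE), sample(cats, n, TRUE))
    extra <- mk_asg("M", sample(roles, 2, TRUE), sample(cats, 2, TRUE),
                    gene = c("M_extra1", "M_extra2"))
    v1 <- call_methylotrophy(base, "archaeal")$is_methylotroph
    v2 <- call_methylotrophy(rbind(base, extra), "archaeal")$is_methylotroph
    expect_false(v1 && !v2)
  }
})

test_that("verdicts are invariant to assignment row order", {
  asg <- rbind(mk_asg("M", "MtxB", "methyl_O", "mtaB methanol"),
               mk_asg("M", "MtxC", "methyl_O", "mtaC methanol"),
               mk_asg("M", "RamX", "ambiguous"))
  perm <- asg[c(3, 1, 2), ]
  expect_identical(call_methylotrophy(asg, "archaeal")$is_methylotroph,
                   call_methylotrophy(perm, "archaeal")$is_methylotroph)
  expect_identical(substrate_profile(asg), substrate_profile(perm))
})

test_that("classify_mags integrates markers, verdicts and lifestyle", {
  ann <- rbind(
    mk_ann("SAR", c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC",
                    "fwdA", "fwdB", "mtd", "mer", "ackA", "pta")),
    mk_ann("MASS", c("mcrA", "mcrB", "mcrG", "hdrA", "hdrB", "hdrC")),
    mk_ann("BACT", c("rpoB")))
  tax <- data.frame(
    mag_id = c("SAR", "MASS", "BACT"),
    gtdb = c("d__Archaea;p__x;c__x;o__Methanosarcinales;f__x;g__x;s__",
             "d__Archaea;p__x;c__x;o__Methanomassiliicoccales;f__x;g__x;s__",
             "d__Bacteria;p__x;c__x;o__Burkholderiales;f__x;g__x;s__"),
    stringsAsFactors = FALSE)
  asg <- rbind(
    mk_asg("SAR", c("MtxB", "MtxC", "MtxA"), "methyl_O",
           c("mtaB methanol", "mtaC methanol", "mtaA methanol")),
    mk_asg("MASS", "MtsFused", "methyl_S", "mtsD"),
    mk_asg("BACT", "MtxB", "methyl_N", "non-Pyl MttB (quaternary amine)"))
  out <- classify_mags(asg, ann, tax)
  ph <- out$physiology
  sar <- ph[ph$mag_id == "SAR", ]
  expect_identical(sar$pathways, "acetoclastic;hydrogenotrophic;methylotrophic")
  expect_identical(sar$lifestyle, "facultative_methylotroph")
  mass <- ph[ph$mag_id == "MASS", ]
  expect_identical(mass$pathways, "methylotrophic")
  expect_identical(mass$lifestyle, "obligate_methylotroph")
  expect_identical(mass$substrate_profile, "methyl_S")
  bact <- ph[ph$mag_id == "BACT", ]
  expect_false(bact$is_methanogen)
  expect_true(bact$is_methylotroph)
  expect_true(is.na(bact$lifestyle))
  expect_identical(ph$order, c("Methanosarcinales", "Methanomassiliicoccales",
                               "Burkholderiales"))
  # traces are complete and serializable
  expect_length(out$traces, 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_rule_traces(out$traces, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
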