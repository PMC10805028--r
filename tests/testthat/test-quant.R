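test_that("count floor zeroes cells strictly below it", {
  m <- matrix(c(4, 5, 0, 12, 1, 7), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  f <- filter_counts(m, 5)
  expect_equal(unname(f[, "s1"]), c(0, 5, 0))
  expect_equal(unname(f[, "s2"]), c(12, 0, 7))
  z <- matrix(0, 3, 2)
  expect_equal(filter_counts(z, 5), z)
  expect_error(filter_counts(matrix(-1, 1, 1)), "non-negative")
})

test_that("TMM factors are unity for identical or purely rescaled samples", {
  set.seed(3)
  x <- rnbinom(50, mu = 100, size = 2) + 1
  m <- cbind(s1 = x, s2 = x)
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-12)
  m2 <- cbind(s1 = x, s2 = 2 * x)  # pure depth difference: all M equal
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
  expect_error(tmm_factors(cbind(s1 = x, s2 = 0 * x)), "s2")
})

test_that("TMM matches the hand recipe on an outlier fixture", {
  m <- cbind(s1 = c(100, 80, 120, 90, 60, 110, 70, 95),
             s2 = c(105, 85, 115, 95, 65, 105, 75, 2000))
  expect_equal(unname(tmm_factors(m)), unname(tmm_oracle(m)),
               tolerance = 1e-6)
  set.seed(8)
  for (k in 1:20) {
    r <- matrix(rnbinom(120, mu = 80, size = 1) + 1, ncol = 4)
    expect_equal(unname(tmm_factors(r)), unname(tmm_oracle(r)),
                 tolerance = 1e-6)
  }
})

test_that("TMM factors always have geometric mean one", {
  set.seed(21)
  for (k in 1:25) {
    nc <- sample(2:5, 1)
    r <- matrix(rnbinom(40 * nc, mu = 60, size = 1) + 1, ncol = nc)
    f <- tmm_factors(r)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-10)
  }
})

test_that("geTMM converts counts to length-corrected per-million values", {
  # single sample: pure RPK proportions
  m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  g <- getmm(m, c(1000, 2000))
  expect_equal(unname(g[, 1]), c(2 / 3, 1 / 3) * 1e6)
  # uniform matrix: every cell 1e6 / G
  u <- matrix(50, nrow = 10, ncol = 3)
  gu <- getmm(u, rep(1500, 10))
  expect_true(all(abs(gu - 1e5) < 1e-9))
  expect_error(getmm(m, c(0, 2000)), "positive")
})

test_that("geTMM matches the hand oracle and is depth-invariant", {
  set.seed(5)
  counts <- matrix(rnbinom(90, mu = 120, size = 2), ncol = 3,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:3)))
  len <- sample(500:3000, 30)
  expect_equal(getmm(counts, len), getmm_oracle(counts, len),
               tolerance = 1e-6)
  # multiplying one sample's counts by a constant changes nothing: exact
  # for the unweighted trimmed mean, approximate under precision weights
  # (whose magnitudes depend on library size)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 7
  unw <- normalization_params(weighted = FALSE)
  expect_equal(getmm(counts, len, unw, filter = FALSE),
               getmm(scaled, len, unw, filter = FALSE), tolerance = 1e-6)
  expect_equal(getmm(counts, len, filter = FALSE),
               getmm(scaled, len, filter = FALSE), tolerance = 0.2)
})

test_that("unweighted TMM matches its hand recipe too", {
  set.seed(14)
  unw <- normalization_params(weighted = FALSE)
  for (k in 1:10) {
    r <- matrix(rnbinom(120, mu = 80, size = 1) + 1, ncol = 4)
    expect_equal(unname(tmm_factors(r, unw)),
                 unname(tmm_oracle(r, weighted = FALSE)), tolerance = 1e-6)
  }
})

test_that("active-methylotroph calls follow the majority-incl-mtxB rule", {
  asg <- mk_asg("M", c("MtxB", "MtxC", "MtxA"), "methyl_O",
                gene = c("M_g1", "M_g2", "M_g3"))
  ge <- function(b, c, a)
    matrix(c(b, c, a), nrow = 3, byrow = TRUE,
           dimnames = list(c("M_g1", "M_g2", "M_g3"), c("r1", "r2")))
  # B and C expressed: 2/3 including mtxB -> active
  act <- classify_active_methylotroph(ge(c(50, 40), c(10, 5), c(0, 0)), asg)
  expect_true(act$active)
  # only C and A expressed: mtxB silent -> inactive
  act2 <- classify_active_methylotroph(ge(c(0, 0), c(10, 5), c(8, 2)), asg)
  expect_false(act2$active)
  # nothing expressed -> inactive
  act3 <- classify_active_methylotroph(ge(c(0, 0), c(0, 0), c(0, 0)), asg)
  expect_false(act3$active)
})

test_that("order activity fractions normalize per group and sum to one", {
  ge <- matrix(c(300, 300, 100, 100), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  gene_mag <- c(g1 = "M1", g2 = "M2")
  mag_order <- c(M1 = "OrderA", M2 = "OrderB")
  f <- order_activity_fractions(ge, gene_mag, mag_order,
                                groups = c("grp", "grp"))
  expect_equal(unname(f["OrderA", "grp"]), 0.75)
  expect_equal(unname(f["OrderB", "grp"]), 0.25)
  expect_equal(sum(f[, "grp"]), 1)
  one <- order_activity_fractions(ge[1, , drop = FALSE], gene_mag["g1"],
                                  mag_order, c("grp", "grp"))
  expect_equal(unname(one[1, 1]), 1)
  zero <- ge * 0
  expect_warning(fz <- order_activity_fractions(zero, gene_mag, mag_order,
                                                c("grp", "grp")),
                 "zero methanogen expression")
  expect_true(all(is.na(fz)))
})

test_that("abundance normalization divides group means, never by zero", {
  ge <- matrix(c(50, 50, 0, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ab <- matrix(c(0.25, 0.5), nrow = 2,
               dimnames = list(c("M1", "M2"), "grp"))
  gene_mag <- c(g1 = "M1", g2 = "M2")
  v <- abundance_normalized_expression(ge, gene_mag, ab, c("grp", "grp"))
  expect_equal(unname(v["g1", "grp"]), 200)
  expect_equal(unname(v["g2", "grp"]), 0)  # zero expression stays zero
  ab0 <- ab; ab0["M1", ] <- 0
  expect_warning(v0 <- abundance_normalized_expression(ge, gene_mag, ab0,
                                                       c("grp", "grp")),
                 "zero/missing")
  expect_true(is.na(v0["g1", "grp"]))
})

test_that("trimmed-mean coverage follows the percentile convention", {
  expect_equal(trimmed_mean_coverage(rep(7, 100)), 7)
  expect_equal(trimmed_mean_coverage(sample(0:99)), 49.5)  # keeps 10..89
  expect_equal(trimmed_mean_coverage(5), 5)  # degenerate length-1
  expect_error(trimmed_mean_coverage(numeric(0)), "empty")
})

test_that("relative abundance is a scale-invariant simplex projection", {
  cov <- matrix(c(2, 2, 4), nrow = 3,
                dimnames = list(c("A", "B", "C"), "s1"))
  ra <- relative_abundance(cov)
  expect_equal(unname(ra[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(relative_abundance(cov * 13), ra)
  # nested denominator: methanogens within archaea
  cov2 <- matrix(c(6, 3, 1), nrow = 3,
                 dimnames = list(c("arch1", "arch2", "meth1"), "s1"))
  nested <- relative_abundance(cov2, c("arch2", "meth1"))
  expect_equal(unname(nested[, 1]), c(0.75, 0.25))
  zero <- matrix(0, 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_warning(rz <- relative_abundance(zero), "zero denominator")
  expect_true(all(is.na(rz)))
})

test_that("pearson r-squared behaves on exact and degenerate inputs", {
  x <- 1:10
  expect_equal(pearson_r2(x, 2 * x + 1), 1)
  expect_equal(pearson_r2(c(-1, 0, 1, 0), c(0, 1, 0, -1)), 0)
  expect_error(pearson_r2(x, rep(3, 10)), "variance")
  expect_error(pearson_r2(1:2, 1:2), "length")
})
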