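# Expression and abundance quantification: count filtering, geTMM
# normalization (gene-length-corrected TMM), active-methylotroph calls,
# order-level activity fractions, abundance-normalized expression, and
# trimmed-mean coverage -> nested relative abundances.

#' Normalization parameters
#'
#' @param trim_M TMM log-ratio trim fraction (default 0.30).
#' @param trim_A TMM absolute-intensity trim fraction (default 0.05).
#' @param count_floor counts strictly below this are zeroed before
#'   normalization (default 5).
#' @param coverage_trim_min,coverage_trim_max depth percentiles excluded by
#'   the trimmed-mean coverage (defaults 0.1 / 0.9).
#' @param weighted use precision (inverse asymptotic variance) weights in
#'   the trimmed mean of M-values (canonical TMM; default TRUE). Because
#'   the weights depend on library size, scaling one sample's counts
#'   perturbs the weighted factors slightly; \code{weighted = FALSE} makes
#'   the factors exactly invariant to per-sample depth changes.
#' @return List of class \code{methyloscan_norm_params}.
#' @export
normalization_params <- function(trim_M = 0.30, trim_A = 0.05,
                                 count_floor = 5L,
                                 coverage_trim_min = 0.1,
                                 coverage_trim_max = 0.9,
                                 weighted = TRUE) {
  if (trim_M < 0 || trim_M >= 0.5 || trim_A < 0 || trim_A >= 0.5)
    stop("trim fractions must lie in [0, 0.5)", call. = FALSE)
  if (coverage_trim_min >= coverage_trim_max)
    stop("coverage_trim_min must be < coverage_trim_max", call. = FALSE)
  if (count_floor < 0) stop("count_floor must be >= 0", call. = FALSE)
  structure(list(trim_M = trim_M, trim_A = trim_A,
                 count_floor = as.integer(count_floor),
                 coverage_trim_min = coverage_trim_min,
                 coverage_trim_max = coverage_trim_max,
                 weighted = isTRUE(weighted)),
            class = "methyloscan_norm_params")
}

#' Zero out low counts
#'
#' Applies the per-cell read-count floor: every count strictly below
#' \code{count_floor} is set to 0; the matrix shape is unchanged.
#'
#' @param counts genes x samples non-negative count matrix.
#' @param count_floor default 5 (counts of <5 removed).
#' @return Filtered matrix.
#' @export
filter_counts <- function(counts, count_floor = 5L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts[counts < count_floor] <- 0
  counts
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Canonical TMM: the reference sample is the one whose 75th-percentile
#' count fraction is closest to the mean of those; per sample, M (log
#' ratio) and A (log abundance) values are computed over genes positive in
#' both sample and reference, the most extreme \code{trim_M} of M and
#' \code{trim_A} of A are removed, and the factor is 2 to the
#' precision-weighted mean M, rescaled so the factors' geometric mean is 1.
#' Computation is delegated to edgeR's TMM implementation.
#'
#' @param mat genes x samples matrix of counts (or reads-per-kilobase for
#'   geTMM).
#' @param params a [normalization_params()].
#' @return Named per-sample scaling factors with geometric mean 1.
#' @export
tmm_factors <- function(mat, params = normalization_params()) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(mat)
  if (any(lib <= 0))
    stop("sample(s) with zero library sum: ",
         paste(colnames(mat)[lib <= 0], collapse = ", "), call. = FALSE)
  f <- edgeR::calcNormFactors(mat, method = "TMM",
                              logratioTrim = params$trim_M,
                              sumTrim = params$trim_A,
                              doWeighting = params$weighted)
  setNames(f, colnames(mat))
}

#' geTMM normalization
#'
#' Gene-length-corrected TMM: counts are converted to reads per kilobase
#' (RPK = count / (length/1000)), TMM scaling factors are computed on the
#' RPK matrix, and each cell is scaled per million of its sample's
#' effective library size:
#' \code{geTMM[g,s] = RPK[g,s] / (sum_g RPK[g,s] * factor_s) * 1e6}. Each
#' sample column therefore sums to \code{1e6 / factor_s}. With a single
#' sample the factor is 1 (TMM is relative between samples).
#'
#' @param counts genes x samples count matrix.
#' @param lengths per-gene lengths in bp (recycled by row).
#' @param params a [normalization_params()].
#' @param filter apply [filter_counts()] first (default TRUE).
#' @return geTMM matrix, same shape as \code{counts}.
#' @export
getmm <- function(counts, lengths, params = normalization_params(),
                  filter = TRUE) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("need one gene length per count row", call. = FALSE)
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (filter) counts <- filter_counts(counts, params$count_floor)
  rpk <- counts / (lengths / 1000)
  libs <- colSums(rpk)
  if (any(libs <= 0))
    stop("sample(s) with no post-filter signal: ",
         paste(colnames(counts)[libs <= 0], collapse = ", "), call. = FALSE)
  f <- if (ncol(counts) >= 2) tmm_factors(rpk, params) else
    setNames(1, colnames(counts))
  sweep(rpk, 2, libs * f, "/") * 1e6
}

#' Group means of an expression matrix
#'
#' @param mat genes x samples matrix.
#' @param groups character/factor of length ncol(mat) mapping samples to
#'   replicate groups (habitat x depth; n = 3 in the field design).
#' @return genes x groups matrix of replicate means.
#' @export
group_means <- function(mat, groups) {
  mat <- as.matrix(mat)
  if (length(groups) != ncol(mat))
    stop("need one group per sample column", call. = FALSE)
  gl <- unique(as.character(groups))
  out <- sapply(gl, function(g)
    rowMeans(mat[, groups == g, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat),
                                       dimnames = list(rownames(mat), gl))
  out
}

#' Call a MAG an active methylotroph
#'
#' A MAG is an active methylotroph (per replicate group) when, for at least
#' one identified methyltransferase system, more than half of the system's
#' member genes have group-mean geTMM > 0 \emph{and} the
#' substrate-demethylating member (mtxB, or a fused MtsD/F/H gene) is among
#' the expressed members. Systems are the MAG's syntenic operon clusters
#' when available, falling back to the MAG's full methylotrophy gene set.
#'
#' @param getmm_mag geTMM rows for the MAG's methylotrophy genes (rownames
#'   = gene ids).
#' @param assignments_mag the MAG's assignment rows.
#' @param groups sample-to-group mapping (length ncol); NULL = one group.
#' @param operons_mag operon data.frame rows for this MAG (optional).
#' @return List: \code{active_by_group} (named logical) and \code{active}
#'   (TRUE when active in any group).
#' @export
classify_active_methylotroph <- function(getmm_mag, assignments_mag,
                                         groups = NULL, operons_mag = NULL) {
  if (is.null(groups)) groups <- rep("all", ncol(getmm_mag))
  gm <- group_means(getmm_mag, groups)
  # identified systems mirror the methylotrophy-call routes: syntenic
  # operon clusters, each tri-functional fused gene by itself, the
  # two-part methyl-sulfide mtsA/mtsB pair, and the core-role gene set
  systems <- list()
  if (!is.null(operons_mag) && nrow(operons_mag) > 0)
    systems <- strsplit(operons_mag$member_gene_ids, ";", fixed = TRUE)
  fused <- assignments_mag$gene_id[assignments_mag$role == "MtsFused"]
  systems <- c(systems, as.list(fused))
  mts2 <- assignments_mag$gene_id[.is_mts_single(assignments_mag) &
                                    assignments_mag$role != "MtsFused"]
  if (length(mts2)) systems <- c(systems, list(mts2))
  core <- assignments_mag$gene_id[assignments_mag$role %in%
                                    c("MtxB", "MtxC", "MtxA")]
  if (length(core)) systems <- c(systems, list(core))
  is_b <- setNames(assignments_mag$role %in% c("MtxB", "MtsFused"),
                   assignments_mag$gene_id)
  active_by_group <- apply(gm > 0, 2, function(expressed) {
    names(expressed) <- rownames(gm)
    any(vapply(systems, function(members) {
      members <- intersect(members, names(expressed))
      if (!length(members)) return(FALSE)
      expr_members <- members[expressed[members]]
      length(expr_members) > length(members) / 2 &&
        any(is_b[expr_members], na.rm = TRUE)
    }, logical(1)))
  })
  list(active_by_group = active_by_group, active = any(active_by_group))
}

#' Order-level activity fractions
#'
#' The fraction of methanogen transcription attributable to each order:
#' replicate-averaged geTMM values of all methanogen-expressed genes are
#' summed at the order level and normalized to the total over all
#' methanogen genes, per group.
#'
#' @param getmm_mat geTMM matrix over methanogen genes.
#' @param gene_mag named character: gene id -> MAG id.
#' @param mag_order named character: MAG id -> taxonomic order.
#' @param groups sample-to-group mapping.
#' @return orders x groups matrix of fractions; columns sum to 1 where the
#'   group has any methanogen expression, and are NA (with a warning)
#'   otherwise.
#' @export
order_activity_fractions <- function(getmm_mat, gene_mag, mag_order, groups) {
  gm <- group_means(getmm_mat, groups)
  ord <- mag_order[gene_mag[rownames(gm)]]
  if (anyNA(ord))
    stop("gene(s) without a MAG order mapping: ",
         paste(rownames(gm)[is.na(ord)][1:min(3, sum(is.na(ord)))],
               collapse = ", "), call. = FALSE)
  sums <- rowsum(gm, ord)
  tot <- colSums(sums)
  zero <- tot == 0
  if (any(zero))
    warning("group(s) with zero methanogen expression reported as missing: ",
            paste(colnames(sums)[zero], collapse = ", "))
  out <- sweep(sums, 2, tot, "/")
  out[, zero] <- NA_real_
  out
}

#' Abundance-normalized expression
#'
#' Group-mean geTMM of each expressed gene divided by the gene's MAG
#' relative abundance in the matched metagenome group. Zero abundance with
#' nonzero expression is reported as missing (NA, with a warning), never
#' as infinity; zero expression is 0 regardless of abundance.
#'
#' @param getmm_mat geTMM matrix.
#' @param gene_mag named character: gene id -> MAG id.
#' @param abundance MAG x group relative-abundance matrix.
#' @param groups sample-to-group mapping (group names must match
#'   \code{colnames(abundance)}).
#' @return genes x groups matrix.
#' @export
abundance_normalized_expression <- function(getmm_mat, gene_mag, abundance,
                                            groups) {
  gm <- group_means(getmm_mat, groups)
  miss <- setdiff(colnames(gm), colnames(abundance))
  if (length(miss))
    stop("group(s) missing from the abundance table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ab <- abundance[gene_mag[rownames(gm)], colnames(gm), drop = FALSE]
  out <- gm / ab
  out[gm == 0] <- 0
  undef <- gm > 0 & (is.na(ab) | ab == 0)
  if (any(undef)) {
    warning(sum(undef), " cell(s) with expression but zero/missing MAG ",
            "abundance reported as missing")
    out[undef] <- NA_real_
  }
  dimnames(out) <- dimnames(gm)
  out
}

#' Trimmed-mean coverage of a depth vector
#'
#' Mean per-position depth after discarding positions outside the
#' [trim_min, trim_max] coverage percentiles. Convention: the sorted depths
#' at ranks \code{(floor(trim_min * n) + 1) : ceiling(trim_max * n)} are
#' kept, so a length-1 vector degenerates to its single value.
#'
#' @param depths per-position depth vector.
#' @param params a [normalization_params()] (uses coverage_trim_min/max).
#' @return Trimmed mean (a single number).
#' @export
trimmed_mean_coverage <- function(depths, params = normalization_params()) {
  n <- length(depths)
  if (n == 0) stop("empty depth vector", call. = FALSE)
  s <- sort(depths)
  lo <- floor(params$coverage_trim_min * n) + 1L
  hi <- ceiling(params$coverage_trim_max * n)
  mean(s[lo:hi])
}

#' Relative abundance over a denominator set
#'
#' \code{fraction[m, s] = coverage[m, s] / sum over the denominator set},
#' computed per sample. Supports the nested rollups (all MAGs, archaea
#' only, methanogens only) by passing the respective MAG set.
#'
#' @param coverages MAG x sample trimmed-mean coverage matrix.
#' @param denominator_set MAG ids forming the denominator (default: all
#'   rows). Fractions are returned for these MAGs.
#' @return MAG x sample fraction matrix; samples whose denominator sums to
#'   zero (e.g. methanogens below detection in palsa) are NA with a
#'   warning.
#' @export
relative_abundance <- function(coverages, denominator_set = rownames(coverages)) {
  coverages <- as.matrix(coverages)
  miss <- setdiff(denominator_set, rownames(coverages))
  if (length(miss))
    stop("denominator MAG(s) missing from the coverage table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sub <- coverages[denominator_set, , drop = FALSE]
  tot <- colSums(sub)
  zero <- tot == 0
  if (any(zero))
    warning("sample(s) with zero denominator coverage reported as missing: ",
            paste(colnames(sub)[zero], collapse = ", "))
  out <- sweep(sub, 2, tot, "/")
  out[, zero] <- NA_real_
  out
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return r-squared in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need two vectors of equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)^2
}
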