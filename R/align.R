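# Local protein alignment and bitscore computation for the homology screen.
# Smith-Waterman with affine gaps is delegated to Biostrings (whose gap cost
# convention, open + k * extend, matches the BLAST 11/1 semantics); the
# Karlin-Altschul bitscore transform lives here.

#' Alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties, and the
#' Karlin-Altschul statistical parameters used to convert raw
#' Smith-Waterman scores into bitscores via
#' \eqn{(\lambda S - \ln K)/\ln 2}. Defaults are BLOSUM62 with gap
#' open 11 / extend 1 and the gapped-BLOSUM62 values \eqn{\lambda = 0.267},
#' \eqn{K = 0.041}, so bitscore thresholds carry the same semantics as
#' standard protein-search output. Unknown residues (X) score 0 against
#' everything.
#'
#' @param substitution_matrix symmetric integer scoring matrix over the 20
#'   amino acids plus X; default BLOSUM62 with the X row/column zeroed.
#' @param gap_open,gap_extend positive gap penalties; a gap of length k
#'   costs \code{gap_open + k * gap_extend}.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return An object of class \code{methyloscan_scheme}.
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_x0()
  m <- substitution_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !identical(rownames(m), colnames(m)))
    stop("substitution matrix must be square with matching dimnames",
         call. = FALSE)
  if (max(abs(m - t(m))) > 0)
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gap_open <= 0 || gap_extend <= 0 || gap_extend > gap_open)
    stop("need 0 < gap_extend <= gap_open", call. = FALSE)
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive", call. = FALSE)
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "methyloscan_scheme")
}

# BLOSUM62 restricted to the 20 standard residues + X, with X scoring 0.
blosum62_x0 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

#' Convert a raw alignment score to a bitscore
#'
#' @param raw_score raw Smith-Waterman score(s).
#' @param scheme a [scoring_scheme()].
#' @return Bitscore(s): \code{(lambda * raw_score - log(K)) / log(2)}.
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment with affine gap penalties. When no
#' residue pair scores positively the empty alignment (raw score 0) is
#' optimal and no alignment is reported.
#'
#' @param query,subject amino-acid strings (20 standard residues plus X;
#'   X scores 0 against everything).
#' @param scheme a [scoring_scheme()].
#' @return A list: \code{raw_score}, \code{bitscore},
#'   \code{percent_identity} (of the aligned region, in [0,100]),
#'   \code{aln_length} (alignment columns including gaps),
#'   \code{query_coverage} (aligned query residues / query length) and
#'   \code{aligned} (FALSE when the optimal local alignment is empty).
#' @export
align_local <- function(query, subject, scheme = scoring_scheme()) {
  .validate_protein(query, "query")
  .validate_protein(subject, "subject")
  a <- Biostrings::pairwiseAlignment(
    toupper(query), toupper(subject), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  raw <- max(0, Biostrings::score(a))
  if (raw == 0) {
    return(list(raw_score = 0, bitscore = bitscore(0, scheme),
                percent_identity = 0, aln_length = 0L,
                query_coverage = 0, aligned = FALSE))
  }
  alned_q <- as.character(Biostrings::alignedPattern(a))
  list(raw_score = raw,
       bitscore = bitscore(raw, scheme),
       percent_identity = Biostrings::pid(a),
       aln_length = nchar(alned_q),
       query_coverage = nchar(gsub("-", "", alned_q)) / nchar(query),
       aligned = TRUE)
}
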