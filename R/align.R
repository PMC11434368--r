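.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Fetched from Biostrings and cached for the session.
#' @return a numeric substitution matrix with residue dimnames
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Karlin-Altschul bit score
#'
#' `(lambda * S - ln K) / ln 2` with the published gapped BLOSUM62/11-1
#' constants as defaults. No length-adjusted effective search space is
#' applied (a documented simplification relative to BLAST).
#'
#' @param raw_score raw alignment score in substitution-matrix units
#' @param lambda,k Karlin-Altschul parameters (must be positive)
#' @return bit score (numeric)
#' @export
bit_score <- function(raw_score, lambda = 0.267, k = 0.041) {
  if (lambda <= 0 || k <= 0) stop("lambda and k must be positive")
  (lambda * raw_score - log(k)) / log(2)
}

#' Estimate a BLAST-style E-value for a local alignment score
#'
#' `E = m * n * 2^(-bitscore)`, i.e. `K * m * n * exp(-lambda * S)`.
#'
#' @param raw_score raw alignment score
#' @param len_a,len_b sequence lengths (>= 1)
#' @param lambda,k Karlin-Altschul parameters
#' @return the expected number of chance hits at this score (numeric)
#' @export
estimate_evalue <- function(raw_score, len_a, len_b, lambda = 0.267,
                            k = 0.041) {
  if (len_a < 1 || len_b < 1) stop("sequence lengths must be >= 1")
  len_a * len_b * 2^(-bit_score(raw_score, lambda, k))
}

#' Optimal local (Smith-Waterman) alignment of two protein sequences
#'
#' Exact affine-gap local alignment; this replaces the seeded heuristics of
#' BLASTP with the optimal score, which is adequate at desk scale (up to a
#' few thousand sequences). Identity is computed over alignment columns
#' (gap columns count in the denominator). Coverage modes: `"min"` (default)
#' is alignment columns over the shorter sequence length, `"query"` over
#' `len_a`, `"mutual"` over the longer length.
#'
#' @param seq_a,seq_b non-empty normalized protein sequences
#' @param submat substitution matrix (default [blosum62()])
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`
#' @param coverage_mode `"min"`, `"query"` or `"mutual"`
#' @param lambda,k Karlin-Altschul parameters for the E-value
#' @return a one-row data.frame with columns `raw_score`, `bitscore`,
#'   `evalue`, `identity`, `coverage`, `aln_length`, `matches`,
#'   `a_start`, `a_end`, `b_start`, `b_end`
#' @export
pairwise_local_align <- function(seq_a, seq_b, submat = blosum62(),
                                 gap_open = 11, gap_extend = 1,
                                 coverage_mode = c("min", "query", "mutual"),
                                 lambda = 0.267, k = 0.041) {
  coverage_mode <- match.arg(coverage_mode)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  hit <- sw_align_cpp(seq_a, seq_b, submat, gap_open, gap_extend)
  la <- nchar(seq_a)
  lb <- nchar(seq_b)
  denom <- switch(coverage_mode, min = min(la, lb), query = la,
                  mutual = max(la, lb))
  data.frame(
    raw_score = hit$score,
    bitscore = bit_score(hit$score, lambda, k),
    evalue = estimate_evalue(hit$score, la, lb, lambda, k),
    identity = if (hit$aln_length > 0) hit$matches / hit$aln_length else 0,
    coverage = hit$aln_length / denom,
    aln_length = hit$aln_length, matches = hit$matches,
    a_start = hit$a_start, a_end = hit$a_end,
    b_start = hit$b_start, b_end = hit$b_end)
}
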