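#' Scan a protein sequence for CXXCH / CXXXCH heme-binding motifs
#'
#' The two motifs are the canonical c-type cytochrome heme attachment sites
#' with two or three wildcard residues between the cysteines. Wildcard
#' positions accept any residue including the unknown residue `X`; anchor
#' positions (C, C, H) must be the literal residues, since they define the
#' heme ligation chemistry.
#'
#' Under the default `nonoverlap_greedy` policy the sequence is scanned left
#' to right; at each position `CXXCH` is tried before `CXXXCH`; on a match
#' the hit is emitted and scanning resumes after the matched window, so no
#' residue serves two motifs (the global-match semantics of a scripted regex
#' alternation). Under `all_matches` every window satisfying either pattern
#' is emitted and overlaps are allowed.
#'
#' @param sequence a normalized amino-acid string (may be empty)
#' @param policy `"nonoverlap_greedy"` or `"all_matches"`
#' @return data.frame with columns `start` (0-based index of the leading C)
#'   and `pattern` (`"CXXCH"` or `"CXXXCH"`)
#' @examples
#' scan_heme_motifs("CAACHCAAACH")
#' @export
scan_heme_motifs <- function(sequence,
                             policy = c("nonoverlap_greedy", "all_matches")) {
  policy <- match.arg(policy)
  empty <- data.frame(start = integer(), pattern = character(),
                      stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < 5L) return(empty)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  is_c <- ch == "C"
  is_h <- ch == "H"
  # window predicates at 1-based start i
  cxxch_at <- function(i) i + 4L <= n && is_c[i] && is_c[i + 3L] && is_h[i + 4L]
  cxxxch_at <- function(i) i + 5L <= n && is_c[i] && is_c[i + 4L] && is_h[i + 5L]
  starts <- integer(0)
  pats <- character(0)
  if (policy == "all_matches") {
    i5 <- which(is_c[1:(n - 4L)] & is_c[4:(n - 1L)] & is_h[5:n])
    starts <- c(starts, i5)
    pats <- c(pats, rep("CXXCH", length(i5)))
    if (n >= 6L) {
      i6 <- which(is_c[1:(n - 5L)] & is_c[5:(n - 1L)] & is_h[6:n])
      starts <- c(starts, i6)
      pats <- c(pats, rep("CXXXCH", length(i6)))
    }
    ord <- order(starts, nchar(pats))
    starts <- starts[ord]
    pats <- pats[ord]
  } else {
    i <- 1L
    while (i <= n - 4L) {
      if (cxxch_at(i)) {
        starts <- c(starts, i)
        pats <- c(pats, "CXXCH")
        i <- i + 5L
      } else if (cxxxch_at(i)) {
        starts <- c(starts, i)
        pats <- c(pats, "CXXXCH")
        i <- i + 6L
      } else {
        i <- i + 1L
      }
    }
  }
  data.frame(start = starts - 1L, pattern = pats, stringsAsFactors = FALSE)
}

.heme_class <- function(n_total) {
  ifelse(n_total == 0L, "none",
         ifelse(n_total == 1L, "mono", ifelse(n_total == 2L, "bi", "multi")))
}

#' Annotate every protein of a genome set with heme-motif counts
#'
#' Produces one annotation per protein: motif counts per pattern, the heme
#' class (`none`/`mono`/`bi`/`multi`, with multi meaning >= 3 motifs), a
#' both-motif flag, and the predicted subcellular localization. Proteins
#' absent from the localization table get `"unknown"`; localization rows
#' referencing unknown proteins are ignored with a warning.
#'
#' @param gs a [genome_set()]
#' @param localization data.frame with columns `protein_id`, `category`
#'   (may be `NULL` or partial)
#' @param policy motif-scan policy, see [scan_heme_motifs()]
#' @return data.frame with columns `protein_id`, `genome_id`, `n_cxxch`,
#'   `n_cxxxch`, `n_total`, `heme_class`, `both_motifs`, `localization`;
#'   the per-motif hit table is attached as attribute `"hits"` (columns
#'   `protein_id`, `start`, `pattern`)
#' @export
annotate_proteome <- function(gs, localization = NULL,
                              policy = c("nonoverlap_greedy", "all_matches")) {
  policy <- match.arg(policy)
  stopifnot(inherits(gs, "genome_set"))
  hits_list <- lapply(gs$proteins$sequence, scan_heme_motifs, policy = policy)
  n_cxxch <- vapply(hits_list, function(h) sum(h$pattern == "CXXCH"), 0L)
  n_cxxxch <- vapply(hits_list, function(h) sum(h$pattern == "CXXXCH"), 0L)
  n_total <- n_cxxch + n_cxxxch
  loc <- rep("unknown", nrow(gs$proteins))
  if (!is.null(localization) && nrow(localization)) {
    unknown_ids <- setdiff(localization$protein_id, gs$proteins$protein_id)
    if (length(unknown_ids)) {
      eet_log("warning", length(unknown_ids), " localization row(s) reference",
              " unknown protein_id(s); ignored")
      localization <- localization[
        !localization$protein_id %in% unknown_ids, , drop = FALSE]
    }
    idx <- match(gs$proteins$protein_id, localization$protein_id)
    loc[!is.na(idx)] <- localization$category[idx[!is.na(idx)]]
  }
  ann <- data.frame(protein_id = gs$proteins$protein_id,
                    genome_id = gs$proteins$genome_id,
                    n_cxxch = n_cxxch, n_cxxxch = n_cxxxch, n_total = n_total,
                    heme_class = .heme_class(n_total),
                    both_motifs = n_cxxch >= 1L & n_cxxxch >= 1L,
                    localization = loc, stringsAsFactors = FALSE)
  nh <- vapply(hits_list, nrow, 0L)
  attr(ann, "hits") <- data.frame(
    protein_id = rep(gs$proteins$protein_id, nh),
    do.call(rbind, hits_list), stringsAsFactors = FALSE)
  ann
}

#' Per-family census of heme-motif-bearing proteins
#'
#' Summarizes, per bacterial family: the mean number of motif-bearing
#' proteins per genome; the percentage of motif-bearing proteins by motif
#' type (CXXCH-only / CXXXCH-only / both, three mutually exclusive
#' per-protein categories); counts by heme class; the mean number of
#' extracellular-predicted multi-heme proteins per genome; and the
#' percentage of multi-heme proteins predicted extracellular.
#'
#' @param annotations output of [annotate_proteome()]
#' @param gs the [genome_set()] the annotations cover
#' @return data.frame with one row per family
#' @export
family_heme_summary <- function(annotations, gs) {
  stopifnot(inherits(gs, "genome_set"))
  fam_of <- family_map(gs)
  annotations$family <- unname(fam_of[annotations$genome_id])
  fams <- sort(unique(gs$metadata$family))
  rows <- lapply(fams, function(f) {
    gset <- gs$metadata$genome_id[gs$metadata$family == f]
    a <- annotations[annotations$family == f, , drop = FALSE]
    bearing <- a[a$n_total >= 1L, , drop = FALSE]
    nb <- nrow(bearing)
    multi <- a[a$heme_class == "multi", , drop = FALSE]
    extra_multi <- multi[multi$localization == "extracellular", , drop = FALSE]
    per_genome_bearing <- vapply(
      gset, function(g) sum(bearing$genome_id == g), 0L)
    per_genome_extra_multi <- vapply(
      gset, function(g) sum(extra_multi$genome_id == g), 0L)
    data.frame(
      family = f,
      n_genomes = length(gset),
      mean_heme_proteins = mean(per_genome_bearing),
      pct_cxxch_only = if (nb) 100 * sum(bearing$n_cxxxch == 0L) / nb else 0,
      pct_cxxxch_only = if (nb) 100 * sum(bearing$n_cxxch == 0L) / nb else 0,
      pct_both = if (nb) 100 * sum(bearing$both_motifs) / nb else 0,
      n_none = sum(a$heme_class == "none"),
      n_mono = sum(a$heme_class == "mono"),
      n_bi = sum(a$heme_class == "bi"),
      n_multi = nrow(multi),
      mean_extracellular_multiheme = mean(per_genome_extra_multi),
      pct_multiheme_extracellular =
        if (nrow(multi)) 100 * nrow(extra_multi) / nrow(multi) else 0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
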