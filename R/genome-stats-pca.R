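#' Genome quality-control filter
#'
#' Keeps genomes with completeness strictly above 98% and contamination
#' strictly below 5% (both bounds read strictly).
#'
#' @param checkm data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (the `checkm` TSV schema)
#' @param completeness_min,contamination_max strict QC bounds (percent)
#' @return list with `kept` (character vector of genome ids) and `dropped`
#'   (data.frame genome_id, reason)
#' @export
qc_filter <- function(checkm, completeness_min = 98, contamination_max = 5) {
  if (anyNA(checkm$completeness) || anyNA(checkm$contamination)) {
    stop("missing completeness/contamination value")
  }
  keep <- checkm$completeness > completeness_min &
    checkm$contamination < contamination_max
  reason <- ifelse(checkm$completeness <= completeness_min,
                   sprintf("completeness %.2f <= %g", checkm$completeness,
                           completeness_min),
                   sprintf("contamination %.2f >= %g", checkm$contamination,
                           contamination_max))
  list(kept = checkm$genome_id[keep],
       dropped = data.frame(genome_id = checkm$genome_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Genome length and G+C content from a nucleotide FASTA
#'
#' Length counts all bases over all contigs including ambiguous `N`; the GC
#' fraction is `(G + C) / (A + C + G + T)`, excluding ambiguous bases from
#' the denominator.
#'
#' @param path path to a genome FASTA
#' @return list with `length_bp` (integer) and `gc_fraction` (numeric)
#' @export
genome_size_gc <- function(path) {
  fa <- read_fasta(path, alphabet = "nucleotide")
  counts <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  for (s in fa$sequence) {
    tab <- table(strsplit(s, "", fixed = TRUE)[[1L]])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  unamb <- sum(counts[c("A", "C", "G", "T")])
  if (unamb == 0) stop("no unambiguous bases in ", path, "; GC undefined")
  list(length_bp = as.integer(sum(counts)),
       gc_fraction = unname((counts[["G"]] + counts[["C"]]) / unamb))
}

#' Assemble the 13-variable genomic feature table
#'
#' One row per genome, columns in the fixed order of [FEATURE_COLUMNS]:
#' genome size (Mbp), GC (%), prophage count, heme-motif-bearing proteins
#' per Mbp (`total_cyt_per_mbp`), complete integrons, CRISPR arrays, IS
#' count, ICE types, and EET-marker copy numbers -- `ppcA`, `ompJ` and
#' `cymA` copies plus the summed copies over all markers of the
#' "cytochrome bc complex" and "riboflavin biosynthesis" categories.
#' Zeros are explicit; a genome missing from any source is an error.
#'
#' @param gs a [genome_set()] with `genome_info` (lengths and GC)
#' @param mat marker copy-number matrix from [presence_matrix()]
#' @param markers marker table (for the category sums)
#' @param annotations heme annotations from [annotate_proteome()]
#' @param profiles mobilome profiles from [build_mobilome_profiles()]
#' @param cyt_classes heme classes counted in `total_cyt_per_mbp`
#'   (default all motif-bearing proteins)
#' @return data.frame with a `genome_id` column plus [FEATURE_COLUMNS]
#' @export
assemble_feature_table <- function(gs, mat, markers, annotations, profiles,
                                   cyt_classes = c("mono", "bi", "multi")) {
  gids <- genome_ids(gs)
  if (is.null(gs$genome_info)) stop("genome_set carries no genome_info")
  gi <- gs$genome_info[match(gids, gs$genome_info$genome_id), , drop = FALSE]
  if (anyNA(gi$genome_length_bp)) {
    stop("genome missing from genome_info: ",
         gids[which(is.na(gi$genome_length_bp))[1L]])
  }
  miss <- setdiff(gids, profiles$genome_id)
  if (length(miss)) stop("genome missing from mobilome profiles: ", miss[1L])
  miss <- setdiff(gids, rownames(mat))
  if (length(miss)) stop("genome missing from copy-number matrix: ", miss[1L])
  prof <- profiles[match(gids, profiles$genome_id), , drop = FALSE]
  size_mbp <- gi$genome_length_bp / 1e6
  n_cyt <- vapply(gids, function(g) {
    sum(annotations$genome_id == g & annotations$heme_class %in% cyt_classes)
  }, 0L)
  marker_col <- function(mk) {
    if (mk %in% colnames(mat)) as.numeric(mat[gids, mk]) else {
      rep(0, length(gids))
    }
  }
  cat_sum <- function(category) {
    mks <- intersect(markers$marker_id[markers$category == category],
                     colnames(mat))
    if (!length(mks)) return(rep(0, length(gids)))
    rowSums(mat[gids, mks, drop = FALSE])
  }
  out <- data.frame(
    genome_id = gids,
    genome_size_mbp = size_mbp,
    gc_percent = 100 * gi$gc_fraction,
    prophages = prof$prophages_total,
    total_cyt_per_mbp = n_cyt / size_mbp,
    integrons_complete = prof$integrons_complete,
    crispr_arrays = prof$crispr_arrays,
    is_count = prof$is_count,
    ice_types = prof$ice_types,
    ppcA_copies = marker_col("ppcA"),
    ompJ_copies = marker_col("ompJ"),
    cbc_copies_sum = cat_sum("cytochrome bc complex"),
    cymA_copies = marker_col("cymA"),
    rib_copies_sum = cat_sum("riboflavin biosynthesis"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(out)) stop("feature table contains missing cells")
  out[, c("genome_id", FEATURE_COLUMNS)]
}

#' Principal component analysis of the genomic feature table
#'
#' Columns are z-scored (mean 0, sd 1, n-1 denominator) by default, so the
#' decomposition is of the correlation matrix; the 13 variables mix Mbp,
#' percentages and counts, and unstandardized PCA would be dominated by
#' scale. Constant columns are dropped with a warning when standardizing.
#' Each loading vector is oriented so its largest-magnitude entry is
#' positive.
#'
#' @param features data.frame from [assemble_feature_table()] (a
#'   `genome_id` column is used for score rownames if present), or a
#'   numeric matrix
#' @param standardize z-score the columns first (default `TRUE`)
#' @return list with `loadings` (variables x components), `scores`
#'   (genomes x components), `variance_explained` (percent per component,
#'   summing to 100) and `sdev`
#' @export
run_pca <- function(features, standardize = TRUE) {
  if (is.data.frame(features)) {
    ids <- if ("genome_id" %in% names(features)) features$genome_id else {
      rownames(features)
    }
    X <- as.matrix(features[, setdiff(names(features), "genome_id"),
                            drop = FALSE])
    rownames(X) <- ids
  } else {
    X <- as.matrix(features)
  }
  if (nrow(X) < 3L) stop("PCA needs at least 3 genomes, got ", nrow(X))
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      eet_log("warning", "dropping constant column(s): ",
              paste(colnames(X)[sds == 0], collapse = ", "))
      X <- X[, sds > 0, drop = FALSE]
    }
    X <- scale(X, center = TRUE, scale = TRUE)
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  eig <- eigen(stats::cov(X), symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  V <- eig$vectors
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  comp <- paste0("PC", seq_len(ncol(V)))
  dimnames(V) <- list(colnames(X), comp)
  scores <- X %*% V
  colnames(scores) <- comp
  list(loadings = V, scores = scores,
       variance_explained = 100 * lam / sum(lam), sdev = sqrt(lam))
}
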