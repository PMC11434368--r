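#' Parse an orthogroup table (OrthoFinder Orthogroups.tsv dialect)
#'
#' First column `Orthogroup`, one column per genome, cells holding
#' comma-space separated protein ids, empty cell meaning absent.
#'
#' @param path path to the TSV
#' @return a long data.frame with columns `og_id`, `genome_id`,
#'   `protein_id`; genome column order is kept in attribute `"genome_ids"`
#' @export
parse_orthogroups <- function(path) {
  tab <- read_table(path, "orthogroups")
  genomes <- setdiff(names(tab), "Orthogroup")
  if (!length(genomes)) stop("orthogroups table has no genome columns")
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    og <- tab$Orthogroup[r]
    any_member <- FALSE
    for (g in genomes) {
      cell <- tab[[g]][r]
      if (is.na(cell) || !nzchar(cell)) next
      ids <- strsplit(cell, ",[ ]?")[[1L]]
      ids <- ids[nzchar(ids)]
      if (!length(ids)) next
      any_member <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og, genome_id = g, protein_id = ids,
        stringsAsFactors = FALSE)
    }
    if (!any_member) stop("empty orthogroup ", og)
  }
  out <- do.call(rbind, rows)
  dup <- duplicated(out$protein_id)
  if (any(dup)) {
    stop("protein ", out$protein_id[dup][1L], " listed in two orthogroups")
  }
  attr(out, "genome_ids") <- genomes
  out
}

#' Write a long orthogroup table in the Orthogroups.tsv dialect
#'
#' @param og long data.frame (`og_id`, `genome_id`, `protein_id`)
#' @param genome_ids genome column order
#' @param path output path
#' @return `path`, invisibly
#' @export
write_orthogroups <- function(og, genome_ids, path) {
  ogs <- unique(og$og_id)
  wide <- data.frame(Orthogroup = ogs, stringsAsFactors = FALSE,
                     check.names = FALSE)
  for (g in genome_ids) {
    wide[[g]] <- vapply(ogs, function(o) {
      paste(og$protein_id[og$og_id == o & og$genome_id == g], collapse = ", ")
    }, "")
  }
  write_tsv(wide, path)
}

#' Fraction of proteins assigned to orthogroups
#'
#' @param og long orthogroup data.frame
#' @param gs a [genome_set()]
#' @return list with `assigned`, `total`, `assigned_fraction`
#' @export
og_assignment_stats <- function(og, gs) {
  total <- nrow(gs$proteins)
  assigned <- sum(gs$proteins$protein_id %in% og$protein_id)
  list(assigned = assigned, total = total,
       assigned_fraction = if (total) assigned / total else NA_real_)
}

#' Single-copy core orthogroups
#'
#' Orthogroups in which every requested genome has exactly one member; these
#' are the loci concatenated into a phylogenomic supermatrix.
#'
#' @param og long orthogroup data.frame
#' @param genome_ids genomes that must each contribute exactly one protein
#' @return character vector of og_ids, sorted
#' @export
single_copy_core <- function(og, genome_ids) {
  ogs <- sort(unique(og$og_id))
  keep <- vapply(ogs, function(o) {
    cnt <- table(factor(og$genome_id[og$og_id == o], levels = genome_ids))
    all(cnt == 1L)
  }, NA)
  ogs[keep]
}

#' Concatenate per-orthogroup alignments into a supermatrix
#'
#' Orthogroups are concatenated in sorted og_id order so the result is
#' independent of input order. Partition coordinates are 1-based inclusive.
#'
#' @param alignments named list: og_id -> named character vector
#'   (genome_id -> aligned sequence, equal lengths within an OG)
#' @return list with `sequences` (named genome -> concatenated string) and
#'   `partitions` (data.frame og_id, start, end)
#' @export
concatenate_supermatrix <- function(alignments) {
  if (!length(alignments)) stop("no alignments supplied")
  ogs <- sort(names(alignments))
  genomes <- sort(names(alignments[[ogs[1L]]]))
  parts <- data.frame(og_id = ogs, start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  seqs <- stats::setNames(rep("", length(genomes)), genomes)
  pos <- 0L
  for (i in seq_along(ogs)) {
    aln <- alignments[[ogs[i]]]
    missing <- setdiff(genomes, names(aln))
    if (length(missing) || length(aln) != length(genomes)) {
      stop("alignment ", ogs[i], " does not cover the same genome set",
           if (length(missing)) paste0(" (missing ",
                                       paste(missing, collapse = ", "), ")"))
    }
    len <- unique(nchar(aln))
    if (length(len) != 1L) stop("unequal aligned lengths in ", ogs[i])
    seqs <- paste0(seqs, aln[genomes])
    parts$start[i] <- pos + 1L
    parts$end[i] <- pos + len
    pos <- pos + len
  }
  list(sequences = stats::setNames(seqs, genomes), partitions = parts)
}

#' Orthogroup sharing statistics
#'
#' Counts: orthogroups present in every genome (universal core),
#' species-specific orthogroups (members in exactly one genome),
#' family-exclusive orthogroups (members from exactly one family, spanning
#' at least `min_genomes_exclusive` genomes), and for each family pair the
#' orthogroups whose members span exactly those two families.
#'
#' @param og long orthogroup data.frame
#' @param fam_map named character vector genome_id -> family (must cover all
#'   genomes of `og` and defines the genome universe)
#' @param min_genomes_exclusive minimum genome count for a family-exclusive
#'   orthogroup (default 2 keeps species-specific OGs out of the count)
#' @return list with `n_universal`, `n_species_specific`,
#'   `n_family_exclusive`, `family_exclusive` (named counts per family) and
#'   `family_pairs` (data.frame family_a, family_b, n_ogs)
#' @export
og_sharing_stats <- function(og, fam_map, min_genomes_exclusive = 2L) {
  miss <- setdiff(unique(og$genome_id), names(fam_map))
  if (length(miss)) stop("family_map misses genome(s): ",
                         paste(miss, collapse = ", "))
  all_genomes <- names(fam_map)
  sp <- split(og$genome_id, og$og_id)
  n_genomes <- vapply(sp, function(g) length(unique(g)), 0L)
  n_universal <- sum(vapply(sp, function(g) {
    all(all_genomes %in% g)
  }, NA))
  n_species_specific <- sum(n_genomes == 1L)
  fams_of <- lapply(sp, function(g) sort(unique(unname(fam_map[g]))))
  n_fams <- lengths(fams_of)
  excl <- n_fams == 1L & n_genomes >= min_genomes_exclusive
  fam_levels <- sort(unique(unname(fam_map)))
  excl_counts <- stats::setNames(integer(length(fam_levels)), fam_levels)
  tab <- table(unlist(fams_of[excl]))
  excl_counts[names(tab)] <- as.integer(tab)
  pairs <- if (length(fam_levels) >= 2L) {
    cmb <- utils::combn(fam_levels, 2L)
    data.frame(
      family_a = cmb[1L, ], family_b = cmb[2L, ],
      n_ogs = apply(cmb, 2L, function(p) {
        sum(vapply(fams_of, function(f) identical(f, sort(p)), NA))
      }), stringsAsFactors = FALSE)
  } else {
    data.frame(family_a = character(), family_b = character(),
               n_ogs = integer(), stringsAsFactors = FALSE)
  }
  list(n_universal = n_universal, n_species_specific = n_species_specific,
       n_family_exclusive = sum(excl), family_exclusive = excl_counts,
       family_pairs = pairs)
}

#' Infer orthogroups by reciprocal best hits (self-contained fallback)
#'
#' A deliberately simple stand-in for a dedicated orthology tool: all-vs-all
#' Smith-Waterman between genome pairs, reciprocal best hits (by raw score,
#' ties broken by lexicographic protein id) passing the identity and
#' coverage thresholds form edges, and connected components of the RBH graph
#' are the orthogroups. With `attach_paralogs` (default), proteins left out
#' of every component -- typically extra within-genome copies, since only
#' one paralog can be a genome pair's reciprocal best hit -- are attached to
#' the orthogroup of their best cross-genome hit passing the same
#' thresholds. Remaining proteins stay unassigned; no singleton orthogroups
#' are created. Deterministic given its inputs.
#'
#' @param gs a [genome_set()] with at least two genomes
#' @param min_identity,min_coverage hit thresholds (fractions)
#' @param attach_paralogs attach leftover proteins to their best hit's
#'   orthogroup
#' @return long orthogroup data.frame as from [parse_orthogroups()]
#' @export
infer_orthogroups_rbh <- function(gs, min_identity = 0.30,
                                  min_coverage = 0.70,
                                  attach_paralogs = TRUE) {
  stopifnot(inherits(gs, "genome_set"))
  genomes <- genome_ids(gs)
  empty <- vapply(genomes, function(g) {
    sum(gs$proteins$genome_id == g) == 0L
  }, NA)
  if (any(empty)) {
    eet_log("warning", "excluding genome(s) with empty proteome: ",
            paste(genomes[empty], collapse = ", "))
    genomes <- genomes[!empty]
  }
  if (length(genomes) < 2L) stop("need >= 2 genomes with proteins")
  prot <- gs$proteins[gs$proteins$genome_id %in% genomes, , drop = FALSE]
  prot <- prot[order(prot$protein_id), ]
  by_genome <- split(prot[, c("protein_id", "sequence")], prot$genome_id)
  submat <- blosum62()
  # per genome pair: score matrix of hits passing the thresholds (NA = fail)
  edges <- list()
  best_of <- list()  # protein -> c(score, partner) best passing hit overall
  note_best <- function(p, q, s) {
    cur <- best_of[[p]]
    if (is.null(cur) || s > cur$score ||
        (s == cur$score && q < cur$partner)) {
      best_of[[p]] <<- list(score = s, partner = q)
    }
  }
  for (ia in seq_along(genomes)) {
    for (ib in seq_len(ia - 1L)) {
      A <- by_genome[[genomes[ia]]]
      B <- by_genome[[genomes[ib]]]
      S <- matrix(NA_real_, nrow(A), nrow(B))
      for (i in seq_len(nrow(A))) {
        for (j in seq_len(nrow(B))) {
          h <- pairwise_local_align(A$sequence[i], B$sequence[j],
                                    submat = submat)
          if (h$identity >= min_identity && h$coverage >= min_coverage &&
              h$raw_score > 0) {
            S[i, j] <- h$raw_score
            note_best(A$protein_id[i], B$protein_id[j], h$raw_score)
            note_best(B$protein_id[j], A$protein_id[i], h$raw_score)
          }
        }
      }
      # rows/cols are protein_id-sorted, so which.max keeps the tie rule
      ab <- apply(S, 1L, function(r) {
        if (all(is.na(r))) NA_integer_ else which.max(r)
      })
      ba <- apply(S, 2L, function(cc) {
        if (all(is.na(cc))) NA_integer_ else which.max(cc)
      })
      for (i in seq_len(nrow(A))) {
        j <- ab[i]
        if (!is.na(j) && !is.na(ba[j]) && ba[j] == i) {
          edges[[length(edges) + 1L]] <- c(A$protein_id[i], B$protein_id[j])
        }
      }
    }
  }
  empty_out <- function() {
    out <- data.frame(og_id = character(), genome_id = character(),
                      protein_id = character(), stringsAsFactors = FALSE)
    attr(out, "genome_ids") <- genomes
    out
  }
  if (!length(edges)) return(empty_out())
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  og_of <- stats::setNames(rep(seq_along(members), lengths(members)),
                           unlist(members))
  if (attach_paralogs) {
    leftovers <- setdiff(prot$protein_id, names(og_of))
    for (p in sort(leftovers)) {
      b <- best_of[[p]]
      if (!is.null(b) && b$partner %in% names(og_of)) {
        og_of[[p]] <- og_of[[b$partner]]
      }
    }
  }
  members <- split(names(og_of), og_of)
  members <- members[order(vapply(members, min, ""))]
  rows <- lapply(seq_along(members), function(i) {
    ids <- sort(members[[i]])
    data.frame(og_id = sprintf("OG%07d", i),
               genome_id = prot$genome_id[match(ids, prot$protein_id)],
               protein_id = ids, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genome_ids") <- genomes
  out
}

#' Map EET markers to orthogroups
#'
#' If a marker's reference protein is itself a member of an orthogroup, the
#' marker maps to that orthogroup. Otherwise the reference sequence is
#' aligned against all orthogroup members and the marker maps to the
#' orthogroup of the best-scoring hit passing the identity and coverage
#' thresholds; with no such hit the marker is unmapped (dropped from the
#' presence matrix with a warning). Two markers may map to the same
#' orthogroup (paralogous markers); this is logged.
#'
#' @param markers marker table (columns `marker_id`, `reference_protein_id`,
#'   `source_model`, `category`)
#' @param og long orthogroup data.frame
#' @param gs a [genome_set()] providing member sequences
#' @param reference_sequences named character vector
#'   (reference_protein_id -> sequence) for references external to `gs`
#' @param min_identity,min_coverage best-hit thresholds (the similarity
#'   network thresholds, for one threshold vocabulary across the pipeline)
#' @return named character vector marker_id -> og_id (`NA` for unmapped)
#' @export
map_markers_to_ogs <- function(markers, og, gs, reference_sequences = NULL,
                               min_identity = 0.30, min_coverage = 0.70) {
  submat <- blosum62()
  member_seq <- gs$proteins[gs$proteins$protein_id %in% og$protein_id,
                            c("protein_id", "sequence")]
  member_seq <- member_seq[order(member_seq$protein_id), ]
  og_of <- stats::setNames(og$og_id, og$protein_id)
  out <- stats::setNames(rep(NA_character_, nrow(markers)),
                         markers$marker_id)
  for (i in seq_len(nrow(markers))) {
    ref <- markers$reference_protein_id[i]
    if (ref %in% names(og_of)) {
      out[i] <- og_of[[ref]]
      next
    }
    refseq <- if (!is.null(reference_sequences) &&
                  ref %in% names(reference_sequences)) {
      reference_sequences[[ref]]
    } else if (ref %in% gs$proteins$protein_id) {
      gs$proteins$sequence[match(ref, gs$proteins$protein_id)]
    } else {
      eet_log("warning", "marker ", markers$marker_id[i],
              ": reference sequence unavailable; unmapped")
      next
    }
    best_score <- -Inf
    best_og <- NA_character_
    for (r in seq_len(nrow(member_seq))) {
      h <- pairwise_local_align(refseq, member_seq$sequence[r],
                                submat = submat)
      if (h$raw_score > best_score && h$identity >= min_identity &&
          h$coverage >= min_coverage) {
        best_score <- h$raw_score
        best_og <- og_of[[member_seq$protein_id[r]]]
      }
    }
    if (is.na(best_og)) {
      eet_log("warning", "marker ", markers$marker_id[i],
              " below mapping thresholds; dropped")
    }
    out[i] <- best_og
  }
  dup_og <- out[!is.na(out)][duplicated(out[!is.na(out)])]
  if (length(dup_og)) {
    eet_log("info", "markers sharing an orthogroup (paralogous markers): ",
            paste(unique(dup_og), collapse = ", "))
  }
  out
}

#' Genome x marker copy-number matrix
#'
#' `cell(genome, marker)` is the number of the genome's proteins in the
#' marker's orthogroup; presence is the derived boolean view `copy >= 1`.
#' Unmapped markers are dropped.
#'
#' @param og long orthogroup data.frame
#' @param marker_map named vector marker_id -> og_id from
#'   [map_markers_to_ogs()]
#' @param genome_ids row order of the matrix
#' @return integer matrix with genome rows and marker columns
#' @export
presence_matrix <- function(og, marker_map, genome_ids) {
  marker_map <- marker_map[!is.na(marker_map)]
  if (!length(marker_map)) stop("no mapped markers")
  mat <- matrix(0L, nrow = length(genome_ids), ncol = length(marker_map),
                dimnames = list(genome_ids, names(marker_map)))
  for (mk in names(marker_map)) {
    sel <- og[og$og_id == marker_map[[mk]], , drop = FALSE]
    counts <- table(sel$genome_id)
    hit <- intersect(names(counts), genome_ids)
    mat[hit, mk] <- as.integer(counts[hit])
  }
  mat
}

#' Per-family marker prevalence and mean copy number
#'
#' Prevalence is the percentage of a family's genomes carrying at least one
#' copy; the mean copy number averages over all genomes of the family
#' (zeros included).
#'
#' @param mat copy-number matrix from [presence_matrix()]
#' @param fam_map named vector genome_id -> family
#' @return data.frame with columns `family`, `marker`, `prevalence_pct`,
#'   `mean_copies`
#' @export
marker_prevalence_and_copies <- function(mat, fam_map) {
  fams <- sort(unique(unname(fam_map[rownames(mat)])))
  rows <- list()
  for (f in fams) {
    g <- rownames(mat)[unname(fam_map[rownames(mat)]) == f]
    sub <- mat[g, , drop = FALSE]
    for (mk in colnames(mat)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, marker = mk,
        prevalence_pct = 100 * sum(sub[, mk] >= 1L) / nrow(sub),
        mean_copies = mean(sub[, mk]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
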