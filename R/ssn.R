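#' Select sequences for the extracellular-cytochrome similarity network
#'
#' A protein qualifies if it is multi-heme (>= 3 motifs) and predicted
#' extracellular or outer membrane. The returned set is the union of all
#' members of every orthogroup containing at least one qualifying protein
#' (so members that did not themselves pass the localization filter are
#' carried along with their orthogroup).
#'
#' @param og long orthogroup data.frame
#' @param annotations output of [annotate_proteome()]
#' @return sorted character vector of protein ids
#' @export
select_network_sequences <- function(og, annotations) {
  qualifying <- annotations$protein_id[
    annotations$heme_class == "multi" &
      annotations$localization %in% c("extracellular", "outer membrane")]
  ogs <- unique(og$og_id[og$protein_id %in% qualifying])
  sort(unique(og$protein_id[og$og_id %in% ogs]))
}

#' Build a protein sequence similarity network
#'
#' All unordered sequence pairs are aligned with [pairwise_local_align()];
#' an edge is kept iff `evalue <= evalue_max` and `identity >= min_identity`
#' and `coverage >= min_coverage`. Edge weight is the bit score (E-values
#' saturate numerically far below the filter threshold, bit scores do not).
#' Isolated nodes are retained.
#'
#' @param gs a [genome_set()] providing sequences and family labels
#' @param protein_ids nodes of the network (default: all proteins of `gs`)
#' @param og optional long orthogroup data.frame for the `og_id` node
#'   attribute
#' @param evalue_max,min_identity,min_coverage edge filters
#' @param coverage_mode see [pairwise_local_align()]
#' @param gap_open,gap_extend alignment gap penalties
#' @return an undirected `igraph` with node attributes `name`, `genome_id`,
#'   `family`, `og_id` and edge attributes `score`, `bitscore`, `evalue`,
#'   `identity`, `coverage`, `aln_length`, `weight`
#' @export
build_ssn <- function(gs, protein_ids = NULL, og = NULL,
                      evalue_max = 1e-40, min_identity = 0.30,
                      min_coverage = 0.70, coverage_mode = "min",
                      gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(gs, "genome_set"))
  if (is.null(protein_ids)) protein_ids <- gs$proteins$protein_id
  protein_ids <- sort(unique(protein_ids))
  miss <- setdiff(protein_ids, gs$proteins$protein_id)
  if (length(miss)) stop("unknown protein id(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  idx <- match(protein_ids, gs$proteins$protein_id)
  seqs <- gs$proteins$sequence[idx]
  gid <- gs$proteins$genome_id[idx]
  fam <- unname(family_map(gs)[gid])
  og_of <- if (!is.null(og)) {
    o <- stats::setNames(og$og_id, og$protein_id)
    unname(o[protein_ids])
  } else {
    rep(NA_character_, length(protein_ids))
  }
  submat <- blosum62()
  n <- length(protein_ids)
  edges <- vector("list", 0L)
  if (n >= 2L) {
    for (i in 2:n) {
      for (j in seq_len(i - 1L)) {
        h <- pairwise_local_align(seqs[j], seqs[i], submat = submat,
                                  gap_open = gap_open,
                                  gap_extend = gap_extend,
                                  coverage_mode = coverage_mode)
        if (h$evalue <= evalue_max && h$identity >= min_identity &&
            h$coverage >= min_coverage) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = protein_ids[j], to = protein_ids[i],
            score = h$raw_score, bitscore = h$bitscore, evalue = h$evalue,
            identity = h$identity, coverage = h$coverage,
            aln_length = h$aln_length, weight = h$bitscore,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  vertices <- data.frame(name = protein_ids, genome_id = gid, family = fam,
                         og_id = og_of, stringsAsFactors = FALSE)
  edf <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(from = character(), to = character(), score = numeric(),
               bitscore = numeric(), evalue = numeric(),
               identity = numeric(), coverage = numeric(),
               aln_length = integer(), weight = numeric(),
               stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vertices)
}

#' Attach a Louvain partition to a similarity network
#'
#' @param graph an `igraph` from [build_ssn()]
#' @param resolution Louvain resolution parameter
#' @param seed RNG seed for the node-order shuffle
#' @return the graph with a `community` node attribute and graph attributes
#'   `modularity` and `resolution`
#' @export
partition_ssn <- function(graph, resolution = 1.0, seed = 1L) {
  res <- louvain_partition(graph, resolution = resolution, seed = seed)
  graph <- igraph::set_vertex_attr(graph, "community",
                                   value = unname(res$membership))
  graph <- igraph::set_graph_attr(graph, "modularity", res$modularity)
  igraph::set_graph_attr(graph, "resolution", resolution)
}

#' Summarize community structure of a partitioned network
#'
#' Singleton communities count toward the community total; the number of
#' communities with two or more nodes is reported separately. A community is
#' family-exclusive when all its members come from one family.
#'
#' @param graph a partitioned `igraph` (see [partition_ssn()])
#' @return list with `n_nodes`, `n_edges`, `n_communities`,
#'   `n_communities_ge2`, `modularity` and `communities` (data.frame with
#'   size, per-family counts and the family-exclusive flag)
#' @export
community_summary <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L, n_communities = 0L,
                n_communities_ge2 = 0L, modularity = 0,
                communities = data.frame(community = integer(),
                                         size = integer(),
                                         n_families = integer(),
                                         family_exclusive = logical(),
                                         families = character(),
                                         stringsAsFactors = FALSE)))
  }
  comm <- igraph::vertex_attr(graph, "community")
  if (is.null(comm)) stop("graph has no community attribute; run ",
                          "partition_ssn() first")
  fam <- igraph::vertex_attr(graph, "family")
  if (is.null(fam)) fam <- rep(NA_character_, n)
  sp <- split(fam, comm)
  tab <- data.frame(
    community = names(sp),
    size = lengths(sp),
    n_families = vapply(sp, function(f) length(unique(f)), 0L),
    family_exclusive = vapply(sp, function(f) length(unique(f)) == 1L, NA),
    families = vapply(sp, function(f) {
      paste(sort(unique(f)), collapse = ",")
    }, ""), stringsAsFactors = FALSE, row.names = NULL)
  mod <- igraph::graph_attr(graph, "modularity")
  list(n_nodes = n, n_edges = igraph::ecount(graph),
       n_communities = length(sp),
       n_communities_ge2 = sum(lengths(sp) >= 2L),
       modularity = if (is.null(mod)) NA_real_ else mod,
       communities = tab[order(-tab$size, tab$community), ])
}
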