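#' Default pipeline parameters
#'
#' Thresholds and policy switches of the end-to-end analysis, overridable
#' through the `params` argument of [run_pipeline()].
#'
#' @return a named list
#' @export
default_params <- function() {
  list(
    completeness_min = 98, contamination_max = 5,
    motif_policy = "nonoverlap_greedy",
    evalue_max = 1e-40, min_identity = 0.30, min_coverage = 0.70,
    coverage_mode = "min", resolution = 1.0,
    is_min_length = 700, is_evalue_max = 1e-6,
    density_numerator = "total",
    standardize = TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full comparative-genomics pipeline on a study directory
#'
#' Executes the stages in dependency order -- genome QC, orthogroup
#' statistics, heme-motif census, marker profiling, similarity network with
#' community detection, mobilome aggregation, feature-table assembly and
#' PCA -- reading the study layout written by [generate_study()] and
#' writing per-stage TSVs plus a JSON manifest with MD5 hashes of every
#' output. All randomness derives from `seed` via per-stage child seeds, so
#' reruns with identical inputs reproduce identical hashes.
#'
#' @param study_dir directory holding the study inputs (layout of
#'   [generate_study()])
#' @param out_dir output directory (created if needed)
#' @param seed integer base seed
#' @param params named list overriding entries of [default_params()]
#' @return invisible manifest list (also written to
#'   `out_dir/manifest.json`)
#' @export
run_pipeline <- function(study_dir, out_dir, seed = 1L, params = list()) {
  p <- utils::modifyList(default_params(), params)
  need <- c("metadata.tsv", "checkm.tsv", "orthogroups.tsv",
            "localization.tsv", "markers.tsv", "markers.faa")
  for (f in need) {
    if (!file.exists(file.path(study_dir, f))) {
      stop("missing input: ", file.path(study_dir, f))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, parameters = p, stages = list())
  add_stage <- function(name, files) {
    hashes <- as.list(unname(tools::md5sum(files)))
    names(hashes) <- basename(files)
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, outputs = hashes)
    eet_log("info", "stage ", name, ": ", length(files), " output(s)")
  }

  # qc ---------------------------------------------------------------------
  kept <- .stage("qc", {
    checkm <- read_table(file.path(study_dir, "checkm.tsv"), "checkm")
    qc <- qc_filter(checkm, p$completeness_min, p$contamination_max)
    write_tsv(data.frame(genome_id = qc$kept), file.path(out_dir,
                                                         "qc_kept.tsv"))
    write_tsv(qc$dropped, file.path(out_dir, "qc_dropped.tsv"))
    qc$kept
  })
  add_stage("qc", file.path(out_dir, c("qc_kept.tsv", "qc_dropped.tsv")))

  metadata <- read_table(file.path(study_dir, "metadata.tsv"), "metadata")
  metadata <- metadata[metadata$genome_id %in% kept, , drop = FALSE]
  proteomes <- stats::setNames(
    file.path(study_dir, "proteome", paste0(metadata$genome_id, ".faa")),
    metadata$genome_id)
  if (!all(file.exists(proteomes))) {
    stop("missing proteome path: ", proteomes[!file.exists(proteomes)][1L])
  }
  gstats <- lapply(metadata$genome_id, function(g) {
    genome_size_gc(file.path(study_dir, "genome", paste0(g, ".fna")))
  })
  genome_info <- data.frame(
    genome_id = metadata$genome_id,
    genome_length_bp = vapply(gstats, `[[`, 0L, "length_bp"),
    gc_fraction = vapply(gstats, `[[`, 0, "gc_fraction"),
    stringsAsFactors = FALSE)
  gs <- load_genome_set(proteomes, file.path(study_dir, "metadata.tsv"),
                        genome_info = genome_info)
  gs$metadata <- metadata
  fmap <- family_map(gs)

  # orthogroups ------------------------------------------------------------
  og <- .stage("orthogroups", {
    og <- parse_orthogroups(file.path(study_dir, "orthogroups.tsv"))
    og <- og[og$genome_id %in% kept, , drop = FALSE]
    sharing <- og_sharing_stats(og, fmap)
    assigned <- og_assignment_stats(og, gs)
    core <- single_copy_core(og, genome_ids(gs))
    write_tsv(data.frame(
      statistic = c("n_universal", "n_species_specific",
                    "n_family_exclusive", "n_single_copy_core",
                    "assigned_fraction"),
      value = c(sharing$n_universal, sharing$n_species_specific,
                sharing$n_family_exclusive, length(core),
                assigned$assigned_fraction)),
      file.path(out_dir, "og_stats.tsv"))
    write_tsv(sharing$family_pairs, file.path(out_dir,
                                              "og_family_pairs.tsv"))
    write_tsv(data.frame(og_id = core),
              file.path(out_dir, "single_copy_core.tsv"))
    og
  })
  add_stage("orthogroups",
            file.path(out_dir, c("og_stats.tsv", "og_family_pairs.tsv",
                                 "single_copy_core.tsv")))

  # heme scan --------------------------------------------------------------
  ann <- .stage("heme_scan", {
    loc <- read_table(file.path(study_dir, "localization.tsv"),
                      "localization")
    ann <- annotate_proteome(gs, loc, policy = p$motif_policy)
    write_tsv(ann, file.path(out_dir, "heme_annotations.tsv"))
    write_tsv(attr(ann, "hits"), file.path(out_dir, "heme_hits.tsv"))
    write_tsv(family_heme_summary(ann, gs),
              file.path(out_dir, "heme_family_summary.tsv"))
    ann
  })
  add_stage("heme_scan",
            file.path(out_dir, c("heme_annotations.tsv", "heme_hits.tsv",
                                 "heme_family_summary.tsv")))

  # marker profile ---------------------------------------------------------
  mat <- .stage("profile", {
    markers <- read_table(file.path(study_dir, "markers.tsv"), "markers")
    ref <- read_fasta(file.path(study_dir, "markers.faa"), "protein")
    refseq <- stats::setNames(ref$sequence, ref$id)
    mmap <- map_markers_to_ogs(markers, og, gs, refseq,
                               min_identity = p$min_identity,
                               min_coverage = p$min_coverage)
    mat <- presence_matrix(og, mmap, genome_ids(gs))
    write_tsv(cbind(data.frame(genome_id = rownames(mat)),
                    as.data.frame(mat)),
              file.path(out_dir, "marker_copy_matrix.tsv"))
    write_tsv(marker_prevalence_and_copies(mat, fmap),
              file.path(out_dir, "marker_prevalence.tsv"))
    mat
  })
  add_stage("profile",
            file.path(out_dir, c("marker_copy_matrix.tsv",
                                 "marker_prevalence.tsv")))

  # similarity network -----------------------------------------------------
  .stage("ssn", {
    sel <- select_network_sequences(og, ann)
    graph <- build_ssn(gs, protein_ids = sel, og = og,
                       evalue_max = p$evalue_max,
                       min_identity = p$min_identity,
                       min_coverage = p$min_coverage,
                       coverage_mode = p$coverage_mode)
    graph <- partition_ssn(graph, resolution = p$resolution,
                           seed = .derive_seed(seed, "ssn"))
    summ <- community_summary(graph)
    write_graph_file(graph, file.path(out_dir, "ssn.graphml"), "graphml")
    write_graph_file(graph, file.path(out_dir, "ssn_edges.tsv"),
                     "edge_tsv")
    write_tsv(summ$communities, file.path(out_dir, "ssn_communities.tsv"))
    write_tsv(data.frame(
      statistic = c("n_nodes", "n_edges", "n_communities",
                    "n_communities_ge2", "modularity"),
      value = c(summ$n_nodes, summ$n_edges, summ$n_communities,
                summ$n_communities_ge2, summ$modularity)),
      file.path(out_dir, "ssn_stats.tsv"))
  })
  add_stage("ssn", file.path(out_dir, c("ssn.graphml", "ssn_edges.tsv",
                                        "ssn_communities.tsv",
                                        "ssn_stats.tsv")))

  # mobilome ---------------------------------------------------------------
  profiles <- .stage("mobilome", {
    mdir <- file.path(study_dir, "mobilome")
    profiles <- build_mobilome_profiles(
      gs,
      prophages = read_table(file.path(mdir, "prophages.tsv"), "prophages"),
      crispr = read_table(file.path(mdir, "crispr.tsv"), "crispr"),
      integrons = read_table(file.path(mdir, "integrons.tsv"), "integrons"),
      is_hits = read_table(file.path(mdir, "is_hits.tsv"), "is_hits"),
      ices = read_table(file.path(mdir, "ices.tsv"), "ices"),
      is_min_length = p$is_min_length, is_evalue_max = p$is_evalue_max,
      density_numerator = p$density_numerator)
    write_tsv(profiles, file.path(out_dir, "mobilome_profiles.tsv"))
    subclade <- stats::setNames(gs$metadata$subclade, gs$metadata$genome_id)
    write_tsv(family_mobilome_summary(profiles, fmap, subclade),
              file.path(out_dir, "mobilome_summary.tsv"))
    profiles
  })
  add_stage("mobilome",
            file.path(out_dir, c("mobilome_profiles.tsv",
                                 "mobilome_summary.tsv")))

  # features ---------------------------------------------------------------
  features <- .stage("features", {
    markers <- read_table(file.path(study_dir, "markers.tsv"), "markers")
    features <- assemble_feature_table(gs, mat, markers, ann, profiles)
    write_tsv(features, file.path(out_dir, "features.tsv"))
    features
  })
  add_stage("features", file.path(out_dir, "features.tsv"))

  # pca --------------------------------------------------------------------
  .stage("pca", {
    pca <- run_pca(features, standardize = p$standardize)
    write_tsv(cbind(data.frame(variable = rownames(pca$loadings)),
                    as.data.frame(pca$loadings)),
              file.path(out_dir, "pca_loadings.tsv"))
    write_tsv(cbind(data.frame(genome_id = rownames(pca$scores)),
                    as.data.frame(pca$scores)),
              file.path(out_dir, "pca_scores.tsv"))
    write_tsv(data.frame(component = colnames(pca$loadings),
                         variance_explained_pct = pca$variance_explained),
              file.path(out_dir, "pca_variance.tsv"))
  })
  add_stage("pca", file.path(out_dir, c("pca_loadings.tsv",
                                        "pca_scores.tsv",
                                        "pca_variance.tsv")))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
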