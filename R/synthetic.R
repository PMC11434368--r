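#' Configuration for the synthetic study generator
#'
#' Defaults describe a small three-family cohort with gene families whose
#' within-family sequence identity is well above, and between-family
#' identity well below, the pipeline's 30%-identity threshold; mobilome
#' element rates follow per-strain averages typical of the sulfate- and
#' iron-reducing families the pipeline targets.
#'
#' @param seed integer RNG seed
#' @param n_families number of bacterial families
#' @param genomes_per_family genomes per family
#' @param n_gene_families number of planted gene families (orthogroups)
#' @param single_copy_fraction fraction of gene families that are strictly
#'   single copy in every genome (the phylogenomic core)
#' @param within_family_identity target pairwise identity among copies of
#'   one gene family (0-1)
#' @param between_family_identity upper bound on identity between distinct
#'   gene families (0-1); must be below `within_family_identity`
#' @param marker_fraction fraction of gene families designated EET markers
#' @param heme_motif_rate per-protein Poisson mean of planted heme motifs
#' @param genome_length_mean_mbp mean genome length (Mbp) of the nucleotide
#'   filler genomes
#' @param gc_range GC-fraction range of the filler genomes
#' @param mobilome_rates named list of per-genome Poisson means:
#'   `prophage_intact`, `prophage_questionable`, `prophage_incomplete`,
#'   `crispr`, `integron_complete`, `integron_In0`, `integron_CALIN`,
#'   `is_hits`, `ice`
#' @param orphans_per_genome proteins per genome left out of every
#'   orthogroup (the unassigned fraction)
#' @param pca_latent_factors rank of the planted feature-table covariance
#'   used by [generate_latent_feature_table()]
#' @return a validated list of class `synth_config`
#' @export
synth_config <- function(seed = 1L, n_families = 3L, genomes_per_family = 4L,
                         n_gene_families = 50L, single_copy_fraction = 0.2,
                         within_family_identity = 0.85,
                         between_family_identity = 0.20,
                         marker_fraction = 0.3, heme_motif_rate = 1.0,
                         genome_length_mean_mbp = 3.9,
                         gc_range = c(0.55, 0.65),
                         mobilome_rates = list(
                           prophage_intact = 0.48,
                           prophage_questionable = 0.24,
                           prophage_incomplete = 1.97, crispr = 2.0,
                           integron_complete = 0.15, integron_In0 = 0.1,
                           integron_CALIN = 0.3, is_hits = 5, ice = 1.2),
                         orphans_per_genome = 2L,
                         pca_latent_factors = 2L) {
  if (within_family_identity <= between_family_identity) {
    stop("within_family_identity must exceed between_family_identity")
  }
  if (any(unlist(mobilome_rates) < 0) || heme_motif_rate < 0) {
    stop("rates must be non-negative")
  }
  stopifnot(n_families >= 1L, genomes_per_family >= 1L,
            n_gene_families >= 1L,
            single_copy_fraction >= 0, single_copy_fraction <= 1,
            within_family_identity > 0, within_family_identity <= 1,
            between_family_identity >= 0)
  structure(as.list(environment()), class = "synth_config")
}

.MARKER_NAMES <- data.frame(
  marker_id = c("ppcA", "ompJ", "cymA", "cbcA", "cbcB", "ribB", "ribE",
                "omcA"),
  category = c("periplasmic", "outer-membrane cytochrome/protein", "other",
               "cytochrome bc complex", "cytochrome bc complex",
               "riboflavin biosynthesis", "riboflavin biosynthesis",
               "outer-membrane cytochrome/protein"),
  stringsAsFactors = FALSE)

.rand_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

# mutate a fraction r of positions to a different residue
.mutate_seq <- function(seq, r) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < r)
  for (i in hit) {
    ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# plant non-overlapping heme-motif windows; wildcards avoid C/H so planted
# windows do not interact with each other
.plant_motifs <- function(seq, n_cxxch, n_cxxxch) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  len <- length(ch)
  pats <- c(rep(5L, n_cxxch), rep(6L, n_cxxxch))
  pats <- pats[sample.int(length(pats))]
  free <- rep(TRUE, len)
  wild <- setdiff(.AA20, c("C", "H"))
  for (w in pats) {
    ok <- which(vapply(seq_len(max(0L, len - w + 1L)), function(s) {
      all(free[s:(s + w - 1L)])
    }, NA))
    if (!length(ok)) next
    s <- if (length(ok) == 1L) ok else sample(ok, 1L)
    motif <- if (w == 5L) {
      c("C", sample(wild, 2L, replace = TRUE), "C", "H")
    } else {
      c("C", sample(wild, 3L, replace = TRUE), "C", "H")
    }
    ch[s:(s + w - 1L)] <- motif
    free[max(1L, s - 5L):min(len, s + w + 4L)] <- FALSE
  }
  paste(ch, collapse = "")
}

.rand_genome_fasta <- function(path, genome_id, len, gc, n_contigs = 3L) {
  cuts <- sort(sample(seq_len(len - 1L), n_contigs - 1L))
  sizes <- diff(c(0L, cuts, len))
  seqs <- vapply(sizes, function(sz) {
    paste(sample(c("G", "C", "A", "T"), sz, replace = TRUE,
                 prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
          collapse = "")
  }, "")
  write_fasta(sprintf("%s_contig%02d", genome_id, seq_along(seqs)), seqs,
              path)
}

#' Generate a complete synthetic study with truth tables
#'
#' Emits, under `out_dir`, every input the pipeline consumes -- per-genome
#' proteome and genome FASTA, an orthogroup table, localization, marker,
#' mobilome, CheckM and metadata TSVs -- together with `truth/` TSVs
#' recording the planted gene-family assignment, realized heme-motif
#' counts, localization labels, marker copy numbers and mobilome counts.
#' Heme motifs are planted after sequence mutation and the truth records
#' the counts the scanner actually realizes, so mutation can never silently
#' invalidate the truth. Output is byte-identical for identical
#' config + seed.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory (created if needed)
#' @return invisible list with `paths` (named file/directory paths),
#'   `truth` (in-memory truth tables) and `config`
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("proteome", "genome", "mobilome", "truth")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }

  fams <- sprintf("Family%02d", seq_len(config$n_families))
  metadata <- do.call(rbind, lapply(seq_along(fams), function(fi) {
    gids <- sprintf("G%02d%02d", fi, seq_len(config$genomes_per_family))
    data.frame(genome_id = gids, family = fams[fi],
               subclade = paste0(fams[fi], "_clade",
                                 rep(c("A", "B"),
                                     length.out = length(gids))),
               isolation_source = sample(
                 c("freshwater sediment", "marine sediment", "soil",
                   "oilfield", "host-associated"), length(gids),
                 replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  gids <- metadata$genome_id

  # --- gene families -------------------------------------------------------
  nf <- config$n_gene_families
  n_single <- round(config$single_copy_fraction * nf)
  gf_ids <- sprintf("GF%04d", seq_len(nf))
  single_copy <- c(rep(TRUE, n_single), rep(FALSE, nf - n_single))
  anc_len <- sample(150:450, nf, replace = TRUE)
  ancestors <- vapply(anc_len, .rand_protein, "")
  names(ancestors) <- gf_ids
  mut_rate <- 1 - sqrt(config$within_family_identity)

  prot_rows <- list()
  og_rows <- list()
  copy_count <- matrix(0L, nrow = length(gids), ncol = nf,
                       dimnames = list(gids, gf_ids))
  counter <- stats::setNames(rep(0L, length(gids)), gids)
  for (k in seq_len(nf)) {
    for (g in gids) {
      nc <- if (single_copy[k]) 1L else stats::rpois(1L, 1.0)
      copy_count[g, k] <- nc
      if (nc == 0L) next
      for (cp in seq_len(nc)) {
        counter[g] <- counter[g] + 1L
        pid <- sprintf("%s_p%04d", g, counter[g])
        seq <- .mutate_seq(ancestors[[k]], mut_rate)
        n5 <- stats::rpois(1L, config$heme_motif_rate * 0.85)
        n6 <- stats::rpois(1L, config$heme_motif_rate * 0.15)
        if (n5 + n6 > 0L) seq <- .plant_motifs(seq, n5, n6)
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          protein_id = pid, genome_id = g, sequence = seq,
          description = gf_ids[k], stringsAsFactors = FALSE)
        og_rows[[length(og_rows) + 1L]] <- data.frame(
          og_id = gf_ids[k], genome_id = g, protein_id = pid,
          stringsAsFactors = FALSE)
      }
    }
  }
  # orphan proteins assigned to no orthogroup
  for (g in gids) {
    for (o in seq_len(config$orphans_per_genome)) {
      counter[g] <- counter[g] + 1L
      pid <- sprintf("%s_p%04d", g, counter[g])
      seq <- .rand_protein(sample(100:300, 1L))
      n5 <- stats::rpois(1L, config$heme_motif_rate * 0.85)
      n6 <- stats::rpois(1L, config$heme_motif_rate * 0.15)
      if (n5 + n6 > 0L) seq <- .plant_motifs(seq, n5, n6)
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        protein_id = pid, genome_id = g, sequence = seq,
        description = "orphan", stringsAsFactors = FALSE)
    }
  }
  proteins <- do.call(rbind, prot_rows)
  og <- do.call(rbind, og_rows)

  # realized motif counts are the truth (recorded by scanning)
  scans <- lapply(proteins$sequence, scan_heme_motifs,
                  policy = "nonoverlap_greedy")
  true_motifs <- data.frame(
    protein_id = proteins$protein_id,
    n_cxxch = vapply(scans, function(h) sum(h$pattern == "CXXCH"), 0L),
    n_cxxxch = vapply(scans, function(h) sum(h$pattern == "CXXXCH"), 0L),
    stringsAsFactors = FALSE)

  localization <- data.frame(
    protein_id = proteins$protein_id,
    category = sample(LOCALIZATION_CATEGORIES, nrow(proteins),
                      replace = TRUE,
                      prob = c(0.05, 0.08, 0.12, 0.15, 0.45, 0.15)),
    stringsAsFactors = FALSE)

  # --- markers -------------------------------------------------------------
  n_markers <- max(1L, round(config$marker_fraction * nf))
  marker_gf <- sort(sample(gf_ids, n_markers))
  named <- utils::head(.MARKER_NAMES, n_markers)
  extra_n <- n_markers - nrow(named)
  markers <- rbind(named, if (extra_n > 0) data.frame(
    marker_id = sprintf("mkr%02d", seq_len(extra_n)),
    category = sample(MARKER_CATEGORIES, extra_n, replace = TRUE),
    stringsAsFactors = FALSE))
  markers$reference_protein_id <- paste0("REF_", markers$marker_id)
  markers$source_model <- sample(c("G. sulfurreducens PCA",
                                   "S. oneidensis MR-1"),
                                 n_markers, replace = TRUE)
  markers$gene_family <- marker_gf
  true_marker_copies <- copy_count[, marker_gf, drop = FALSE]
  colnames(true_marker_copies) <- markers$marker_id

  # --- mobilome ------------------------------------------------------------
  mr <- config$mobilome_rates
  ng <- length(gids)
  m_counts <- list(
    prophage_intact = stats::rpois(ng, mr$prophage_intact),
    prophage_questionable = stats::rpois(ng, mr$prophage_questionable),
    prophage_incomplete = stats::rpois(ng, mr$prophage_incomplete),
    crispr = stats::rpois(ng, mr$crispr),
    integron_complete = stats::rpois(ng, mr$integron_complete),
    integron_In0 = stats::rpois(ng, mr$integron_In0),
    integron_CALIN = stats::rpois(ng, mr$integron_CALIN),
    is_hits = stats::rpois(ng, mr$is_hits),
    ice = pmin(stats::rpois(ng, mr$ice), 5L))
  ice_types_pool <- c("T4SS_typeF", "T4SS_typeG", "T4SS_typeT",
                      "T4SS_typeB", "T4SS_typeI")
  prophage_tab <- do.call(rbind, lapply(seq_len(ng), function(i) {
    reps <- c(rep("intact", m_counts$prophage_intact[i]),
              rep("questionable", m_counts$prophage_questionable[i]),
              rep("incomplete", m_counts$prophage_incomplete[i]))
    if (!length(reps)) return(NULL)
    data.frame(genome_id = gids[i],
               region_id = sprintf("%s_ph%02d", gids[i], seq_along(reps)),
               completeness = reps, stringsAsFactors = FALSE)
  }))
  crispr_tab <- do.call(rbind, lapply(seq_len(ng), function(i) {
    k <- m_counts$crispr[i]
    if (!k) return(NULL)
    data.frame(genome_id = gids[i],
               array_id = sprintf("%s_cr%02d", gids[i], seq_len(k)),
               stringsAsFactors = FALSE)
  }))
  integron_tab <- do.call(rbind, lapply(seq_len(ng), function(i) {
    reps <- c(rep("complete", m_counts$integron_complete[i]),
              rep("In0", m_counts$integron_In0[i]),
              rep("CALIN", m_counts$integron_CALIN[i]))
    if (!length(reps)) return(NULL)
    data.frame(genome_id = gids[i],
               element_id = sprintf("%s_in%02d", gids[i], seq_along(reps)),
               kind = reps, stringsAsFactors = FALSE)
  }))
  is_families <- c("IS3", "IS4", "IS5", "IS21", "IS110", "IS256", "IS630")
  is_tab <- do.call(rbind, lapply(seq_len(ng), function(i) {
    k <- m_counts$is_hits[i]
    decoys <- stats::rpois(1L, 1.0)
    rows <- list()
    if (k) {
      rows[[1L]] <- data.frame(
        genome_id = gids[i],
        is_name = sprintf("%s_IS%02d", gids[i], seq_len(k)),
        family = sample(is_families, k, replace = TRUE),
        aln_length = sample(701:1500, k, replace = TRUE),
        evalue = 10^-stats::runif(k, 7, 30), stringsAsFactors = FALSE)
    }
    if (decoys) {
      fail_len <- stats::runif(decoys) < 0.5
      rows[[2L]] <- data.frame(
        genome_id = gids[i],
        is_name = sprintf("%s_ISx%02d", gids[i], seq_len(decoys)),
        family = sample(is_families, decoys, replace = TRUE),
        aln_length = ifelse(fail_len, sample(100:700, decoys,
                                             replace = TRUE),
                            sample(701:1500, decoys, replace = TRUE)),
        evalue = ifelse(fail_len, 10^-stats::runif(decoys, 7, 30),
                        10^-stats::runif(decoys, 0, 5.9)),
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) NULL else do.call(rbind, rows)
  }))
  ice_tab <- do.call(rbind, lapply(seq_len(ng), function(i) {
    k <- m_counts$ice[i]
    if (!k) return(NULL)
    data.frame(genome_id = gids[i],
               system_type = sample(ice_types_pool, k),
               stringsAsFactors = FALSE)
  }))
  true_mobilome <- data.frame(
    genome_id = gids,
    prophages_intact = m_counts$prophage_intact,
    prophages_questionable = m_counts$prophage_questionable,
    prophages_incomplete = m_counts$prophage_incomplete,
    crispr_arrays = m_counts$crispr,
    integrons_complete = m_counts$integron_complete,
    integrons_In0 = m_counts$integron_In0,
    integrons_CALIN = m_counts$integron_CALIN,
    is_count = m_counts$is_hits, ice_types = m_counts$ice,
    stringsAsFactors = FALSE)

  # --- genomes and QC ------------------------------------------------------
  glen <- pmax(20000L,
               round(stats::rnorm(ng, config$genome_length_mean_mbp * 1e6,
                                  config$genome_length_mean_mbp * 1e5)))
  gc <- stats::runif(ng, config$gc_range[1L], config$gc_range[2L])
  checkm <- data.frame(
    genome_id = gids,
    completeness = round(stats::runif(ng, 98.05, 99.95), 2L),
    contamination = round(stats::runif(ng, 0.05, 4.90), 2L),
    stringsAsFactors = FALSE)

  # --- write everything ----------------------------------------------------
  paths <- list(
    metadata = file.path(out_dir, "metadata.tsv"),
    checkm = file.path(out_dir, "checkm.tsv"),
    orthogroups = file.path(out_dir, "orthogroups.tsv"),
    localization = file.path(out_dir, "localization.tsv"),
    markers = file.path(out_dir, "markers.tsv"),
    marker_fasta = file.path(out_dir, "markers.faa"),
    proteome_dir = file.path(out_dir, "proteome"),
    genome_dir = file.path(out_dir, "genome"),
    mobilome_dir = file.path(out_dir, "mobilome"),
    truth_dir = file.path(out_dir, "truth"))
  write_tsv(metadata, paths$metadata)
  write_tsv(checkm, paths$checkm)
  write_orthogroups(og, gids, paths$orthogroups)
  write_tsv(localization, paths$localization)
  write_tsv(markers[, c("marker_id", "reference_protein_id", "source_model",
                        "category")], paths$markers)
  write_fasta(markers$reference_protein_id,
              unname(ancestors[markers$gene_family]), paths$marker_fasta,
              descriptions = markers$marker_id)
  for (g in gids) {
    sub <- proteins[proteins$genome_id == g, , drop = FALSE]
    write_fasta(sub$protein_id, sub$sequence,
                file.path(paths$proteome_dir, paste0(g, ".faa")),
                descriptions = sub$description)
  }
  for (i in seq_len(ng)) {
    .rand_genome_fasta(file.path(paths$genome_dir,
                                 paste0(gids[i], ".fna")),
                       gids[i], glen[i], gc[i])
  }
  mob_paths <- list(prophages = prophage_tab, crispr = crispr_tab,
                    integrons = integron_tab, is_hits = is_tab,
                    ices = ice_tab)
  for (nm in names(mob_paths)) {
    tab <- mob_paths[[nm]]
    if (is.null(tab)) {
      tab <- switch(nm,
        prophages = data.frame(genome_id = character(),
                               region_id = character(),
                               completeness = character()),
        crispr = data.frame(genome_id = character(),
                            array_id = character()),
        integrons = data.frame(genome_id = character(),
                               element_id = character(),
                               kind = character()),
        is_hits = data.frame(genome_id = character(),
                             is_name = character(), family = character(),
                             aln_length = numeric(), evalue = numeric()),
        ices = data.frame(genome_id = character(),
                          system_type = character()))
    }
    write_tsv(tab, file.path(paths$mobilome_dir, paste0(nm, ".tsv")))
  }
  tm <- cbind(data.frame(genome_id = gids, stringsAsFactors = FALSE),
              as.data.frame(true_marker_copies))
  write_tsv(data.frame(protein_id = proteins$protein_id,
                       gene_family = proteins$description,
                       stringsAsFactors = FALSE),
            file.path(paths$truth_dir, "true_og.tsv"))
  write_tsv(true_motifs, file.path(paths$truth_dir,
                                   "true_motif_counts.tsv"))
  write_tsv(localization, file.path(paths$truth_dir,
                                    "true_localization.tsv"))
  write_tsv(tm, file.path(paths$truth_dir, "true_marker_copies.tsv"))
  write_tsv(true_mobilome, file.path(paths$truth_dir, "true_mobilome.tsv"))

  truth <- list(true_og = stats::setNames(proteins$description,
                                          proteins$protein_id),
                true_motif_counts = true_motifs,
                true_localization = stats::setNames(localization$category,
                                                    localization$protein_id),
                true_marker_copies = true_marker_copies,
                true_mobilome = true_mobilome,
                markers = markers, single_copy_families =
                  gf_ids[single_copy],
                genome_length_bp = stats::setNames(glen, gids),
                gc_fraction = stats::setNames(gc, gids))
  invisible(list(paths = paths, truth = truth, config = config))
}

#' Planted-partition benchmark graph
#'
#' Bernoulli edges with probability `p_in` within and `p_out` between
#' blocks, unit weights; the truth is the block assignment.
#'
#' @param n_blocks,block_size number and size of the blocks
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`
#' @param seed RNG seed
#' @return list with `graph` (an `igraph`) and `membership` (named integer
#'   vector of true blocks)
#' @export
generate_planted_partition_graph <- function(n_blocks, block_size, p_in,
                                             p_out, seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("require 0 <= p_out < p_in <= 1")
  }
  rng <- .seeded_rng(seed)
  n <- n_blocks * block_size
  block <- rep(seq_len(n_blocks), each = block_size)
  names(block) <- sprintf("n%04d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  p <- ifelse(block[pairs[1L, ]] == block[pairs[2L, ]], p_in, p_out)
  keep <- rng$runif(ncol(pairs)) < p
  g <- igraph::graph_from_edgelist(
    cbind(names(block)[pairs[1L, keep]], names(block)[pairs[2L, keep]]),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(names(block), igraph::V(g)$name))
  g <- igraph::set_edge_attr(g, "weight", value = 1)
  list(graph = g, membership = block)
}

#' Feature table with a planted low-rank factor structure
#'
#' `X = Z L' + E` with standard-normal factor scores `Z` (n x k), loadings
#' `L` (p x k) and Gaussian noise `E`; useful for checking that PCA
#' recovers a known factor subspace.
#'
#' @param n_genomes number of rows
#' @param n_vars number of variables (13 gives the pipeline's feature
#'   column names)
#' @param n_factors planted rank
#' @param noise_sd standard deviation of the additive noise
#' @param seed RNG seed
#' @return list with `table` (data.frame incl. `genome_id`), `loadings_true`
#'   (p x k) and `scores_true` (n x k)
#' @export
generate_latent_feature_table <- function(n_genomes = 30L, n_vars = 13L,
                                          n_factors = 2L, noise_sd = 0.05,
                                          seed = 1L) {
  rng <- .seeded_rng(seed)
  Z <- matrix(stats::qnorm(rng$runif(n_genomes * n_factors)), n_genomes,
              n_factors)
  L <- matrix(stats::qnorm(rng$runif(n_vars * n_factors)), n_vars,
              n_factors)
  E <- matrix(stats::qnorm(rng$runif(n_genomes * n_vars)), n_genomes,
              n_vars) * noise_sd
  X <- Z %*% t(L) + E
  cols <- if (n_vars == length(FEATURE_COLUMNS)) FEATURE_COLUMNS else {
    sprintf("var%02d", seq_len(n_vars))
  }
  colnames(X) <- cols
  tab <- cbind(data.frame(genome_id = sprintf("G%03d", seq_len(n_genomes)),
                          stringsAsFactors = FALSE), as.data.frame(X))
  list(table = tab, loadings_true = L, scores_true = Z)
}
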