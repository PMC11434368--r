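# Shared fixtures, generated once per test run. Study sizes are scaled for
# a single-CPU run: 3 families x 4 genomes, 30 gene families, 0.02-Mbp
# filler genomes.
.fixture_env <- new.env(parent = emptyenv())

fixture_config <- function() {
  synth_config(seed = 42L, n_gene_families = 30L,
               genome_length_mean_mbp = 0.02)
}

study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "eetkit-study-fixture")
    old <- set_log_level("error")
    on.exit(set_log_level(old))
    .fixture_env$study <- generate_study(fixture_config(), dir)
  }
  .fixture_env$study
}

study_genome_set <- function() {
  if (is.null(.fixture_env$gs)) {
    st <- study_fixture()
    gids <- names(st$truth$genome_length_bp)
    old <- set_log_level("error")
    on.exit(set_log_level(old))
    .fixture_env$gs <- load_genome_set(
      stats::setNames(file.path(st$paths$proteome_dir,
                                paste0(gids, ".faa")), gids),
      st$paths$metadata,
      genome_info = data.frame(
        genome_id = gids,
        genome_length_bp = unname(st$truth$genome_length_bp),
        gc_fraction = unname(st$truth$gc_fraction)))
  }
  .fixture_env$gs
}

pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    st <- study_fixture()
    out <- file.path(tempdir(), "eetkit-pipeline-fixture")
    old <- set_log_level("error")
    on.exit(set_log_level(old))
    .fixture_env$pipeline <- list(
      manifest = run_pipeline(dirname(st$paths$metadata), out, seed = 7L),
      out_dir = out)
  }
  .fixture_env$pipeline
}

ssn_fixture <- function() {
  if (is.null(.fixture_env$ssn)) {
    st <- study_fixture()
    gs <- study_genome_set()
    og <- suppressMessages(parse_orthogroups(st$paths$orthogroups))
    loc <- data.frame(protein_id = names(st$truth$true_localization),
                      category = unname(st$truth$true_localization),
                      stringsAsFactors = FALSE)
    ann <- suppressMessages(annotate_proteome(gs, loc))
    sel <- select_network_sequences(og, ann)
    .fixture_env$ssn <- build_ssn(gs, protein_ids = sel, og = og)
  }
  .fixture_env$ssn
}

# tiny genome set built in code
toy_genome_set <- function(seqs_by_genome, families = NULL) {
  genomes <- names(seqs_by_genome)
  if (is.null(families)) families <- rep("FamA", length(genomes))
  proteins <- do.call(rbind, lapply(genomes, function(g) {
    s <- seqs_by_genome[[g]]
    data.frame(protein_id = names(s), genome_id = g, sequence = unname(s),
               stringsAsFactors = FALSE)
  }))
  genome_set(proteins,
             data.frame(genome_id = genomes, family = families,
                        stringsAsFactors = FALSE))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}
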