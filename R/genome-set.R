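#' Construct a genome set
#'
#' The central container every stage indexes into: protein sequences grouped
#' by genome, with family/subclade/isolation-source labels. Genome ids are
#' the join key throughout the pipeline; family labels live only in the
#' metadata to avoid duplication.
#'
#' @param proteins data.frame with columns `protein_id`, `genome_id`,
#'   `sequence`, and optionally `description`
#' @param metadata data.frame with columns `genome_id`, `family`, and
#'   optionally `subclade`, `isolation_source`
#' @param genome_info optional data.frame with columns `genome_id`,
#'   `genome_length_bp`, `gc_fraction`
#' @return an object of class `genome_set`
#' @export
genome_set <- function(proteins, metadata, genome_info = NULL) {
  stopifnot(all(c("protein_id", "genome_id", "sequence") %in%
                  names(proteins)),
            all(c("genome_id", "family") %in% names(metadata)))
  if (!"description" %in% names(proteins)) proteins$description <- ""
  if (!"subclade" %in% names(metadata)) metadata$subclade <- ""
  if (!"isolation_source" %in% names(metadata)) {
    metadata$isolation_source <- "unknown"
  }
  if (anyDuplicated(metadata$genome_id)) {
    stop("duplicate genome_id in metadata: ",
         metadata$genome_id[duplicated(metadata$genome_id)][1L])
  }
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein_id: ",
         proteins$protein_id[duplicated(proteins$protein_id)][1L])
  }
  orphan <- setdiff(proteins$genome_id, metadata$genome_id)
  if (length(orphan)) {
    stop("protein genome_id(s) absent from metadata: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  if (any(grepl("\\s", proteins$protein_id))) {
    stop("protein_id must not contain whitespace")
  }
  if (any(nchar(proteins$sequence) < 1L)) stop("empty protein sequence")
  bad <- grepl(sprintf("[^%sX]", paste(.AA20, collapse = "")),
               proteins$sequence)
  if (any(bad)) {
    stop("non-normalized protein sequence for ",
         proteins$protein_id[bad][1L],
         " (run read_fasta() with alphabet = 'protein')")
  }
  if (!is.null(genome_info)) {
    stopifnot(all(c("genome_id", "genome_length_bp") %in% names(genome_info)))
    if (!"gc_fraction" %in% names(genome_info)) {
      genome_info$gc_fraction <- NA_real_
    }
  }
  structure(list(proteins = proteins, metadata = metadata,
                 genome_info = genome_info),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", nrow(x$metadata), "genome(s),",
      nrow(x$proteins), "protein(s),",
      length(unique(x$metadata$family)), "family(ies)\n")
  invisible(x)
}

#' Genome ids of a genome set
#' @param gs a `genome_set`
#' @return character vector
#' @export
genome_ids <- function(gs) gs$metadata$genome_id

#' Named genome -> family lookup
#' @param gs a `genome_set`
#' @return named character vector keyed by genome_id
#' @export
family_map <- function(gs) {
  stats::setNames(gs$metadata$family, gs$metadata$genome_id)
}

#' Load a genome set from proteome FASTA files plus a metadata table
#'
#' @param proteome_paths character vector of FASTA paths, named by genome_id
#' @param metadata_path path to a metadata TSV
#'   (columns `genome_id`, `family`, optional `subclade`, `isolation_source`)
#' @param genome_info optional data.frame as in [genome_set()]
#' @return a `genome_set`
#' @export
load_genome_set <- function(proteome_paths, metadata_path,
                            genome_info = NULL) {
  metadata <- read_table(metadata_path, "metadata")
  if (is.null(names(proteome_paths))) {
    stop("proteome_paths must be named by genome_id")
  }
  proteins <- do.call(rbind, lapply(names(proteome_paths), function(g) {
    fa <- read_fasta(proteome_paths[[g]], alphabet = "protein")
    data.frame(protein_id = fa$id, genome_id = g, sequence = fa$sequence,
               description = fa$description, stringsAsFactors = FALSE)
  }))
  genome_set(proteins, metadata, genome_info)
}
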