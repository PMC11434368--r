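#' Subcellular localization vocabulary (PSORTb-style)
#' @export
LOCALIZATION_CATEGORIES <- c("extracellular", "outer membrane", "periplasmic",
                             "cytoplasmic membrane", "cytoplasmic", "unknown")

#' EET marker functional categories
#' @export
MARKER_CATEGORIES <- c("outer-membrane cytochrome/protein", "periplasmic",
                       "porin-cytochrome complex", "cytochrome bc complex",
                       "riboflavin biosynthesis", "other")

#' Fixed column order of the genomic feature table
#' @export
FEATURE_COLUMNS <- c("genome_size_mbp", "gc_percent", "prophages",
                     "total_cyt_per_mbp", "integrons_complete",
                     "crispr_arrays", "is_count", "ice_types", "ppcA_copies",
                     "ompJ_copies", "cbc_copies_sum", "cymA_copies",
                     "rib_copies_sum")

# Registry of TSV schemas: required/optional columns, numeric columns and
# fixed category vocabularies. All external tables are TSV with header rows.
.schemas <- list(
  orthogroups = list(required = "Orthogroup", optional = character(),
                     numeric = character(), levels = list()),
  localization = list(required = c("protein_id", "category"),
                      optional = character(), numeric = character(),
                      levels = list(category = LOCALIZATION_CATEGORIES)),
  markers = list(required = c("marker_id", "reference_protein_id",
                              "source_model", "category"),
                 optional = character(), numeric = character(),
                 levels = list(category = MARKER_CATEGORIES)),
  checkm = list(required = c("genome_id", "completeness", "contamination"),
                optional = character(),
                numeric = c("completeness", "contamination"), levels = list()),
  metadata = list(required = c("genome_id", "family"),
                  optional = c(subclade = "", isolation_source = "unknown"),
                  numeric = character(), levels = list()),
  features = list(required = c("genome_id", FEATURE_COLUMNS),
                  optional = character(), numeric = FEATURE_COLUMNS,
                  levels = list()),
  prophages = list(required = c("genome_id", "region_id", "completeness"),
                   optional = character(), numeric = character(),
                   levels = list(completeness = c("intact", "questionable",
                                                  "incomplete"))),
  crispr = list(required = c("genome_id", "array_id"),
                optional = character(), numeric = character(), levels = list()),
  integrons = list(required = c("genome_id", "element_id", "kind"),
                   optional = character(), numeric = character(),
                   levels = list(kind = c("complete", "In0", "CALIN"))),
  is_hits = list(required = c("genome_id", "is_name", "family", "aln_length",
                              "evalue"),
                 optional = character(), numeric = c("aln_length", "evalue"),
                 levels = list()),
  ices = list(required = c("genome_id", "system_type"),
              optional = character(), numeric = character(), levels = list())
)

#' Names of the registered TSV schemas
#' @return character vector of schema names accepted by [read_table()]
#' @export
table_schemas <- function() names(.schemas)

#' Read and validate a tab-separated table against a named schema
#'
#' All pipeline tables are TSV with a header row. Required columns must be
#' present; missing optional columns are filled with the schema default;
#' columns with a fixed vocabulary are checked against it.
#'
#' @param path path to a TSV file
#' @param schema_name one of [table_schemas()]
#' @return a data.frame validated against the schema
#' @export
read_table <- function(path, schema_name) {
  if (!schema_name %in% names(.schemas)) {
    stop("unknown schema '", schema_name, "'; known: ",
         paste(names(.schemas), collapse = ", "))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- .schemas[[schema_name]]
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_req <- setdiff(sch$required, names(tab))
  if (length(missing_req)) {
    stop("schema '", schema_name, "': missing required column(s) ",
         paste(missing_req, collapse = ", "), " in ", path)
  }
  for (col in names(sch$optional)) {
    if (!col %in% names(tab)) tab[[col]] <- sch$optional[[col]]
  }
  for (col in sch$numeric) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(val) && !anyNA(tab[[col]])) {
      stop("schema '", schema_name, "': non-numeric value in column '",
           col, "'")
    }
    tab[[col]] <- val
  }
  for (col in names(sch$levels)) {
    bad <- setdiff(unique(tab[[col]]), sch$levels[[col]])
    if (length(bad)) {
      stop("schema '", schema_name, "': invalid value(s) in '", col, "': ",
           paste(bad, collapse = ", "))
    }
  }
  eet_log("info", "read ", nrow(tab), " row(s) from ", basename(path),
          " [schema ", schema_name, "]")
  tab
}

#' Write a data.frame as a TSV with a header row
#'
#' @param tab a data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
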