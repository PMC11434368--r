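.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a FASTA file with alphabet normalization
#'
#' Sequences are upper-cased. For the protein alphabet, characters outside
#' the 20 standard amino acids are replaced by `X` (unknown); for the
#' nucleotide alphabet, characters outside `ACGT` are mapped to `N`. The
#' number of replacements is logged. Record order is preserved.
#'
#' @param path path to a FASTA file
#' @param alphabet `"protein"` or `"nucleotide"`
#' @return a data.frame with columns `id`, `description`, `sequence`, with
#'   attribute `n_replaced` giving the normalized-character count
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: empty file ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate id ", ids[duplicated(ids)][1L], " in ", path)
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "protein") {
    clean <- gsub(sprintf("[^%sX]", paste(.AA20, collapse = "")), "X", seqs)
  } else {
    clean <- gsub("[^ACGTN]", "N", seqs)
  }
  n_replaced <- sum(nchar(seqs)) - sum(mapply(
    function(a, b) sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]),
    seqs, clean, USE.NAMES = FALSE))
  if (n_replaced > 0) {
    eet_log("warning", n_replaced, " non-standard character(s) normalized in ",
            basename(path))
  }
  out <- data.frame(id = unname(ids), description = unname(desc),
                    sequence = unname(clean), stringsAsFactors = FALSE)
  attr(out, "n_replaced") <- as.integer(n_replaced)
  out
}

#' Write sequences to a FASTA file
#'
#' @param ids,sequences character vectors of equal length
#' @param path output path
#' @param descriptions optional descriptions appended to headers
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(ids, sequences, path, descriptions = NULL,
                        width = 70L) {
  stopifnot(length(ids) == length(sequences))
  headers <- if (is.null(descriptions)) ids else {
    ifelse(nzchar(descriptions), paste(ids, descriptions), ids)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    s <- sequences[[i]]
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", headers[[i]]), chunks), con)
  }
  invisible(path)
}
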