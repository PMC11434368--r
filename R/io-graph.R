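#' Write a similarity-network graph to disk
#'
#' GraphML output carries all node attributes (genome, family, orthogroup,
#' community) and edge attributes, and is suitable for external layout in
#' Gephi-style tools. The edge TSV has fixed columns
#' `(source, target, score, evalue, identity, coverage, weight)`.
#'
#' @param graph an `igraph` object whose vertices are named
#' @param path output path
#' @param format `"graphml"` or `"edge_tsv"`
#' @return `path`, invisibly
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ok <- tryCatch({
      igraph::write_graph(graph, path, format = "graphml")
      TRUE
    }, error = function(e) {
      stop("I/O error writing ", path, ": ", conditionMessage(e))
    })
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    get_attr <- function(a) {
      if (a %in% igraph::edge_attr_names(graph)) {
        igraph::edge_attr(graph, a)
      } else {
        rep(NA_real_, nrow(el))
      }
    }
    tab <- data.frame(source = el[, 1L], target = el[, 2L],
                      score = get_attr("score"), evalue = get_attr("evalue"),
                      identity = get_attr("identity"),
                      coverage = get_attr("coverage"),
                      weight = get_attr("weight"),
                      stringsAsFactors = FALSE)
    write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a graph written by [write_graph_file()]
#'
#' GraphML round-trips node and edge sets and attributes. The edge-TSV form
#' carries edges only, so isolated nodes are not recoverable from it.
#'
#' @param path input path
#' @param format `"graphml"` or `"edge_tsv"`
#' @return an `igraph` object
#' @export
read_graph_file <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(tab, directed = FALSE)
}
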