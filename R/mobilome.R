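#' Filter insertion-sequence hits
#'
#' Keeps rows with alignment length strictly over `min_length` (default
#' 700 bp) and E-value at or below `evalue_max` (default 1e-6). Rows with
#' negative lengths are rejected with a warning.
#'
#' @param hits data.frame with columns `genome_id`, `is_name`, `family`,
#'   `aln_length`, `evalue` (the `is_hits` TSV schema)
#' @param min_length strict lower bound on alignment length (bp)
#' @param evalue_max inclusive upper bound on E-value
#' @param genome_ids optional genome universe for the count vector (genomes
#'   without retained hits get 0)
#' @return list with `filtered` (retained rows) and `counts` (named integer
#'   vector per genome)
#' @export
filter_is_hits <- function(hits, min_length = 700, evalue_max = 1e-6,
                           genome_ids = NULL) {
  neg <- !is.na(hits$aln_length) & hits$aln_length < 0
  if (any(neg)) {
    eet_log("warning", sum(neg), " IS hit row(s) with negative length ",
            "rejected")
    hits <- hits[!neg, , drop = FALSE]
  }
  keep <- hits$aln_length > min_length & hits$evalue <= evalue_max
  filtered <- hits[keep, , drop = FALSE]
  universe <- if (is.null(genome_ids)) unique(hits$genome_id) else genome_ids
  counts <- table(factor(filtered$genome_id, levels = universe))
  list(filtered = filtered,
       counts = stats::setNames(as.integer(counts), universe))
}

#' Aggregate per-genome mobile-genetic-element profiles
#'
#' Consumes normalized per-element TSV tables (the detection tools
#' themselves are external; their reports are assumed already reduced to
#' these schemas) and produces one row per genome: prophage counts by
#' completeness category, CRISPR arrays, integron elements by kind, retained
#' IS hits, distinct conjugation-system (ICE) types, and prophage density
#' (prophages per Mbp of genome).
#'
#' @param gs a [genome_set()] whose `genome_info` carries `genome_length_bp`
#' @param prophages,crispr,integrons,is_hits,ices data.frames in the
#'   respective TSV schemas (any may be `NULL` for all-zero counts)
#' @param is_min_length,is_evalue_max IS filter parameters, see
#'   [filter_is_hits()]
#' @param density_numerator `"total"` (default) or `"intact"`: which
#'   prophage count enters the density
#' @return data.frame with one row per genome
#' @export
build_mobilome_profiles <- function(gs, prophages = NULL, crispr = NULL,
                                    integrons = NULL, is_hits = NULL,
                                    ices = NULL, is_min_length = 700,
                                    is_evalue_max = 1e-6,
                                    density_numerator = c("total",
                                                          "intact")) {
  density_numerator <- match.arg(density_numerator)
  stopifnot(inherits(gs, "genome_set"))
  gids <- genome_ids(gs)
  check_known <- function(tab, what) {
    if (is.null(tab)) return(invisible(NULL))
    bad <- setdiff(unique(tab$genome_id), gids)
    if (length(bad)) {
      stop(what, " table references genome(s) not in the genome set: ",
           paste(bad, collapse = ", "))
    }
    miss <- setdiff(gids, unique(tab$genome_id))
    if (length(miss)) {
      eet_log("warning", what, ": ", length(miss),
              " genome(s) absent from table, counted as zero")
    }
    invisible(NULL)
  }
  check_known(prophages, "prophage")
  check_known(crispr, "CRISPR")
  check_known(integrons, "integron")
  check_known(is_hits, "IS")
  check_known(ices, "ICE")
  count_by <- function(tab, filter = NULL) {
    if (is.null(tab) || nrow(tab) == 0L) {
      return(stats::setNames(integer(length(gids)), gids))
    }
    sub <- if (is.null(filter)) tab else tab[filter(tab), , drop = FALSE]
    cnt <- table(factor(sub$genome_id, levels = gids))
    stats::setNames(as.integer(cnt), gids)
  }
  p_int <- count_by(prophages, function(t) t$completeness == "intact")
  p_que <- count_by(prophages, function(t) t$completeness == "questionable")
  p_inc <- count_by(prophages, function(t) t$completeness == "incomplete")
  n_crispr <- count_by(crispr)
  i_com <- count_by(integrons, function(t) t$kind == "complete")
  i_in0 <- count_by(integrons, function(t) t$kind == "In0")
  i_cal <- count_by(integrons, function(t) t$kind == "CALIN")
  n_is <- if (is.null(is_hits) || nrow(is_hits) == 0L) {
    stats::setNames(integer(length(gids)), gids)
  } else {
    filter_is_hits(is_hits, min_length = is_min_length,
                   evalue_max = is_evalue_max, genome_ids = gids)$counts
  }
  n_ice <- if (is.null(ices) || nrow(ices) == 0L) {
    stats::setNames(integer(length(gids)), gids)
  } else {
    v <- vapply(gids, function(g) {
      length(unique(ices$system_type[ices$genome_id == g]))
    }, 0L)
    stats::setNames(v, gids)
  }
  if (is.null(gs$genome_info)) {
    stop("genome_set carries no genome_info (genome_length_bp needed for ",
         "prophage density)")
  }
  len_bp <- gs$genome_info$genome_length_bp[
    match(gids, gs$genome_info$genome_id)]
  if (anyNA(len_bp) || any(len_bp <= 0)) {
    stop("genome_length_bp must be known and positive for every genome")
  }
  total <- p_int + p_que + p_inc
  dens_num <- if (density_numerator == "total") total else p_int
  data.frame(
    genome_id = gids,
    prophages_intact = p_int, prophages_questionable = p_que,
    prophages_incomplete = p_inc, prophages_total = total,
    crispr_arrays = n_crispr,
    integrons_complete = i_com, integrons_In0 = i_in0,
    integrons_CALIN = i_cal,
    is_count = n_is, ice_types = n_ice,
    prophage_density = dens_num / (len_bp / 1e6),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-family (and per-subclade) mobilome summary
#'
#' For each grouping level: the mean count per strain of each element, the
#' prevalence (fraction of strains with at least one), and the mean
#' prophage density.
#'
#' @param profiles data.frame from [build_mobilome_profiles()]
#' @param fam_map named vector genome_id -> family
#' @param subclade_map optional named vector genome_id -> subclade; when
#'   given, per-subclade rows are appended with `level = "subclade"`
#' @return data.frame with one row per group
#' @export
family_mobilome_summary <- function(profiles, fam_map, subclade_map = NULL) {
  elements <- c("prophages_total", "prophages_intact",
                "prophages_questionable", "prophages_incomplete",
                "crispr_arrays", "integrons_complete", "integrons_In0",
                "integrons_CALIN", "is_count", "ice_types")
  one_level <- function(map, level) {
    groups <- sort(unique(unname(map[profiles$genome_id])))
    do.call(rbind, lapply(groups, function(grp) {
      sub <- profiles[unname(map[profiles$genome_id]) == grp, , drop = FALSE]
      row <- data.frame(level = level, group = grp, n_strains = nrow(sub),
                        stringsAsFactors = FALSE)
      for (el in elements) {
        row[[paste0("mean_", el)]] <- mean(sub[[el]])
        row[[paste0("prevalence_", el)]] <- mean(sub[[el]] >= 1)
      }
      row$mean_prophage_density <- mean(sub$prophage_density)
      row
    }))
  }
  out <- one_level(fam_map, "family")
  if (!is.null(subclade_map)) {
    out <- rbind(out, one_level(subclade_map, "subclade"))
  }
  out
}
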