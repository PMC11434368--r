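test_that("IS filter boundary behavior is strict on length, inclusive on E", {
  hits <- data.frame(
    genome_id = "g1", is_name = paste0("is", 1:4), family = "IS3",
    aln_length = c(700, 701, 701, 800), evalue = c(1e-7, 1e-7, 1e-6, 1e-5),
    stringsAsFactors = FALSE)
  res <- filter_is_hits(hits, genome_ids = "g1")
  expect_equal(res$counts[["g1"]], 2L)  # 700 rejected, 1e-5 rejected
  expect_setequal(res$filtered$is_name, c("is2", "is3"))
})

test_that("IS filter warns on negative lengths and zeros empty tables", {
  hits <- data.frame(genome_id = "g1", is_name = "bad", family = "IS3",
                     aln_length = -5, evalue = 1e-9,
                     stringsAsFactors = FALSE)
  expect_message(res <- filter_is_hits(hits, genome_ids = c("g1", "g2")),
                 "negative")
  expect_equal(unname(res$counts), c(0L, 0L))
  empty <- hits[0, ]
  res <- filter_is_hits(empty, genome_ids = c("g1", "g2"))
  expect_equal(unname(res$counts), c(0L, 0L))
})

test_that("IS filter equals a brute-force row scan on random tables", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(1:40, 1)
    hits <- data.frame(
      genome_id = sample(paste0("g", 1:3), n, replace = TRUE),
      is_name = paste0("is", 1:n), family = "IS5",
      aln_length = sample(400:1200, n, replace = TRUE),
      evalue = 10^-runif(n, 0, 12), stringsAsFactors = FALSE)
    res <- filter_is_hits(hits, genome_ids = paste0("g", 1:3))
    for (g in paste0("g", 1:3)) {
      brute <- sum(hits$genome_id == g & hits$aln_length > 700 &
                     hits$evalue <= 1e-6)
      expect_equal(res$counts[[g]], brute)
    }
  }
})

mob_gs <- function() {
  gs <- toy_genome_set(list(g1 = c(p1 = "MKVL"), g2 = c(p2 = "MKVL")),
                       families = c("F1", "F2"))
  gs$genome_info <- data.frame(genome_id = c("g1", "g2"),
                               genome_length_bp = c(4e6, 2e6),
                               gc_fraction = c(0.6, 0.55))
  gs
}

test_that("profile totals, zeros and densities are exact", {
  gs <- mob_gs()
  prophages <- data.frame(
    genome_id = c(rep("g1", 6), rep("g2", 2)),
    region_id = paste0("ph", 1:8),
    completeness = c("intact", "intact", "questionable", "incomplete",
                     "incomplete", "incomplete", "intact", "intact"),
    stringsAsFactors = FALSE)
  prof <- suppressMessages(build_mobilome_profiles(gs, prophages = prophages))
  p1 <- prof[prof$genome_id == "g1", ]
  expect_equal(p1$prophages_intact, 2L)
  expect_equal(p1$prophages_questionable, 1L)
  expect_equal(p1$prophages_incomplete, 3L)
  expect_equal(p1$prophages_total, 6L)
  expect_equal(p1$prophage_density, 6 / 4)
  # genome absent from a table gets zero
  expect_equal(p1$crispr_arrays, 0L)
  # 8 total prophages in a 4-Mbp genome would be density 2.0
  prophages2 <- rbind(prophages,
                      data.frame(genome_id = c("g1", "g1"),
                                 region_id = c("ph9", "ph10"),
                                 completeness = c("intact", "intact")))
  prof2 <- suppressMessages(build_mobilome_profiles(gs,
                                                    prophages = prophages2))
  expect_equal(prof2$prophage_density[prof2$genome_id == "g1"], 2.0)
  # intact-only density mode
  prof3 <- suppressMessages(build_mobilome_profiles(
    gs, prophages = prophages, density_numerator = "intact"))
  expect_equal(prof3$prophage_density[prof3$genome_id == "g1"], 2 / 4)
})

test_that("unknown genomes in element tables are an error", {
  gs <- mob_gs()
  bad <- data.frame(genome_id = "ghost", region_id = "ph1",
                    completeness = "intact", stringsAsFactors = FALSE)
  expect_error(build_mobilome_profiles(gs, prophages = bad), "ghost")
})

test_that("ICE metric counts distinct conjugation-system types", {
  gs <- mob_gs()
  ices <- data.frame(genome_id = c("g1", "g1", "g1", "g2"),
                     system_type = c("T4SS_typeF", "T4SS_typeF",
                                     "T4SS_typeG", "T4SS_typeT"),
                     stringsAsFactors = FALSE)
  prof <- suppressMessages(build_mobilome_profiles(gs, ices = ices))
  expect_equal(prof$ice_types[prof$genome_id == "g1"], 2L)
  expect_equal(prof$ice_types[prof$genome_id == "g2"], 1L)
})

test_that("family summary prevalence and means are exact", {
  profiles <- data.frame(
    genome_id = paste0("g", 1:4),
    prophages_intact = 0L, prophages_questionable = 0L,
    prophages_incomplete = 0L, prophages_total = 0L,
    crispr_arrays = 0L, integrons_complete = 0L, integrons_In0 = 0L,
    integrons_CALIN = 0L, is_count = c(0L, 0L, 2L, 5L), ice_types = 0L,
    prophage_density = 0, stringsAsFactors = FALSE)
  fam <- stats::setNames(rep("F", 4), paste0("g", 1:4))
  s <- family_mobilome_summary(profiles, fam)
  expect_equal(s$prevalence_is_count, 0.5)
  expect_equal(s$mean_is_count, 1.75)
  expect_equal(s$prevalence_prophages_total, 0)
})

test_that("aggregation is a linear fold over disjoint genome sets", {
  set.seed(73)
  profiles <- data.frame(
    genome_id = paste0("g", 1:8),
    prophages_intact = rpois(8, 1), prophages_questionable = rpois(8, 1),
    prophages_incomplete = rpois(8, 2), crispr_arrays = rpois(8, 2),
    integrons_complete = rpois(8, 1), integrons_In0 = rpois(8, 1),
    integrons_CALIN = rpois(8, 1), is_count = rpois(8, 4),
    ice_types = rpois(8, 1), stringsAsFactors = FALSE)
  profiles$prophages_total <- profiles$prophages_intact +
    profiles$prophages_questionable + profiles$prophages_incomplete
  profiles$prophage_density <- profiles$prophages_total / 4
  fam <- stats::setNames(rep("F", 8), profiles$genome_id)
  whole <- family_mobilome_summary(profiles, fam)
  part1 <- family_mobilome_summary(profiles[1:3, ], fam[1:3])
  part2 <- family_mobilome_summary(profiles[4:8, ], fam[4:8])
  pooled <- (3 * part1$mean_is_count + 5 * part2$mean_is_count) / 8
  expect_equal(whole$mean_is_count, pooled)
  pooled_prev <- (3 * part1$prevalence_crispr_arrays +
                    5 * part2$prevalence_crispr_arrays) / 8
  expect_equal(whole$prevalence_crispr_arrays, pooled_prev)
})

test_that("profiles and summaries equal the generator truth", {
  st <- study_fixture()
  gs <- study_genome_set()
  mdir <- st$paths$mobilome_dir
  prof <- suppressMessages(build_mobilome_profiles(
    gs,
    prophages = read_table(file.path(mdir, "prophages.tsv"), "prophages"),
    crispr = read_table(file.path(mdir, "crispr.tsv"), "crispr"),
    integrons = read_table(file.path(mdir, "integrons.tsv"), "integrons"),
    is_hits = read_table(file.path(mdir, "is_hits.tsv"), "is_hits"),
    ices = read_table(file.path(mdir, "ices.tsv"), "ices")))
  truth <- st$truth$true_mobilome
  idx <- match(prof$genome_id, truth$genome_id)
  for (col in c("prophages_intact", "prophages_questionable",
                "prophages_incomplete", "crispr_arrays",
                "integrons_complete", "integrons_In0", "integrons_CALIN",
                "is_count", "ice_types")) {
    expect_equal(prof[[col]], truth[[col]][idx], ignore_attr = TRUE,
                 label = col)
  }
  # summary equals a direct aggregation of the truth
  fam <- family_map(gs)
  s <- family_mobilome_summary(prof, fam)
  fs <- s[s$level == "family", ]
  for (f in fs$group) {
    g_in_f <- names(fam)[fam == f]
    expect_equal(fs$mean_crispr_arrays[fs$group == f],
                 mean(truth$crispr_arrays[truth$genome_id %in% g_in_f]))
    expect_equal(fs$prevalence_is_count[fs$group == f],
                 mean(truth$is_count[truth$genome_id %in% g_in_f] >= 1))
  }
})
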