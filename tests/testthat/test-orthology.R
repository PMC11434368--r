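write_og_tsv <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}

test_that("orthogroup table parsing follows the OrthoFinder dialect", {
  p <- write_og_tsv(c("Orthogroup\tA\tB\tC", "OG0000001\tp1, p2\t\tp3"))
  og <- suppressMessages(parse_orthogroups(p))
  expect_equal(og$og_id, rep("OG0000001", 3))
  expect_equal(og$protein_id[og$genome_id == "A"], c("p1", "p2"))
  expect_equal(og$protein_id[og$genome_id == "C"], "p3")
  expect_equal(attr(og, "genome_ids"), c("A", "B", "C"))
})

test_that("empty orthogroups and duplicated memberships are errors", {
  p <- write_og_tsv(c("Orthogroup\tA\tB", "OG1\t\t"))
  expect_error(suppressMessages(parse_orthogroups(p)), "empty orthogroup")
  p <- write_og_tsv(c("Orthogroup\tA\tB", "OG1\tp1\tp2", "OG2\tp1\t"))
  expect_error(suppressMessages(parse_orthogroups(p)),
               "p1 listed in two orthogroups")
})

test_that("orthogroup write/parse round-trips", {
  og <- data.frame(og_id = c("OG1", "OG1", "OG2"),
                   genome_id = c("A", "B", "A"),
                   protein_id = c("p1", "p2", "p3"),
                   stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_orthogroups(og, c("A", "B"), p)
  back <- suppressMessages(parse_orthogroups(p))
  expect_equal(back[order(back$protein_id),
                    c("og_id", "genome_id", "protein_id")],
               og[order(og$protein_id), ], ignore_attr = TRUE)
})

test_that("single-copy selection matches its definition and a brute force", {
  og <- data.frame(
    og_id = c("OG1", "OG1", "OG2", "OG2", "OG2", "OG3"),
    genome_id = c("A", "B", "A", "A", "B", "A"),
    protein_id = paste0("p", 1:6), stringsAsFactors = FALSE)
  expect_equal(single_copy_core(og, c("A", "B")), "OG1")

  set.seed(31)
  for (rep in 1:100) {
    genomes <- paste0("g", 1:4)
    n_og <- 50
    rows <- list()
    pid <- 0
    for (o in seq_len(n_og)) {
      for (g in genomes) {
        k <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
        if (k > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            og_id = sprintf("OG%03d", o), genome_id = g,
            protein_id = paste0("p", pid + seq_len(k)),
            stringsAsFactors = FALSE)
          pid <- pid + k
        }
      }
    }
    og <- do.call(rbind, rows)
    # brute force: per og, tabulate and require exactly one per genome
    expected <- sort(Filter(function(o) {
      sub <- og[og$og_id == o, ]
      all(vapply(genomes, function(g) sum(sub$genome_id == g), 0L) == 1L)
    }, unique(og$og_id)))
    expect_equal(single_copy_core(og, genomes), expected)
  }
})

test_that("sharing statistics match brute-force recomputation", {
  set.seed(37)
  genomes <- paste0("g", 1:6)
  fam <- stats::setNames(rep(c("F1", "F2", "F3"), each = 2), genomes)
  for (rep in 1:100) {
    rows <- list()
    pid <- 0
    for (o in 1:30) {
      present <- genomes[sample(c(TRUE, FALSE), 6, replace = TRUE,
                                prob = c(0.5, 0.5))]
      if (!length(present)) next
      for (g in present) {
        pid <- pid + 1
        rows[[length(rows) + 1]] <- data.frame(
          og_id = sprintf("OG%02d", o), genome_id = g,
          protein_id = paste0("p", pid), stringsAsFactors = FALSE)
      }
    }
    og <- do.call(rbind, rows)
    st <- og_sharing_stats(og, fam)
    sp <- split(og$genome_id, og$og_id)
    expect_equal(st$n_universal,
                 sum(vapply(sp, function(g) all(genomes %in% g), NA)))
    expect_equal(st$n_species_specific,
                 sum(vapply(sp, function(g) length(unique(g)) == 1, NA)))
    fams_of <- lapply(sp, function(g) unique(unname(fam[g])))
    expect_equal(st$n_family_exclusive,
                 sum(vapply(seq_along(sp), function(i) {
                   length(fams_of[[i]]) == 1 &&
                     length(unique(sp[[i]])) >= 2
                 }, NA)))
    for (r in seq_len(nrow(st$family_pairs))) {
      pr <- sort(c(st$family_pairs$family_a[r], st$family_pairs$family_b[r]))
      expect_equal(st$family_pairs$n_ogs[r],
                   sum(vapply(fams_of, function(f) {
                     identical(sort(f), pr)
                   }, NA)))
    }
  }
})

test_that("supermatrix concatenation is sorted, partitioned and total", {
  aln <- list(OGb = c(gA = "MKV-", gB = "MKVL"),
              OGa = c(gA = "ACDEFG", gB = "ACD--G"))
  sm <- concatenate_supermatrix(aln)
  expect_equal(sm$partitions$og_id, c("OGa", "OGb"))
  expect_equal(sm$partitions$start, c(1L, 7L))
  expect_equal(sm$partitions$end, c(6L, 10L))
  expect_equal(sm$sequences[["gA"]], "ACDEFGMKV-")
  expect_equal(nchar(sm$sequences[["gB"]]), 10L)
  # single OG passes through; shuffled input gives identical output
  one <- concatenate_supermatrix(aln["OGa"])
  expect_equal(one$sequences[["gB"]], "ACD--G")
  expect_identical(concatenate_supermatrix(rev(aln)), sm)
  # missing genome violates the single-copy precondition
  expect_error(concatenate_supermatrix(
    list(OGa = c(gA = "MK"), OGb = c(gA = "MK", gB = "MK"))),
    "genome set")
})

test_that("marker mapping uses membership first, then best-hit fallback", {
  set.seed(41)
  ref_in <- rand_seq(120, alphabet = AA20)
  fam2 <- rand_seq(150, alphabet = AA20)
  gs <- toy_genome_set(list(
    g1 = c(p_ppcA = ref_in, q1 = fam2),
    g2 = c(r1 = ref_in, r2 = fam2)))
  og <- data.frame(og_id = c("OG_7", "OG_7", "OG_3", "OG_3"),
                   genome_id = c("g1", "g2", "g1", "g2"),
                   protein_id = c("p_ppcA", "r1", "q1", "r2"),
                   stringsAsFactors = FALSE)
  markers <- data.frame(
    marker_id = c("ppcA", "cymA", "lost"),
    reference_protein_id = c("p_ppcA", "REF_cymA", "REF_lost"),
    source_model = "G. sulfurreducens PCA",
    category = c("periplasmic", "other", "other"),
    stringsAsFactors = FALSE)
  refs <- c(REF_cymA = fam2, REF_lost = rand_seq(200, alphabet = AA20))
  mm <- suppressMessages(
    map_markers_to_ogs(markers, og, gs, reference_sequences = refs))
  expect_equal(unname(mm["ppcA"]), "OG_7")   # membership rule
  expect_equal(unname(mm["cymA"]), "OG_3")   # best-hit fallback
  expect_true(is.na(mm["lost"]))             # below thresholds -> unmapped
})

test_that("copy-number matrix counts orthogroup membership per genome", {
  og <- data.frame(og_id = c("OG1", "OG1", "OG1", "OG2"),
                   genome_id = c("gA", "gA", "gB", "gB"),
                   protein_id = paste0("p", 1:4), stringsAsFactors = FALSE)
  mm <- c(ppcA = "OG1", cymA = "OG2")
  mat <- presence_matrix(og, mm, c("gA", "gB", "gC"))
  expect_equal(mat["gA", "ppcA"], 2L)
  expect_equal(mat["gB", "ppcA"], 1L)
  expect_equal(mat["gC", "ppcA"], 0L)
  expect_equal(mat["gA", "cymA"], 0L)
  expect_true(all(mat >= 0))
  # row sums invariant under genome reordering; boolean view is copy >= 1
  mat2 <- presence_matrix(og, mm, c("gC", "gB", "gA"))
  expect_equal(rowSums(mat)[c("gA", "gB", "gC")],
               rowSums(mat2)[c("gA", "gB", "gC")])
  expect_identical(mat >= 1, mat > 0)
})

test_that("prevalence and mean copies use whole-family denominators", {
  mat <- matrix(c(1L, 2L, 0L, 1L, 5L, 6L, 5L, 4L), ncol = 2,
                dimnames = list(paste0("g", 1:4), c("mkA", "mkB")))
  fam <- stats::setNames(rep("F", 4), paste0("g", 1:4))
  pv <- marker_prevalence_and_copies(mat, fam)
  expect_equal(pv$prevalence_pct[pv$marker == "mkA"], 75)
  expect_equal(pv$mean_copies[pv$marker == "mkB"], 5)
  mat[, "mkB"] <- 0L
  pv <- marker_prevalence_and_copies(mat, fam)
  expect_equal(pv$prevalence_pct[pv$marker == "mkB"], 0)
  expect_equal(pv$mean_copies[pv$marker == "mkB"], 0)
})

test_that("RBH inference handles degenerate two-genome cases", {
  s <- rand_seq(100, alphabet = AA20)
  gs <- toy_genome_set(list(g1 = c(a1 = s), g2 = c(b1 = s)))
  og <- infer_orthogroups_rbh(gs)
  expect_equal(nrow(og), 2L)
  expect_equal(length(unique(og$og_id)), 1L)

  set.seed(43)
  gs2 <- toy_genome_set(list(g1 = c(a1 = rand_seq(100, alphabet = AA20)),
                             g2 = c(b1 = rand_seq(100, alphabet = AA20))))
  expect_equal(nrow(infer_orthogroups_rbh(gs2)), 0L)
})

test_that("RBH inference recovers planted single-copy gene families", {
  old <- set_log_level("error")
  on.exit(set_log_level(old))
  cfg <- synth_config(seed = 2L, n_families = 3L, genomes_per_family = 2L,
                      n_gene_families = 10L, single_copy_fraction = 1,
                      genome_length_mean_mbp = 0.02,
                      orphans_per_genome = 1L)
  st <- generate_study(cfg, file.path(tempdir(), "rbh-single"))
  gids <- names(st$truth$genome_length_bp)
  gs <- load_genome_set(
    stats::setNames(file.path(st$paths$proteome_dir, paste0(gids, ".faa")),
                    gids), st$paths$metadata)
  og <- infer_orthogroups_rbh(gs)
  truth <- st$truth$true_og
  truth <- truth[truth != "orphan"]
  inferred <- stats::setNames(og$og_id, og$protein_id)
  expect_setequal(names(inferred), names(truth))
  # identical partitions: each planted family is exactly one inferred OG
  cross <- table(truth[names(truth)], inferred[names(truth)])
  expect_true(all(rowSums(cross > 0) == 1))
  expect_true(all(colSums(cross > 0) == 1))
})

test_that("assignment stats count orphans as unassigned", {
  st <- study_fixture()
  gs <- study_genome_set()
  og <- suppressMessages(parse_orthogroups(st$paths$orthogroups))
  stats <- og_assignment_stats(og, gs)
  truth_orphans <- sum(st$truth$true_og == "orphan")
  expect_equal(stats$total - stats$assigned, truth_orphans)
  expect_equal(stats$assigned_fraction, stats$assigned / stats$total)
})
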