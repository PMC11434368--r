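test_that("QC boundaries are strict", {
  checkm <- data.frame(
    genome_id = paste0("g", 1:4),
    completeness = c(98.0, 99.5, 99.5, 99.9),
    contamination = c(1.0, 4.99, 5.0, 0.1), stringsAsFactors = FALSE)
  qc <- qc_filter(checkm)
  expect_setequal(qc$kept, c("g2", "g4"))
  expect_setequal(qc$dropped$genome_id, c("g1", "g3"))
  expect_match(qc$dropped$reason[qc$dropped$genome_id == "g1"],
               "completeness")
  expect_match(qc$dropped$reason[qc$dropped$genome_id == "g3"],
               "contamination")
  expect_error(qc_filter(data.frame(genome_id = "g", completeness = NA,
                                    contamination = 1)), "missing")
})

test_that("QC equals a brute-force row scan on random tables", {
  set.seed(79)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    checkm <- data.frame(
      genome_id = paste0("g", 1:n),
      completeness = round(runif(n, 95, 100), 2),
      contamination = round(runif(n, 0, 8), 2), stringsAsFactors = FALSE)
    qc <- qc_filter(checkm)
    brute <- checkm$genome_id[checkm$completeness > 98 &
                                checkm$contamination < 5]
    expect_equal(qc$kept, brute)
  }
})

test_that("genome length counts N, GC excludes it from the denominator", {
  p <- write_tmp_fasta(c(">c1", "GGCC"))
  r <- read_genome_stats <- genome_size_gc(p)
  expect_equal(r$gc_fraction, 1.0)
  p <- write_tmp_fasta(c(">c1", "ATAT"))
  expect_equal(genome_size_gc(p)$gc_fraction, 0.0)
  p <- write_tmp_fasta(c(">c1", "ATGCN"))
  r <- suppressMessages(genome_size_gc(p))
  expect_equal(r$length_bp, 5L)
  expect_equal(r$gc_fraction, 0.5)
  # multiple contigs pool
  p <- write_tmp_fasta(c(">c1", "GG", ">c2", "AT"))
  expect_equal(genome_size_gc(p)$gc_fraction, 0.5)
  p <- write_tmp_fasta(c(">c1", "NNN"))
  expect_error(suppressMessages(genome_size_gc(p)), "GC undefined")
})

feature_inputs <- function() {
  gs <- toy_genome_set(
    list(g1 = c(g1_a = strrep("CAACHAA", 8), g1_b = "MKVL"),
         g2 = c(g2_a = "MKVL")),
    families = c("F1", "F2"))
  gs$genome_info <- data.frame(genome_id = c("g1", "g2"),
                               genome_length_bp = c(4e6, 2e6),
                               gc_fraction = c(0.61, 0.55))
  mat <- matrix(c(2L, 1L, 0L, 3L, 5L, 0L, 1L, 0L, 2L, 2L), nrow = 2,
                dimnames = list(c("g1", "g2"),
                                c("ppcA", "cbcA", "cbcB", "cymA", "ribB")))
  markers <- data.frame(
    marker_id = c("ppcA", "cbcA", "cbcB", "cymA", "ribB"),
    reference_protein_id = paste0("REF_", c("ppcA", "cbcA", "cbcB",
                                            "cymA", "ribB")),
    source_model = "G. sulfurreducens PCA",
    category = c("periplasmic", "cytochrome bc complex",
                 "cytochrome bc complex", "other",
                 "riboflavin biosynthesis"), stringsAsFactors = FALSE)
  ann <- annotate_proteome(gs)
  profiles <- suppressMessages(build_mobilome_profiles(gs))
  list(gs = gs, mat = mat, markers = markers, ann = ann,
       profiles = profiles)
}

test_that("feature assembly sums categories and normalizes cytochromes", {
  fi <- feature_inputs()
  ft <- assemble_feature_table(fi$gs, fi$mat, fi$markers, fi$ann,
                               fi$profiles)
  expect_equal(names(ft), c("genome_id", FEATURE_COLUMNS))
  g1 <- ft[ft$genome_id == "g1", ]
  expect_equal(g1$cbc_copies_sum, 0L + 5L)
  expect_equal(g1$rib_copies_sum, 2L)
  expect_equal(g1$ppcA_copies, 2)
  expect_equal(g1$cymA_copies, 1)
  expect_equal(g1$ompJ_copies, 0)  # marker absent from the matrix
  # 1 motif-bearing protein in a 4-Mbp genome
  expect_equal(g1$total_cyt_per_mbp, 1 / 4)
  expect_equal(g1$gc_percent, 61)
  expect_false(anyNA(ft))
  # a genome missing from a source is an error naming it
  expect_error(assemble_feature_table(
    fi$gs, fi$mat, fi$markers, fi$ann, fi$profiles[1, , drop = FALSE]),
    "g2")
})

test_that("total_cyt arithmetic: 56 heme proteins in 4 Mbp is 14 per Mbp", {
  seqs <- stats::setNames(rep("CAACHAA", 56), sprintf("g1_h%02d", 1:56))
  gs <- toy_genome_set(list(g1 = seqs, g2 = c(g2_a = "MKVL")),
                       families = c("F1", "F2"))
  gs$genome_info <- data.frame(genome_id = c("g1", "g2"),
                               genome_length_bp = c(4e6, 2e6),
                               gc_fraction = c(0.6, 0.6))
  mat <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "ppcA"))
  markers <- data.frame(marker_id = "ppcA",
                        reference_protein_id = "REF_ppcA",
                        source_model = "G. sulfurreducens PCA",
                        category = "periplasmic", stringsAsFactors = FALSE)
  ft <- assemble_feature_table(gs, mat, markers, annotate_proteome(gs),
                               suppressMessages(
                                 build_mobilome_profiles(gs)))
  expect_equal(ft$total_cyt_per_mbp[ft$genome_id == "g1"], 14)
})

test_that("PCA variance accounting and reconstruction are exact", {
  set.seed(83)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- paste0("v", 1:6)
  res <- run_pca(X)
  expect_equal(sum(res$variance_explained), 100, tolerance = 1e-12)
  expect_true(all(diff(res$variance_explained) <= 1e-12))
  # full reconstruction of the standardized matrix
  Xs <- scale(X)
  recon <- res$scores %*% t(res$loadings)
  expect_lt(max(abs(recon - Xs)), 1e-8)
  # score vectors orthogonal
  G <- crossprod(res$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("two perfectly correlated variables load entirely on PC1", {
  set.seed(89)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x + 3)
  res <- run_pca(X)
  expect_equal(res$variance_explained[1], 100, tolerance = 1e-9)
})

test_that("row permutation permutes scores and leaves loadings alone", {
  set.seed(97)
  X <- matrix(rnorm(25 * 5), 25, 5,
              dimnames = list(paste0("g", 1:25), paste0("v", 1:5)))
  res <- run_pca(X)
  perm <- sample(25)
  res_p <- run_pca(X[perm, ])
  expect_equal(res_p$loadings, res$loadings)
  expect_equal(res_p$variance_explained, res$variance_explained)
  expect_equal(res_p$scores, res$scores[perm, ])
})

test_that("PCA guards degenerate inputs", {
  X <- matrix(rnorm(4), 2, 2)
  expect_error(run_pca(X), "at least 3")
  X2 <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  expect_message(res <- run_pca(X2), "constant")
  expect_equal(rownames(res$loadings), c("a", "c"))
})

test_that("a planted two-factor structure is recovered by PC1+PC2", {
  lt <- generate_latent_feature_table(n_genomes = 40, n_factors = 2,
                                      noise_sd = 0.05, seed = 12)
  res <- run_pca(lt$table)
  # compare subspaces in the standardized variable space
  X <- as.matrix(lt$table[, -1])
  D <- diag(1 / apply(X, 2, sd))
  span_true <- qr.Q(qr(D %*% lt$loadings_true))
  span_pca <- qr.Q(qr(res$loadings[, 1:2]))
  angles <- acos(pmin(1, svd(crossprod(span_true, span_pca))$d))
  expect_lt(max(angles) * 180 / pi, 5)
  expect_gt(sum(res$variance_explained[1:2]), 80)
})
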