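test_that("common-total normalization scales columns as expected", {
  m <- matrix(c(6e5, 4e5, 1.2e6, 8e5), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  nm <- normalize_to_common_total(m, target_total = "mean")  # mean = 1.5e6
  expect_equal(nm$target_total, 1.5e6)
  expect_equal(nm$values[, "a"], m[, "a"] * 1.5)
  expect_equal(nm$values[, "b"], m[, "b"] * 0.75)

  same <- matrix(c(10, 20, 15, 15), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(normalize_to_common_total(same, "mean")$values, same)

  zero <- m; zero[, "b"] <- 0
  expect_error(normalize_to_common_total(zero), "b")
})

test_that("normalized columns all sum to the target within 1e-9", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(rpois(60, lambda = sample(50:500, 1)), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    nm <- normalize_to_common_total(m, sample(c("mean", 1e6), 1)[[1]])
    expect_true(all(abs(colSums(nm$values) / nm$target_total - 1) < 1e-9))
  }
})

test_that("guide log2 fold change follows the pseudocount convention", {
  expect_equal(sgrna_log2fc(99, 24), -2)
  expect_equal(sgrna_log2fc(57.3, 57.3), 0)
  expect_equal(sgrna_log2fc(0, 0), 0)
  expect_equal(sgrna_log2fc(99, 24, pseudo_numerator_only = TRUE),
               log2(25 / 99))
  expect_error(sgrna_log2fc(-1, 5), "non-negative")
  expect_error(sgrna_log2fc(1, 5, pseudocount = 0), "pseudocount")
  expect_error(sgrna_log2fc(0, 5, pseudo_numerator_only = TRUE), "initial")
})

test_that("gene ES is the mean of its guides' fold changes", {
  lib <- tiny_library()
  lfc <- c(g1 = -2, g2 = -1, g3 = 0.7, g4 = 0.1, g5 = -3)
  es <- gene_es(lfc, lib)
  expect_equal(es$es[es$gene == "GENEA"], -1.5)
  expect_equal(es$es[es$gene == "GENEB"], 0.7)  # mean of one
  expect_equal(es$es[es$gene == NON_TARGETING_SENTINEL], 0.1)
  expect_identical(es$n_guides[es$gene == "GENEA"], 2L)
  expect_error(gene_es(c(nope = 1), lib), "absent from library")
})

make_es_table <- function(es_matrix, category = NULL) {
  genes <- rownames(es_matrix)
  if (is.null(category)) category <- rep("targeting", length(genes))
  structure(list(es = es_matrix,
                 gene_info = data.frame(gene = genes, category = category,
                                        n_guides = 6L)),
            class = "es_table")
}

test_that("biased ES follows the group-difference convention and ranks descending", {
  m <- rbind(
    HIT  = c(A1 = -2.0, A2 = -1.0, B1 = -0.1, B2 = 0.1, B3 = -0.3, B4 = 0.3),
    FLAT = c(-2, -2, -2, -2, -2, -2),
    NULL1 = c(0.1, -0.1, 0, 0, 0.05, -0.05)
  )
  et <- make_es_table(m)
  bias <- biased_es(et, group_a = c("A1", "A2"))
  expect_equal(bias$biased_es[bias$gene == "HIT"], 0 - (-1.5))
  expect_equal(bias$biased_es[bias$gene == "FLAT"], 0)
  expect_identical(bias$gene[1], "HIT")
  expect_identical(sort(bias$rank), seq_len(nrow(bias)))
  expect_error(biased_es(et, group_a = c("A1", "A2"), group_b = c("A2", "B1")),
               "overlap")
  expect_error(biased_es(et, group_a = c("A1", "NOPE")), "absent")
})

test_that("swapping the groups negates the biased ES exactly", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rnorm(8 * 6), nrow = 8,
                dimnames = list(sprintf("G%02d", 1:8), paste0("L", 1:6)))
    et <- make_es_table(m)
    ga <- paste0("L", 1:2); gb <- paste0("L", 3:6)
    ab <- biased_es(et, ga, gb)
    ba <- biased_es(et, gb, ga)
    ba <- ba[match(ab$gene, ba$gene), ]
    expect_identical(ab$biased_es, -ba$biased_es)
  }
})

test_that("controls are excluded from the ranking by default", {
  m <- rbind(GENEX = c(A = -2, B = 0),
             NON_TARGETING = c(A = 0, B = 0),
             PCNA = c(A = -3, B = -3))
  et <- make_es_table(m, category = c("targeting", "non_targeting",
                                      "positive_control"))
  bias <- biased_es(et, group_a = "A")
  expect_identical(bias$gene, "GENEX")
  all_in <- biased_es(et, group_a = "A", exclude_controls = FALSE)
  expect_identical(nrow(all_in), 3L)
})

test_that("scaling one sample's raw counts leaves every ES unchanged", {
  cfg <- small_screen_config()
  sim <- simulate_screen(cfg, seed = 13)
  es1 <- compute_es_table(sim$counts, sim$sheet, sim$library)
  scaled <- sim$counts$counts
  scaled[, 3] <- scaled[, 3] * 7L
  es2 <- compute_es_table(count_matrix(scaled), sim$sheet, sim$library,
                          target_total = 1e6)
  es1b <- compute_es_table(sim$counts, sim$sheet, sim$library,
                           target_total = 1e6)
  expect_equal(es2$es, es1b$es, tolerance = 1e-9)
})

test_that("heatmap export is rank-ordered with lexicographic tie breaking", {
  m <- rbind(BBB = c(A = -1, B = 0), AAA = c(A = -1, B = 0),
             CCC = c(A = 0, B = 0))
  et <- make_es_table(m)
  bias <- biased_es(et, group_a = "A")
  # AAA and BBB tie at biased_es = 1; AAA must rank first
  expect_identical(bias$gene[1:2], c("AAA", "BBB"))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_es_heatmap_table(et, bias, path)
  tab <- utils::read.delim(path)
  expect_identical(tab$gene, c("AAA", "BBB", "CCC"))
  expect_identical(tab$rank, 1:3)
  expect_true(all(diff(tab$biased_es) <= 0))
})

test_that("ES table TSV round trip preserves values and gene annotations", {
  cfg <- small_screen_config()
  sim <- simulate_screen(cfg, seed = 2)
  es <- compute_es_table(sim$counts, sim$sheet, sim$library)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_es_table(es, path)
  back <- read_es_table(path)
  expect_equal(back$es, es$es, tolerance = 1e-6)
  expect_identical(back$gene_info$category, es$gene_info$category)
})
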