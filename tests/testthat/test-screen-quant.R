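ANCHOR <- "GACGAAACACCG"

test_that("sample sheet validation catches duplicates and bad fields", {
  base <- data.frame(sample_id = c("s1", "s2"), cell_line = "L1",
                     timepoint = c("initial", "final"),
                     barcode = c("ACGT", "TGCA"), stagger_len = 0:1)
  expect_s3_class(sample_sheet(base), "sample_sheet")
  dup_id <- base; dup_id$sample_id <- "s1"
  expect_error(sample_sheet(dup_id), "duplicate sample_id")
  dup_bc <- base; dup_bc$barcode <- "ACGT"; dup_bc$stagger_len <- 0L
  expect_error(sample_sheet(dup_bc), "barcode, stagger")
  bad_tp <- base; bad_tp$timepoint[1] <- "middle"
  expect_error(sample_sheet(bad_tp), "timepoint")
  bad_st <- base; bad_st$stagger_len[1] <- -1L
  expect_error(sample_sheet(bad_st), "stagger_len")
})

test_that("samples whose stagger+barcode patterns can claim the same read are rejected", {
  # barcode TTACGT at offset 0 and ACGT at offset 2 fix identical bases from
  # position 3 on, so some read satisfies both
  sheet <- data.frame(sample_id = c("s1", "s2"), cell_line = "L1",
                      timepoint = c("initial", "final"),
                      barcode = c("TTACGT", "ACGT"), stagger_len = c(0L, 2L))
  expect_error(demultiplex("ACGT", sheet, ANCHOR), "claim the same read")
  # distinct patterns at the same offset are fine
  ok <- sheet; ok$barcode <- c("ACGT", "TGCA"); ok$stagger_len <- c(0L, 0L)
  expect_silent(demultiplex(character(), ok, ANCHOR))
})

test_that("demultiplexing assigns by exact barcode at the stagger offset", {
  lib <- tiny_library()
  sheet <- tiny_sheet()  # ACGT@0, TGCA@2
  reads <- c(
    paste0("ACGT", ANCHOR, lib$records$protospacer[1], "GTTT"),
    paste0("TT", "TGCA", ANCHOR, lib$records$protospacer[2], "GTTT"),
    paste0("GGGG", ANCHOR, lib$records$protospacer[1], "GTTT")  # unknown barcode
  )
  dm <- demultiplex(reads, sheet, ANCHOR)
  expect_identical(lengths(dm$streams), c(L1_initial = 1L, L1_final = 1L))
  expect_identical(dm$orphans, 1L)
  # trimmed streams start at the anchor
  expect_true(startsWith(dm$streams$L1_initial, ANCHOR))
  expect_identical(sum(lengths(dm$streams)) + dm$orphans, length(reads))
})

test_that("counting tolerates no mismatch and books everything else as unassigned", {
  lib <- tiny_library()
  ps <- lib$records$protospacer[1]
  mutated <- paste0("T", substring(ps, 2))
  streams <- list(s1 = c(rep(paste0(ANCHOR, ps, "GTTT"), 10),
                         paste0(ANCHOR, mutated, "GTTT")))
  cm <- count_guides(streams, lib, ANCHOR)
  expect_identical(cm$counts["g1", "s1"], 10L)
  expect_identical(sum(cm$counts[, "s1"]), 10L)
  expect_identical(cm$unassigned[["s1"]], 1L)

  empty <- count_guides(list(s1 = character()), lib, ANCHOR)
  expect_true(all(empty$counts == 0L))
  expect_identical(empty$unassigned[["s1"]], 0L)
})

test_that("counting equals the brute-force oracle and conserves reads", {
  set.seed(11)
  cfg <- small_screen_config(error_rate = 0.01)
  dir <- withr::local_tempdir()
  sim <- simulate_screen(cfg, seed = 11, output = "fastq", dir = dir)
  reads <- unlist(lapply(sim$fastq[1:2], read_fastq), use.names = FALSE)
  reads <- reads[seq_len(min(1000L, length(reads)))]
  dm <- demultiplex(reads, sim$sheet, cfg$anchor)
  cm <- count_guides(dm$streams, sim$library, cfg$anchor)
  # conservation per sample
  expect_identical(unname(colSums(cm$counts) + cm$unassigned),
                   unname(as.numeric(lengths(dm$streams))))
  expect_identical(sum(lengths(dm$streams)) + dm$orphans, length(reads))
  for (s in names(dm$streams)) {
    oracle <- brute_count_reads(dm$streams[[s]], sim$library$records$protospacer,
                                sim$library$records$guide_id, cfg$anchor)
    expect_identical(cm$counts[, s], oracle$counts)
    expect_identical(cm$unassigned[[s]], oracle$unassigned)
  }
})

test_that("counting a permuted read stream yields the identical matrix", {
  cfg <- small_screen_config()
  dir <- withr::local_tempdir()
  sim <- simulate_screen(cfg, seed = 3, output = "fastq", dir = dir)
  reads <- read_fastq(sim$fastq[[1]])
  sheet1 <- sim$sheet[1, , drop = FALSE]
  q1 <- quantify_screen(reads, sheet1, sim$library, cfg$anchor)
  set.seed(99)
  q2 <- quantify_screen(sample(reads), sheet1, sim$library, cfg$anchor)
  expect_identical(q1$counts$counts, q2$counts$counts)
  expect_identical(q1$counts$unassigned, q2$counts$unassigned)
})

test_that("error-free simulator reads reproduce the simulated counts exactly", {
  cfg <- small_screen_config()
  dir <- withr::local_tempdir()
  sim <- simulate_screen(cfg, seed = 21, output = "fastq", dir = dir)
  reads <- unlist(lapply(sim$fastq, read_fastq), use.names = FALSE)
  q <- quantify_screen(reads, sim$sheet, sim$library, cfg$anchor)
  expect_identical(q$counts$counts, sim$counts$counts)
  expect_identical(q$orphans, 0L)
  expect_true(all(q$counts$unassigned == 0L))
})

test_that("representation QC computes fold representation and flags shortfalls", {
  lib <- tiny_library()  # 5 guides
  m <- matrix(c(2000L, 2000L, 2000L, 2000L, 2000L,
                100L, 100L, 100L, 100L, 100L,
                0L, 0L, 0L, 0L, 0L),
              nrow = 5,
              dimnames = list(lib$records$guide_id, c("deep", "shallow", "dead")))
  qc <- representation_qc(count_matrix(m), lib, threshold = 1000)
  expect_equal(qc$fold_representation, c(2000, 100, 0))
  expect_identical(qc$flagged, c(FALSE, TRUE, TRUE))
  expect_equal(qc$zero_fraction[qc$sample_id == "dead"], 1.0)
})

test_that("count matrix TSV round trip preserves counts and unassigned", {
  cfg <- small_screen_config()
  sim <- simulate_screen(cfg, seed = 8)
  sim$counts$unassigned[] <- seq_len(ncol(sim$counts$counts))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(sim$counts, path)
  back <- read_count_matrix(path)
  expect_identical(back$counts, sim$counts$counts)
  expect_identical(as.integer(back$unassigned), as.integer(sim$counts$unassigned))
})
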