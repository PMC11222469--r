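iv <- function(chrom, start, end) list(chrom = chrom, start = start, end = end)

test_that("interval overlap uses half-open semantics", {
  expect_true(intervals_overlap(iv("chr1", 100, 200), iv("chr1", 150, 250)))
  expect_false(intervals_overlap(iv("chr1", 100, 200), iv("chr1", 200, 300)))
  expect_false(intervals_overlap(iv("chr1", 100, 200), iv("chr2", 100, 200)))
  expect_error(intervals_overlap(iv("chr1", 200, 100), iv("chr1", 0, 1)))
})

test_that("loop sets enforce anchor invariants", {
  ok <- data.frame(chrom1 = "chr1", start1 = 100, end1 = 200,
                   chrom2 = "chr1", start2 = 900, end2 = 1000)
  expect_s3_class(loop_set(ok), "loop_set")
  trans <- ok; trans$chrom2 <- "chr2"
  expect_error(loop_set(trans), "share a chromosome")
  swapped <- ok; swapped$start1 <- 950; swapped$end1 <- 1050
  expect_error(loop_set(swapped), "left anchor")
  dup <- rbind(ok, ok)
  expect_error(loop_set(dup), "duplicate")
})

test_that("classification requires both anchors to match the same reference loop", {
  ref <- loop_set(data.frame(
    chrom1 = c("chr1", "chr1"), start1 = c(1000, 50000),
    end1 = c(2000, 51000), chrom2 = c("chr1", "chr1"),
    start2 = c(20000, 90000), end2 = c(21000, 91000),
    name = c("R1", "R2")))
  test <- loop_set(data.frame(
    chrom1 = c("chr1", "chr1", "chr2"),
    start1 = c(1000, 1500, 1000), end1 = c(2000, 2500, 2000),
    chrom2 = c("chr1", "chr1", "chr2"),
    start2 = c(20000, 90200, 20000), end2 = c(21000, 91200, 21000),
    name = c("identical", "straddler", "other_chrom")))
  cls <- classify_loops(test, ref)
  lab <- setNames(cls$test$label, cls$test$name)
  expect_identical(lab[["identical"]], "shared")
  # left anchor overlaps R1's left, right anchor overlaps only R2's right
  expect_identical(lab[["straddler"]], "gained")
  expect_identical(lab[["other_chrom"]], "gained")
  expect_identical(unname(cls$counts[c("shared", "gained")]), c(1L, 2L))
  expect_identical(cls$counts[["shared"]] + cls$counts[["gained"]], nrow(test))
  expect_identical(cls$control_only$name, "R2")
})

test_that("classification matches the brute-force double loop on random sets", {
  set.seed(41)
  for (i in 1:4) {
    test <- loop_set(random_loop_df(120))
    ref <- loop_set(random_loop_df(100))
    cls <- classify_loops(test, ref)
    oracle <- brute_classify_loops(test, ref)
    expect_identical(cls$test$label, oracle$labels)
    expect_identical(nrow(cls$control_only), sum(!oracle$ref_matched))
    expect_identical(sum(cls$counts[c("shared", "gained")]), nrow(test))
  }
})

test_that("classification is invariant to loop order", {
  set.seed(42)
  test <- loop_set(random_loop_df(80))
  ref <- loop_set(random_loop_df(60))
  cls1 <- classify_loops(test, ref)
  perm <- sample(nrow(test))
  cls2 <- classify_loops(loop_set(test[perm, ]), loop_set(ref[sample(nrow(ref)), ]))
  lab1 <- setNames(cls1$test$label, cls1$test$name)
  lab2 <- setNames(cls2$test$label, cls2$test$name)
  expect_identical(lab1[names(lab2)], lab2)
  expect_identical(cls1$counts, cls2$counts)
})

test_that("simulated planted loop classes are recovered exactly", {
  sim <- simulate_loops(n_shared = 150, n_gained = 80, n_control_only = 40,
                        seed = 19)
  cls <- classify_loops(sim$test, sim$reference)
  lab <- setNames(cls$test$label, cls$test$name)
  expect_identical(lab[names(sim$truth$test_labels)],
                   sim$truth$test_labels)
  expect_identical(unname(cls$counts[c("shared", "gained")]), c(150L, 80L))
  none_gained <- simulate_loops(n_shared = 50, n_gained = 0,
                                n_control_only = 10, seed = 19)
  cls0 <- classify_loops(none_gained$test, none_gained$reference)
  expect_identical(cls0$counts[["gained"]], 0L)
})

test_that("loop lengths are midpoint distances with standard order statistics", {
  mk <- function(starts2) loop_set(data.frame(
    chrom1 = "chr1", start1 = 0, end1 = 100,
    chrom2 = "chr1", start2 = starts2, end2 = starts2 + 100))
  st <- loop_length_stats(mk(c(100000, 225000, 400000)))
  expect_equal(st$median, 225000)
  expect_equal(st$n, 3L)
  one <- loop_set(data.frame(chrom1 = "chr1", start1 = 100, end1 = 200,
                             chrom2 = "chr1", start2 = 900, end2 = 1000))
  expect_equal(loop_length_stats(one)$median, 800)  # 950 - 150
  expect_equal(loop_length_stats(one, method = "start")$median, 800)
  even <- loop_length_stats(mk(c(100, 300)))
  expect_equal(even$median, 200)
  expect_error(loop_length_stats(one[0, ]), "empty")
})

test_that("peak venn matches all-pairs brute force and handles edge sets", {
  a <- interval_set(data.frame(chrom = "chr1", start = c(0, 20), end = c(10, 30)))
  b <- interval_set(data.frame(chrom = "chr1", start = c(5, 100), end = c(8, 110)))
  v <- peak_set_venn(a, b)
  expect_identical(v$a_with_overlap, 1L)
  expect_identical(v$a_only, 1L)
  expect_identical(v$b_with_overlap, 1L)
  expect_identical(v$b_only, 1L)
  same <- peak_set_venn(a, a)
  expect_identical(same$a_only, 0L)
  expect_identical(same$b_only, 0L)
  dis <- peak_set_venn(a, interval_set(data.frame(chrom = "chr9",
                                                  start = 0, end = 10)))
  expect_identical(dis$a_with_overlap, 0L)
  set.seed(51)
  for (i in 1:4) {
    ra <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                     start = floor(runif(60, 0, 5e4)))
    ra$end <- ra$start + floor(runif(60, 100, 2000))
    rb <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                     start = floor(runif(50, 0, 5e4)))
    rb$end <- rb$start + floor(runif(50, 100, 2000))
    v <- peak_set_venn(interval_set(ra), interval_set(rb))
    expect_identical(v$a_with_overlap, brute_peak_venn(ra, rb))
    expect_identical(v$b_with_overlap, brute_peak_venn(rb, ra))
  }
})

test_that("BED I/O keeps coordinates verbatim and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "chr1\t0\t100\tp1", "chr2\t500\t900\tp2"), path)
  peaks <- read_bed(path)
  expect_identical(nrow(peaks), 2L)
  expect_identical(peaks$start, c(0, 500))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, out)
  expect_identical(readLines(out), c("chr1\t0\t100\tp1", "chr2\t500\t900\tp2"))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\tfoo\t200"), bad)
  expect_error(read_bed(bad), "line 2")
  short <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t5"), short)
  expect_error(read_bed(short), "line 2")
})

test_that("BEDPE I/O round-trips byte-wise and rejects trans anchors", {
  sim <- simulate_loops(n_shared = 600, n_gained = 400, n_control_only = 0,
                        seed = 29)
  p1 <- withr::local_tempfile(fileext = ".bedpe")
  p2 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(sim$test, p1)
  back <- read_bedpe(p1, name = "test")
  expect_identical(nrow(back), 1000L)
  expect_identical(back$start1, sim$test$start1)
  expect_identical(back$start2, sim$test$start2)
  write_bedpe(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  trans <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t0\t100\tchr2\t500\t600", trans)
  expect_error(read_bedpe(trans), "share a chromosome")
})
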