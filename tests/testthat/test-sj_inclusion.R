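test_that("split-read counts give the published inclusion bounds", {
  est <- pseudoexon_inclusion(5, 12, 993)
  expect_equal(round(est$low, 1), 0.5)
  expect_equal(round(est$high, 1), 1.2)
  expect_true(est$detected)

  # no inclusion junctions at all: undetected, (0, 0)
  none <- pseudoexon_inclusion(0, 0, 993)
  expect_false(none$detected)
  expect_equal(c(none$low, none$high), c(0, 0))

  all_in <- pseudoexon_inclusion(10, 10, 0)
  expect_equal(c(all_in$low, all_in$high), c(100, 100))

  expect_error(pseudoexon_inclusion(-1, 0, 10), "non-negative")
})

test_that("the estimator is scale-invariant and symmetric in the flanks", {
  set.seed(51)
  for (rep in 1:30) {
    j5 <- sample(0:50, 1); j3 <- sample(0:50, 1); js <- sample(0:2000, 1)
    a <- pseudoexon_inclusion(j5, j3, js)
    k <- sample(2:7, 1)
    b <- pseudoexon_inclusion(k * j5, k * j3, k * js)
    expect_equal(c(a$low, a$high), c(b$low, b$high))
    sw <- pseudoexon_inclusion(j3, j5, js)
    expect_equal(c(a$low, a$high), c(sw$low, sw$high))
    expect_lte(a$low, a$high)
  }
  # PSI-style alternative collapses to a single value
  psi <- pseudoexon_inclusion(5, 12, 993, estimator = "psi")
  expect_equal(psi$low, psi$high)
  expect_equal(psi$low, 100 * 8.5 / (993 + 8.5))
})

test_that("SJ files parse with filters and precise error reporting", {
  path <- withr::local_tempfile(fileext = ".tab")
  lines <- c("chr1\t94533627\t94539999\t2\t2\t0\t5\t0\t73",
             "chr1\t94530151\t94533499\t2\t2\t0\t12\t0\t60",
             "chr1\t94530151\t94539999\t2\t2\t1\t993\t0\t90",
             "chr1\t94540200\t94540300\t2\t2\t0\t0\t5\t20")
  writeLines(lines, path)
  recs <- read_sj_file(path, min_unique = 1)
  expect_equal(nrow(recs), 3L)
  expect_equal(attr(recs, "dropped")[["min_unique"]], 1L)
  expect_true(993 %in% recs$n_unique)

  # empty file
  empty <- withr::local_tempfile(fileext = ".tab")
  writeLines(character(0), empty)
  expect_equal(nrow(read_sj_file(empty)), 0L)

  # malformed lines name their line number
  bad <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(lines[1], "chr1\t100\t200\t2"), bad)
  expect_error(read_sj_file(bad), "line 2")
  bad2 <- withr::local_tempfile(fileext = ".tab")
  writeLines("chr1\t100\t200\t2\t2\t0\tx\t0\t10", bad2)
  expect_error(read_sj_file(bad2), "non-integer")
})

test_that("pseudoexon junctions are located by exact boundary matching", {
  g <- fixture_sj_geometry()
  # the three junctions of the region at the published counts
  recs <- data.frame(
    chrom = "chr1",
    intron_start = c(g$pe$end + 1L, g$exon_3p$end + 1L, g$exon_3p$end + 1L),
    intron_end = c(g$exon_5p$start - 1L, g$pe$start - 1L,
                   g$exon_5p$start - 1L),
    strand = 2L, motif = 2L, annotated = c(0L, 0L, 1L),
    n_unique = c(5L, 12L, 993L), n_multi = 0L,
    max_overhang = c(73L, 60L, 90L), stringsAsFactors = FALSE)
  cnt <- locate_pseudoexon_junctions(recs, g$pe, g$exon_5p, g$exon_3p)
  expect_equal(unname(cnt), c(5L, 12L, 993L))
  est <- pseudoexon_inclusion(cnt[["j_in_5"]], cnt[["j_in_3"]],
                              cnt[["j_skip"]])
  expect_equal(round(c(est$low, est$high), 1), c(0.5, 1.2))

  # shuffled record order gives the same counts
  cnt2 <- locate_pseudoexon_junctions(recs[c(3, 1, 2), ], g$pe,
                                      g$exon_5p, g$exon_3p)
  expect_equal(cnt, cnt2)

  # a file without pseudoexon junctions yields zeros but keeps the skip
  skip_only <- recs[recs$annotated == 1L, , drop = FALSE]
  cnt3 <- locate_pseudoexon_junctions(skip_only, g$pe, g$exon_5p, g$exon_3p)
  expect_equal(unname(cnt3), c(0L, 0L, 993L))

  # overlapping spans are refused
  expect_error(
    locate_pseudoexon_junctions(recs, g$pe, g$pe, g$exon_3p),
    "overlap")
})

test_that("simulated SJ counts recover the true inclusion rate", {
  mids <- vapply(1:40, function(s) {
    sim <- simulate_sj_counts(1000, 0.01, seed = s, capture = 1)
    est <- pseudoexon_inclusion(sim$counts[["j_in_5"]],
                                sim$counts[["j_in_3"]],
                                sim$counts[["j_skip"]])
    (est$low + est$high) / 2
  }, 1)
  se <- 100 * sqrt(0.01 * 0.99 / 1000) / sqrt(40)
  expect_lt(abs(mean(mids) - 1), 3 * se)
  # degenerate rates behave as stated
  expect_equal(unname(simulate_sj_counts(500, 0, seed = 1)$counts[1:2]),
               c(0L, 0L))
  expect_equal(simulate_sj_counts(500, 1, seed = 1)$counts[["j_skip"]], 0L)
})

test_that("SJ round trip: simulate, write, read, locate", {
  g <- fixture_sj_geometry()
  path <- withr::local_tempfile(fileext = ".tab")
  sim <- simulate_sj_counts(2000, 0.02, seed = 7, path = path)
  recs <- read_sj_file(path)
  cnt <- locate_pseudoexon_junctions(recs, g$pe, g$exon_5p, g$exon_3p)
  expect_equal(cnt[["j_skip"]], sim$counts[["j_skip"]])
  expect_equal(cnt[["j_in_5"]], sim$counts[["j_in_5"]])
  expect_equal(cnt[["j_in_3"]], sim$counts[["j_in_3"]])
})
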