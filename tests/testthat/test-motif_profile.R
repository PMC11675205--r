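test_that("hexamer counting includes overlaps and matches brute force", {
  expect_equal(count_hexamers("AAAAAAA", hexamer_set("ESE", "AAAAAA")), 2L)
  expect_equal(count_hexamers("ACGTACGTAC", hexamer_set("ESE",
                                                        character(0))), 0L)
  expect_warning(res <- count_hexamers("ACGT", hexamer_set("ESE", "AAAAAA")),
                 "shorter")
  expect_equal(res, 0L)

  sets <- default_hexamer_sets()
  set.seed(31)
  seq <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  brute <- 0L
  for (s in 1:95) {
    if (substr(seq, s, s + 5L) %in% sets$ese$kmers) brute <- brute + 1L
  }
  expect_equal(count_hexamers(seq, sets$ese), brute)
})

test_that("the ESE/ESS ratio handles zero denominators without errors", {
  ese <- hexamer_set("ESE", c("GAAGAA", "AAGAAG"))
  ess <- hexamer_set("ESS", "TAGGGT")
  r <- ese_ess_ratio("GAAGAAGAATAGGGT", ese, ess)
  expect_equal(r$ese_count, 3L)
  expect_equal(r$ess_count, 1L)
  expect_equal(r$ratio, 3)
  expect_true(r$defined)
  r0 <- ese_ess_ratio("CCCCCCCC", ese, ess)
  expect_false(r0$defined)
  expect_true(is.na(r0$ratio))
  rInf <- ese_ess_ratio("GAAGAACC", ese, ess)
  expect_false(rInf$defined)
  expect_equal(rInf$ratio, Inf)
})

test_that("a substitution creating one enhancer hexamer gives ESE delta +1", {
  ese <- hexamer_set("ESE", "GAAGAA")
  ess <- hexamer_set("ESS", character(0))
  # motif-free reference; T>A at position 9 completes GAAGAA
  ref <- "CCCCGAAGTACCCC"
  prof <- variant_motif_delta(ref, data.frame(pos = 9L, ref = "T",
                                              alt = "A"),
                              ese = ese, ess = ess)
  expect_equal(prof$ese$delta, 1L)
  expect_equal(prof$ess$delta, 0L)
})

test_that("deltas equal a brute-force rescan and stay local", {
  fx <- get_fixture()
  sets <- default_hexamer_sets()
  prof <- variant_motif_delta(fx$insert_seq, fx$variants,
                              construct = fx$construct)
  # oracle: apply both substitutions by hand and recount over the windows
  chars <- strsplit(fx$insert_seq, "")[[1]]
  pos <- vapply(fx$variants, construct_position, 1L,
                construct = fx$construct)
  for (k in seq_along(pos)) chars[pos[k]] <- fx$variants[[k]]$alt
  mut <- paste(chars, collapse = "")
  for (lab in c("ese", "ess")) {
    set <- sets[[if (lab == "ese") "ese" else "ess"]]
    cnt <- function(s) sum(substring(s, prof$windows,
                                     prof$windows + 5L) %in% set$kmers)
    expect_equal(prof[[lab]]$reference, cnt(fx$insert_seq))
    expect_equal(prof[[lab]]$variant, cnt(mut))
  }
  # every inspected window overlaps a variant base (no action at a distance)
  expect_true(all(vapply(prof$windows, function(s)
    any(pos >= s & pos <= s + 5L), TRUE)))
})

test_that("applying a variant and reverting it yields a zero profile", {
  fx <- get_fixture()
  v <- fx$variants[[1]]
  chars <- strsplit(fx$insert_seq, "")[[1]]
  p <- construct_position(v, fx$construct)
  chars[p] <- v$alt
  mutated <- paste(chars, collapse = "")
  back <- variant_motif_delta(mutated, data.frame(pos = p, ref = v$alt,
                                                  alt = v$ref))
  fwd <- variant_motif_delta(fx$insert_seq, data.frame(pos = p, ref = v$ref,
                                                       alt = v$alt))
  expect_equal(back$ese$delta, -fwd$ese$delta)
  expect_equal(back$ess$delta, -fwd$ess$delta)
  # revert on top of the forward application: no change at all
  roundtrip <- variant_motif_delta(fx$insert_seq,
                                   data.frame(pos = c(p, p),
                                              ref = c(v$ref, v$alt),
                                              alt = c(v$alt, v$ref)))
  expect_equal(roundtrip$ese$delta, 0L)
  expect_equal(roundtrip$ess$delta, 0L)
})

test_that("joint complex-allele application equals sequential application", {
  fx <- get_fixture()
  sets <- default_hexamer_sets()
  joint <- variant_motif_delta(fx$insert_seq, fx$variants,
                               construct = fx$construct)
  # the two variants are 98 bp apart: windows cannot interact
  chars <- strsplit(fx$insert_seq, "")[[1]]
  p1 <- construct_position(fx$variants[[1]], fx$construct)
  chars[p1] <- fx$variants[[1]]$alt
  step1 <- paste(chars, collapse = "")
  s2 <- variant_motif_delta(step1, list(fx$variants[[2]]),
                            construct = fx$construct)
  s1 <- variant_motif_delta(fx$insert_seq, list(fx$variants[[1]]),
                            construct = fx$construct)
  expect_equal(joint$ese$delta, s1$ese$delta + s2$ese$delta)
  expect_equal(joint$ess$delta, s1$ess$delta + s2$ess$delta)
})

test_that("reference-base mismatches are caught by name", {
  fx <- get_fixture()
  bad <- data.frame(pos = 10L, ref = "A", alt = "G")
  chars <- strsplit(fx$insert_seq, "")[[1]]
  if (chars[10] == "A") bad$ref <- "C"
  expect_error(variant_motif_delta(fx$insert_seq, bad),
               "reference base mismatch at position 10")
})

test_that("motif-matrix hits are compared hit-by-hit around variants", {
  w <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  w["G", ] <- 1
  mm <- motif_matrix("polyG", w, threshold = 4)
  prof <- variant_motif_delta("AAAAGAGGAAAA",
                              data.frame(pos = 6L, ref = "A", alt = "G"),
                              ese = hexamer_set("ESE", character(0)),
                              ess = hexamer_set("ESS", character(0)),
                              matrices = list(mm))
  expect_equal(prof$matrices[[1]]$delta, 1L)
  expect_equal(prof$matrices[[1]]$gained, 5L)
  expect_error(motif_matrix("bad", w, threshold = 9), "outside attainable")
})
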