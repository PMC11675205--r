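test_that("GC content matches the published oligo characteristics", {
  expect_equal(gc_percent("ACAAGCTGCAGTAGCAGCAGG"), 57.1)  # AON1, 21 nt
  expect_equal(gc_percent("ACCAGGAAGCAGAGTTCACC"), 55.0)   # AON2, 20 nt
  expect_equal(gc_percent("ATAT"), 0)
  expect_error(gc_percent("ACGU"), "ACGT")
  expect_error(gc_percent(""), "non-empty")
})

test_that("GC content is invariant under reverse complement", {
  set.seed(61)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_percent(s), gc_percent(rc))
  }
})

test_that("melting temperatures follow each model's definition", {
  expect_equal(as.numeric(melting_temperature("ACGT", "wallace")), 12)
  s <- "ACCAGGAAGCAGAGTTCACC"
  gc_n <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_equal(as.numeric(melting_temperature(s, "basic_gc")),
               64.9 + 41 * (gc_n - 16.4) / nchar(s))
  expect_error(melting_temperature("ACGT", "salt_adjusted"))
})

test_that("nearest-neighbour Tm matches independent reference values", {
  # frozen oracle values from an independent implementation of the unified
  # nearest-neighbour model (50 mM Na+, 25 nM per strand)
  cases <- list(c("ACAAGCTGCAGTAGCAGCAGG", 57.3909),
                c("ACCAGGAAGCAGAGTTCACC", 53.7289),
                c("ACGTACGTACGTACGTAC", 48.3105))
  for (cs in cases) {
    tm <- as.numeric(melting_temperature(cs[1], "nearest_neighbor"))
    expect_equal(tm, as.numeric(cs[2]), tolerance = 1e-4)
  }
})

test_that("binding verdicts require exact antisense complementarity", {
  fx <- get_fixture()
  off <- insert_offset(fx$construct)
  vpos <- off + construct_position(fx$variants[[1]], fx$construct)
  start <- vpos - 10L                       # 21-nt window centred on variant
  window <- substr(fx$premrna_seq, start, start + 20L)
  aon_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window)))
  aon <- aon_candidate("AON1-like", aon_seq, target_start = start,
                       chemistry = "2'-MOE-PTO")
  res <- check_binding(aon, fx$premrna_seq, registry = fx$registry,
                       variants = fx$variants, construct = fx$construct)
  expect_true(res$complementary)
  expect_true(any(grepl("covers c.1555-5882", res$annotations,
                        fixed = TRUE)))

  # the same sequence sense-strand (not complemented) does not bind
  sense <- aon_candidate("sense", window, target_start = start)
  expect_false(check_binding(sense, fx$premrna_seq)$complementary)

  # an AON over the pe11b cryptic donor edge is annotated as such
  donor_pos <- off + construct_position(parse_cnomen("c.1555-5750"),
                                        fx$construct)
  dstart <- donor_pos - 9L
  dwin <- substr(fx$premrna_seq, dstart, dstart + 19L)
  aon2 <- aon_candidate("AON2-like", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(dwin))),
    target_start = dstart)
  res2 <- check_binding(aon2, fx$premrna_seq, registry = fx$registry,
                        construct = fx$construct)
  expect_true(res2$complementary)
  expect_true(any(grepl("covers donor c.1555-5750", res2$annotations,
                        fixed = TRUE)))

  expect_error(check_binding(aon, "ACGT", target_start = 1),
               "extends beyond")
})

test_that("binding is a round trip for any window", {
  fx <- get_fixture()
  set.seed(62)
  for (rep in 1:20) {
    len <- sample(18:25, 1)
    start <- sample(seq_len(nchar(fx$premrna_seq) - len), 1)
    win <- substr(fx$premrna_seq, start, start + len - 1L)
    aon <- aon_candidate("x", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(win))), target_start = start)
    expect_true(check_binding(aon, fx$premrna_seq)$complementary)
  }
})

test_that("guideline flags encode the design ranges", {
  r1 <- aon_report(aon_candidate("AON1", "ACAAGCTGCAGTAGCAGCAGG"))
  expect_equal(unname(r1$flags), c("pass", "pass"))
  expect_equal(r1$length, 21L)
  expect_equal(r1$gc, 57.1)
  short <- aon_report(aon_candidate("short", "ACGTACGTAC"))
  expect_equal(short$flags[["length"]], "warn")
  gc_rich <- aon_report(aon_candidate("gc", "GCGCGCGCGCGCGCGCGCAT"))
  expect_equal(gc_rich$flags[["gc"]], "warn")
})

test_that("AON candidates load from FASTA", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">AON1", "ACAAGCTGCAGTAGCAGCAGG",
               ">AON2", "ACCAGGAAGCAGAGTTCACC"), path)
  aons <- read_aon_fasta(path)
  expect_length(aons, 2L)
  expect_equal(aons[[1]]$id, "AON1")
  expect_equal(gc_percent(aons[[2]]$seq), 55.0)
})
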