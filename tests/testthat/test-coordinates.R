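test_that("c. positions parse, including complex alleles and errors", {
  p <- parse_cnomen("c.1555-5882C>A")
  expect_equal(p$anchor, 1555L)
  expect_equal(p$offset, -5882L)
  expect_equal(p$ref, "C")
  expect_equal(p$alt, "A")

  q <- parse_cnomen("c.1554+1G>T")
  expect_equal(q$anchor, 1554L)
  expect_equal(q$offset, 1L)

  cx <- parse_cnomen("c.[1555-5882C>A;1555-5784C>G]")
  expect_length(cx, 2L)
  expect_equal(cx[[1]]$offset, -5882L)
  expect_equal(cx[[2]]$offset, -5784L)
  # the two positions of the complex allele are 98 bp apart
  expect_equal(cnomen_distance(cx[[1]], cx[[2]]), 98L)

  # transcript accession prefix is tolerated
  expect_equal(parse_cnomen("NM_000350.2:c.1555-5882C>A")$offset, -5882L)

  expect_error(parse_cnomen("c.15x5-3C>A"), "offending token")
  expect_error(parse_cnomen("g.12345C>A"), "c\\.")
})

test_that("interval lengths are inclusive and validated", {
  expect_equal(interval_length(genomic_interval("chr1", 94531516, 94538459,
                                                "-")), 6944L)
  expect_equal(interval_length(genomic_interval("chr1", 100, 100)), 1L)
  expect_error(genomic_interval("chr1", 101, 100), "start")
  # pseudoexon 11b span from its cryptic acceptor and donor
  expect_equal(cnomen_span_length(parse_cnomen("c.1555-5923"),
                                  parse_cnomen("c.1555-5750")), 174L)
})

test_that("c. to genomic conversion on the minus strand", {
  am <- anchor_map(parse_cnomen("c.1555-2643"), 94531516, "-", 14372)
  expect_equal(cnomen_to_genomic(parse_cnomen("c.1555-5882"), am), 94534755)
  expect_equal(cnomen_to_genomic(parse_cnomen("c.1555-2643"), am), 94531516)
  # pe11b edges fall inside the region around the complex allele
  acc <- cnomen_to_genomic(parse_cnomen("c.1555-5923"), am)
  don <- cnomen_to_genomic(parse_cnomen("c.1555-5750"), am)
  expect_equal(acc, 94534796)
  expect_equal(don, 94534623)
  expect_true(all(c(acc, don) >= 94534595 & c(acc, don) <= 94534839))
  expect_error(cnomen_to_genomic(parse_cnomen("c.999-5882"), am),
               "outside the mapped intron")
})

test_that("genomic round trips are identities and strictly monotone", {
  am <- anchor_map(parse_cnomen("c.1555-2643"), 94531516, "-", 14372)
  set.seed(11)
  offs <- sample(1:14372, 200)
  gs <- integer(0)
  for (i in offs) {
    p <- if (i <= 7186) cnomen(1554, i) else cnomen(1555, i - 14373L)
    g <- cnomen_to_genomic(p, am)
    back <- genomic_to_cnomen(g, am)
    expect_identical(c(back$anchor, back$offset), c(p$anchor, p$offset))
    gs <- c(gs, g)
  }
  # transcript direction = increasing intron index = decreasing genomic
  ord <- order(offs)
  expect_true(all(diff(gs[ord]) < 0))
})

test_that("construct positions map the insert span and round-trip", {
  fx <- get_fixture()
  expect_equal(construct_position(parse_cnomen("c.1554+4787"),
                                  fx$construct), 1L)
  expect_equal(construct_position(parse_cnomen("c.1555-2643"),
                                  fx$construct), 6944L)
  expect_equal(construct_position(parse_cnomen("c.1555-5923"),
                                  fx$construct), 3664L)
  expect_error(construct_position(parse_cnomen("c.1554+100"), fx$construct),
               "outside the insert span")
  set.seed(12)
  for (pos in sample(1:6944, 100)) {
    p <- construct_to_cnomen(pos, fx$construct)
    expect_equal(construct_position(p, fx$construct), pos)
  }
})

test_that("transcript lengths reproduce the catalog table", {
  fx <- get_fixture()
  lens <- vapply(fx$catalog$models, transcript_length, 1L)
  expect_equal(unname(lens), c(119L, 246L, 293L, 420L))
  expect_equal(backbone_length(fx$construct), 119L)
  # backbone-only transcript is just the backbone
  t1 <- transcript_model("bb", fx$construct, list())
  expect_equal(transcript_length(t1), 119L)
})

test_that("amplicon lengths are inclusive and respect absent segments", {
  fx <- get_fixture()
  t1 <- fx$catalog$models[["T1"]]
  expect_equal(predicted_amplicon_length(t1, 1, 119), 119L)
  expect_equal(predicted_amplicon_length(t1, 10, 100), 91L)
  expect_error(predicted_amplicon_length(t1, 100, 10), "fwd_start")
  expect_error(predicted_amplicon_length(t1, 1, 500), "outside")
  # forward primer inside pe11b has no product on T1
  pe11b_pos <- insert_offset(fx$construct) +
    construct_position(parse_cnomen("c.1555-5900"), fx$construct)
  res <- predicted_amplicon_length(t1, pe11b_pos,
                                   premrna_length(fx$construct),
                                   coords = "premrna")
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "no product")
  # same primer pair yields a product on T3, which carries pe11b
  t3 <- fx$catalog$models[["T3"]]
  expect_false(is.na(predicted_amplicon_length(t3, pe11b_pos,
                                               premrna_length(fx$construct),
                                               coords = "premrna")))
})

test_that("construct configs round-trip through YAML", {
  fx <- get_fixture()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_construct(fx$construct, path)
  c2 <- load_construct(path)
  expect_equal(c2$insert_length, 6944L)
  expect_equal(backbone_length(c2), 119L)
  expect_equal(construct_position(parse_cnomen("c.1555-5923"), c2), 3664L)
})
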