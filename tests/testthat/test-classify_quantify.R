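test_that("raw junctions snap to registry sites within the window", {
  tiny <- tiny_construct()
  reg <- build_registry(tiny)   # donor 50, acceptor 6051
  aln <- data.frame(qname = "r1", flag = 0L, rname = "tiny", pos = 1L,
                    mapq = 60L, cigar = "50M5999N70M",
                    stringsAsFactors = FALSE)  # acceptor lands at 6050
  ch <- correct_chains(extract_junction_chains(aln), reg,
                       correction_policy(10))
  expect_equal(ch$junctions$donor_c, 50L)
  expect_equal(ch$junctions$acceptor_c, 6051L)
  expect_equal(ch$junctions$shift_acceptor, 1L)
  expect_true(ch$reads$correctable)
})

test_that("endpoints beyond the window make the whole chain uncorrectable", {
  tiny <- tiny_construct()
  reg <- build_registry(tiny)
  aln <- data.frame(qname = "r1", flag = 0L, rname = "tiny", pos = 1L,
                    mapq = 60L, cigar = "35M6016N69M",
                    stringsAsFactors = FALSE)  # donor at 35, 15 bp off
  ch <- correct_chains(extract_junction_chains(aln), reg,
                       correction_policy(10))
  expect_true(is.na(ch$junctions$donor_c))
  expect_false(ch$reads$correctable)
})

test_that("correction is idempotent", {
  fx <- get_fixture()
  sc <- sim_scenario(fx, mt_props, n = 300)
  sim <- simulate_alignments(sc, seed = 17)
  ch <- extract_junction_chains(sim$alignments)
  once <- correct_chains(ch, fx$registry, correction_policy(10),
                         fx$catalog)
  # feed the corrected coordinates back through correction
  ch2 <- once
  keep <- !is.na(once$junctions$donor_c)
  ch2$junctions$donor[keep] <- once$junctions$donor_c[keep]
  keep <- !is.na(once$junctions$acceptor_c)
  ch2$junctions$acceptor[keep] <- once$junctions$acceptor_c[keep]
  twice <- correct_chains(ch2, fx$registry, correction_policy(10),
                          fx$catalog)
  expect_equal(twice$junctions$donor_c, once$junctions$donor_c)
  expect_equal(twice$junctions$acceptor_c, once$junctions$acceptor_c)
})

test_that("chains classify by exact equality against the catalog", {
  fx <- get_fixture()
  sc <- sim_scenario(fx, c(T1 = 0.4, T2 = 0.2, T3 = 0.2, T4 = 0.1),
                     n = 400)
  sim <- simulate_alignments(sc, seed = 19)
  ch <- qc_filter(extract_junction_chains(sim$alignments), fx$construct)
  ch <- correct_chains(ch, fx$registry, correction_policy(10), fx$catalog)
  cl <- classify_chains(ch, fx$catalog)
  truth <- sim$truth$label[match(cl$qname, sim$truth$qname)]
  expect_true(all(cl$label == truth))
  expect_true(all(c("T1", "T2", "T3", "T4", "other") %in% cl$label))
})

test_that("jittered chains within the window are fully recovered", {
  fx <- get_fixture()
  noise <- noise_model(jitter_sd = 2, jitter_max = 8, sub_rate = 0,
                       ins_rate = 0, del_rate = 0, trunc_prob = 0)
  sc <- sim_scenario(fx, c(T1 = 0.5, T3 = 0.5), n = 500, noise = noise)
  sim <- simulate_alignments(sc, seed = 23)
  ch <- qc_filter(extract_junction_chains(sim$alignments), fx$construct)
  ch <- correct_chains(ch, fx$registry, correction_policy(10), fx$catalog)
  cl <- classify_chains(ch, fx$catalog)
  truth <- sim$truth$label[match(cl$qname, sim$truth$qname)]
  expect_gte(mean(cl$label == truth), 0.999)
})

test_that("quantification conserves reads and keeps 'other' in the denominator", {
  fx <- get_fixture()
  labels <- c(rep("T1", 98), "T2", "other")
  qt <- quantify(labels, fx$catalog)
  expect_equal(qt$abundance[qt$transcript_id == "T1"], 98)
  expect_equal(qt$abundance[qt$transcript_id == "T2"], 1)
  expect_equal(qt$abundance[qt$transcript_id == "other"], 1)
  expect_equal(sum(qt$count), length(labels))
  expect_equal(sum(qt$abundance), 100)
  expect_error(quantify(character(0), fx$catalog), "no QC-passing reads")
  expect_error(quantify(c("T1", "T9"), fx$catalog), "outside the catalog")
})

test_that("condition comparison reproduces the published delta arithmetic", {
  wt <- quant_table(c("T1", "T2", "T3", "T4"),
                    c(98.69, 0.74, 0.05, 0))
  mt <- quant_table(c("T1", "T2", "T3", "T4"),
                    c(54.15, 0.04, 44.64, 0.41))
  cmp <- compare_quant(wt, mt)
  expect_equal(cmp$delta[cmp$transcript_id == "T3"], 44.59)
  expect_equal(cmp$delta[cmp$transcript_id == "T1"], -44.54)
  # identical tables give zero deltas; swapping arguments negates
  expect_true(all(compare_quant(wt, wt)$delta == 0))
  expect_equal(compare_quant(mt, wt)$delta, -cmp$delta)
  other <- quant_table(c("X1", "X2"), c(50, 50))
  expect_error(compare_quant(wt, other), "different catalogs")
})

test_that("grouped abundances sum transcripts by event tag", {
  fx <- get_fixture()
  mt <- quantify(c(rep("T1", 5415), rep("T2", 4), rep("T3", 4464),
                   rep("T4", 41), rep("other", 76)), fx$catalog)
  expect_equal(group_abundance(mt, fx$catalog, "pe11b"), 45.05)
  expect_equal(group_abundance(mt, fx$catalog, "WT"), 54.15)
  # all tags together cover every transcript; T4 carries two tags, so it is
  # counted twice and subtracted once; the remainder is everything but "other"
  all_tags <- group_abundance(mt, fx$catalog, "WT") +
    group_abundance(mt, fx$catalog, "pe11a") +
    group_abundance(mt, fx$catalog, "pe11b")
  t4 <- mt$abundance[mt$transcript_id == "T4"]
  expect_equal(all_tags - t4,
               100 - mt$abundance[mt$transcript_id == "other"])
  expect_error(group_abundance(mt, fx$catalog, "pe99"), "unknown event tag")
})

test_that("quant tables round-trip through TSV", {
  wt <- quant_table(c("T1", "T2"), c(99.5, 0.5), c(199, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(wt, path)
  back <- read_quant_table(path)
  expect_equal(back$abundance, wt$abundance)
  expect_equal(back$count, wt$count)
})
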