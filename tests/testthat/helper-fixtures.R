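# Shared fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fx_cache$fx)) .fx_cache$fx <- build_fixture_construct()
  .fx_cache$fx
}

# variant-minigene (MT) per-transcript proportions; remainder 0.76% "other"
mt_props <- c(T1 = 0.5415, T2 = 0.0004, T3 = 0.4464, T4 = 0.0041)

# a minimal two-exon construct whose annotated sites sit at 50 and 6051
tiny_construct <- function() {
  minigene_construct(
    name = "tiny",
    backbone_exons = data.frame(name = c("ex1", "ex2"),
                                length = c(50L, 69L)),
    insert_interval = genomic_interval("chrT", 1001, 7000, "+"),
    insert_span = list(parse_cnomen("c.100+10"),
                       parse_cnomen("c.100+6009")),
    intron_length = 12000L,
    insert_after = 1L)
}

# independent junction oracle: expand the CIGAR base by base and take
# maximal runs of gap operations from the run-length encoding
oracle_junctions <- function(pos, cigar, min_skip, promote_deletion_ge) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  letters <- rep(ops, lens)
  ref_consuming <- letters %in% c("M", "D", "N", "=", "X")
  refpos <- rep(NA_integer_, length(letters))
  refpos[ref_consuming] <- pos + seq_len(sum(ref_consuming)) - 1L
  r <- rle(letters)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  donors <- integer(0); acceptors <- integer(0)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    thr <- if (v == "N") min_skip else if (v == "D") promote_deletion_ge
           else NA_integer_
    if (!is.na(thr) && r$lengths[k] >= thr) {
      donors <- c(donors, refpos[starts[k]] - 1L)
      acceptors <- c(acceptors, refpos[ends[k]] + 1L)
    }
  }
  list(donor = donors, acceptor = acceptors)
}

# random CIGAR generator: alternates match blocks with gap/indel/clip ops
random_cigar <- function() {
  n_blocks <- sample(1:5, 1)
  parts <- character(0)
  if (stats::runif(1) < 0.3) parts <- c(parts, paste0(sample(1:20, 1), "S"))
  for (b in seq_len(n_blocks)) {
    parts <- c(parts, paste0(sample(5:80, 1), "M"))
    if (b < n_blocks) {
      op <- sample(c("N", "D", "I"), 1)
      len <- if (op == "I") sample(1:10, 1) else sample(1:120, 1)
      parts <- c(parts, paste0(len, op))
    }
  }
  if (stats::runif(1) < 0.3) parts <- c(parts, paste0(sample(1:20, 1), "S"))
  paste(parts, collapse = "")
}
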