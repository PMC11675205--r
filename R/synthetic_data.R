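# Synthetic data: an assay-scale minigene fixture construct, multi-isoform
# amplicon reads with nanopore-like noise (FASTQ / pre-aligned SAM), and
# short-read splice-junction count files. Everything is seeded and
# reproducible; no external downloads are needed anywhere in the package.

#' Nanopore-like noise model for simulated amplicon reads
#'
#' @param jitter_sd Standard deviation (bp) of the discretised normal jitter
#'   applied independently to each junction edge.
#' @param jitter_max Hard clip for the jitter (bp); kept below the default
#'   correction window so that recovery bounds are provable.
#' @param sub_rate,ins_rate,del_rate Per-base substitution / insertion /
#'   deletion rates.
#' @param trunc_prob Probability that a read is truncated at each end.
#' @param trunc_mean Mean truncation length (geometric distribution, bp).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(jitter_sd = 2, jitter_max = 8L, sub_rate = 0.03,
                        ins_rate = 0.01, del_rate = 0.01,
                        trunc_prob = 0.02, trunc_mean = 30) {
  rates <- c(sub_rate, ins_rate, del_rate, trunc_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(jitter_sd >= 0, jitter_max >= 0)
  structure(list(jitter_sd = jitter_sd, jitter_max = as.integer(jitter_max),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, trunc_prob = trunc_prob,
                 trunc_mean = trunc_mean),
            class = "noise_model")
}

#' Zero-noise model (exact reads, exact junctions)
#' @return A `noise_model` with all rates and jitter set to zero.
#' @export
no_noise <- function() {
  noise_model(jitter_sd = 0, jitter_max = 0, sub_rate = 0, ins_rate = 0,
              del_rate = 0, trunc_prob = 0)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant <- function(chars, start, motif) {
  m <- strsplit(motif, "")[[1]]
  chars[start:(start + length(m) - 1L)] <- m
  chars
}

#' Build the bundled minigene fixture
#'
#' Constructs a synthetic replica of a minigene carrying 6944 bp of ABCA4
#' intron 11 (chr1:94531516-94538459 on hg19, minus strand; insert span
#' c.1554+4787..c.1555-2643) between two backbone exons of 60 + 59 bp, with
#' two pseudoexons: pe11a (c.1554+6710..c.1554+6836, 127 bp) and pe11b
#' (c.1555-5923..c.1555-5750, 174 bp). The transcript catalog holds T1
#' (backbone only, 119 bp), T2 (+pe11a, 246 bp), T3 (+pe11b, 293 bp) and T4
#' (both pseudoexons, 420 bp). The pre-mRNA sequence is seeded-random DNA
#' with consensus donor/acceptor motifs planted at every splice-site edge
#' and the reference bases of the two deep-intronic variants
#' (c.1555-5882C, c.1555-5784C) planted inside pe11b; it is a synthetic
#' stand-in, not the real genomic sequence.
#'
#' @param seed Seed for the sequence generator.
#' @return List with elements `construct` (`minigene_construct`),
#'   `catalog` (`transcript_catalog`), `registry` (`site_registry`),
#'   `premrna_seq`, `insert_seq`, and `variants` (the complex-allele
#'   `cnomen` pair).
#' @export
build_fixture_construct <- function(seed = 42L) {
  construct <- minigene_construct(
    name = "ABCA4_int11_minigene",
    backbone_exons = data.frame(name = c("RHO_ex3", "RHO_ex5"),
                                length = c(60L, 59L)),
    insert_interval = genomic_interval("chr1", 94531516, 94538459, "-"),
    insert_span = list(parse_cnomen("c.1554+4787"),
                       parse_cnomen("c.1555-2643")),
    intron_length = 14372L,
    insert_after = 1L)

  pe11a <- list(name = "pe11a",
                span = list(parse_cnomen("c.1554+6710"),
                            parse_cnomen("c.1554+6836")))
  pe11b <- list(name = "pe11b",
                span = list(parse_cnomen("c.1555-5923"),
                            parse_cnomen("c.1555-5750")))
  models <- list(
    transcript_model("T1", construct, list(), effect = "WT"),
    transcript_model("T2", construct, list(pe11a), effect = "out-of-frame"),
    transcript_model("T3", construct, list(pe11b), effect = "in-frame-stop"),
    transcript_model("T4", construct, list(pe11a, pe11b),
                     effect = "out-of-frame"))
  catalog <- transcript_catalog(models, construct)

  # splice-site edges on the pre-mRNA
  off <- insert_offset(construct)
  donors <- c(off,
              off + construct_position(pe11a$span[[2]], construct),
              off + construct_position(pe11b$span[[2]], construct))
  acceptors <- c(off + construct_position(pe11a$span[[1]], construct),
                 off + construct_position(pe11b$span[[1]], construct),
                 off + construct$insert_length + 1L)

  mats <- default_splice_matrices()
  don_cons <- consensus_sequence(mats$donor)        # e.g. CAG|GTAAGT
  acc_cons <- consensus_sequence(mats$acceptor)     # (T)10 C C AG | G A
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  chars <- strsplit(random_dna(premrna_length(construct)), "")[[1]]
  for (d in donors)
    chars <- plant(chars, d - mats$donor$n_exonic + 1L, don_cons)
  for (a in acceptors)
    chars <- plant(chars, a - (mats$acceptor$width - mats$acceptor$n_exonic),
                   acc_cons)
  variants <- parse_cnomen("c.[1555-5882C>A;1555-5784C>G]")
  for (v in variants)
    chars[off + construct_position(v, construct)] <- v$ref
  premrna_seq <- paste(chars, collapse = "")

  user_sites <- data.frame(
    kind = c("donor", "donor", "acceptor", "acceptor"),
    pos = c(donors[2:3], acceptors[1:2]),
    score = c(
      score_site(substr(premrna_seq, donors[2] - 2L, donors[2] + 6L),
                 mats$donor)$transformed,
      score_site(substr(premrna_seq, donors[3] - 2L, donors[3] + 6L),
                 mats$donor)$transformed,
      score_site(substr(premrna_seq, acceptors[1] - 14L, acceptors[1] + 1L),
                 mats$acceptor)$transformed,
      score_site(substr(premrna_seq, acceptors[2] - 14L, acceptors[2] + 1L),
                 mats$acceptor)$transformed))
  registry <- build_registry(construct, user_sites = user_sites)

  list(construct = construct, catalog = catalog, registry = registry,
       premrna_seq = premrna_seq,
       insert_seq = substr(premrna_seq, off + 1L,
                           off + construct$insert_length),
       variants = variants)
}

# save/restore the RNG state so fixture generation is reproducible without
# clobbering the caller's random stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Define a simulation scenario
#'
#' @param fixture A fixture list from [build_fixture_construct()].
#' @param proportions Named numeric vector of true per-transcript
#'   proportions (names from the catalog; sum <= 1). The remainder is
#'   emitted as randomised `"other"` chains using off-registry splice
#'   sites at least 25 bp away from every registry site, so they can never
#'   be snapped into the catalog.
#' @param n Number of reads.
#' @param noise A `noise_model`.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(fixture, proportions, n, noise = noise_model()) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)),
            inherits(noise, "noise_model"))
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (sum(proportions) > 1 + 1e-9) stop("proportions must sum to <= 1")
  unknown <- setdiff(names(proportions), names(fixture$catalog$models))
  if (length(unknown))
    stop("proportions name transcripts outside the catalog: ",
         paste(unknown, collapse = ", "))
  if (n < 1L) stop("n must be >= 1")
  structure(list(fixture = fixture, proportions = proportions,
                 n = as.integer(n), noise = noise),
            class = "sim_scenario")
}

# discretised, clipped normal jitter
rjitter <- function(n, sd, clip) {
  if (sd == 0 || clip == 0L) return(integer(n))
  pmax(pmin(as.integer(round(stats::rnorm(n, 0, sd))), clip), -clip)
}

# sample an "other" chain: a novel internal pseudoexon whose edges are
# >= 25 bp away from every registry site
sample_other_chain <- function(fixture, pe_len = 150L, margin = 25L) {
  construct <- fixture$construct
  off <- insert_offset(construct)
  sites <- fixture$registry$sites$pos
  lo <- off + 200L
  hi <- off + construct$insert_length - 400L
  repeat {
    x <- sample(lo:hi, 1L)
    y <- x + pe_len - 1L
    if (min(abs(sites - x)) >= margin && min(abs(sites - y)) >= margin)
      return(data.frame(donor = c(off, y), acceptor = c(x, off +
        construct$insert_length + 1L)))
  }
}

# spliced segments (ref intervals) implied by a chain over the full pre-mRNA
chain_segments <- function(chain, total_len) {
  starts <- c(1L, chain$acceptor)
  ends <- c(chain$donor, total_len)
  data.frame(start = starts, end = ends)
}

#' Simulate spliced alignments of minigene amplicon reads
#'
#' Draws each read's transcript label from the scenario proportions,
#' applies independent discretised-normal jitter to every junction edge
#' (resampling any jitter that would produce an invalid alignment), inserts
#' short indels at the stated per-base rates, optionally truncates read
#' ends, and encodes the result as SAM-style alignment records against the
#' construct pre-mRNA reference.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `alignments` (`data.frame`: `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `seq`) and `truth` (`data.frame`: `qname`,
#'   `label`).
#' @export
simulate_alignments <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  fx <- scenario$fixture
  construct <- fx$construct
  noise <- scenario$noise
  total <- premrna_length(construct)
  ref_chars <- strsplit(fx$premrna_seq, "")[[1]]
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  p <- scenario$proportions
  labels <- sample(c(names(p), "other"), scenario$n, replace = TRUE,
                   prob = c(p, max(0, 1 - sum(p))))
  chains <- lapply(fx$catalog$chains, identity)

  recs <- vector("list", scenario$n)
  for (i in seq_len(scenario$n)) {
    lab <- labels[i]
    chain <- if (lab == "other") sample_other_chain(fx) else chains[[lab]]
    segs <- chain_segments(chain, total)
    # jitter junction edges, resampling until the alignment stays valid
    if (nrow(chain) > 0L && noise$jitter_sd > 0) {
      for (tries in 1:100) {
        jd <- rjitter(nrow(chain), noise$jitter_sd, noise$jitter_max)
        ja <- rjitter(nrow(chain), noise$jitter_sd, noise$jitter_max)
        s2 <- segs
        s2$end[seq_len(nrow(chain))] <- chain$donor + jd
        s2$start[-1] <- chain$acceptor + ja
        ok <- all(s2$end >= s2$start) && all(diff(s2$start) > 0) &&
          all(s2$start[-1] > s2$end[-nrow(s2)] + 1L) &&
          s2$start[1] >= 1L && s2$end[nrow(s2)] <= total
        if (ok) { segs <- s2; break }
      }
    }
    # 5'/3' truncation along the spliced read
    if (noise$trunc_prob > 0) {
      seg_len <- segs$end - segs$start + 1L
      if (stats::runif(1) < noise$trunc_prob) {
        t5 <- min(1L + stats::rgeom(1, 1 / noise$trunc_mean),
                  sum(seg_len) - 1L)
        while (t5 > 0L && nrow(segs) > 0L) {
          take <- min(t5, segs$end[1] - segs$start[1] + 1L)
          if (take == segs$end[1] - segs$start[1] + 1L && nrow(segs) > 1L) {
            segs <- segs[-1, , drop = FALSE]
          } else {
            segs$start[1] <- segs$start[1] + take
          }
          t5 <- t5 - take
        }
      }
      if (stats::runif(1) < noise$trunc_prob) {
        seg_len <- segs$end - segs$start + 1L
        t3 <- min(1L + stats::rgeom(1, 1 / noise$trunc_mean),
                  sum(seg_len) - 1L)
        while (t3 > 0L && nrow(segs) > 0L) {
          nlast <- nrow(segs)
          take <- min(t3, segs$end[nlast] - segs$start[nlast] + 1L)
          if (take == segs$end[nlast] - segs$start[nlast] + 1L &&
              nlast > 1L) {
            segs <- segs[-nlast, , drop = FALSE]
          } else {
            segs$end[nlast] <- segs$end[nlast] - take
          }
          t3 <- t3 - take
        }
      }
    }
    recs[[i]] <- encode_alignment(segs, ref_chars, noise)
  }
  qnames <- sprintf("read%06d", seq_len(scenario$n))
  aln <- data.frame(qname = qnames,
                    flag = 0L,
                    rname = construct$name,
                    pos = vapply(recs, `[[`, 1L, "pos"),
                    mapq = 60L,
                    cigar = vapply(recs, `[[`, "", "cigar"),
                    seq = vapply(recs, `[[`, "", "seq"),
                    stringsAsFactors = FALSE)
  list(alignments = aln,
       truth = data.frame(qname = qnames, label = labels,
                          stringsAsFactors = FALSE))
}

# turn spliced segments into CIGAR + sequence, adding indels/substitutions
encode_alignment <- function(segs, ref_chars, noise) {
  bases <- c("A", "C", "G", "T")
  ops_len <- integer(0); ops_chr <- character(0); seq_parts <- character(0)
  push <- function(len, op) {
    n <- length(ops_len)
    if (n > 0L && ops_chr[n] == op) {
      ops_len[n] <<- ops_len[n] + len
    } else {
      ops_len[n + 1L] <<- len
      ops_chr[n + 1L] <<- op
    }
  }
  for (k in seq_len(nrow(segs))) {
    s <- segs$start[k]; e <- segs$end[k]
    if (k > 1L) push(s - segs$end[k - 1L] - 1L, "N")
    L <- e - s + 1L
    # at most a few short indels per segment at the stated per-base rates
    n_del <- if (noise$del_rate > 0) stats::rbinom(1L, L, noise$del_rate)
             else 0L
    n_ins <- if (noise$ins_rate > 0) stats::rbinom(1L, L, noise$ins_rate)
             else 0L
    events <- data.frame(off = integer(0), type = character(0))
    if (n_del + n_ins > 0L && L >= 8L) {
      offs <- sort(sample(2:(L - 4L), min(n_del + n_ins, L %/% 6L)))
      if (length(offs)) {
        types <- sample(rep(c("D", "I"), c(n_del, n_ins)))[seq_along(offs)]
        events <- data.frame(off = offs, type = types,
                             stringsAsFactors = FALSE)
      }
    }
    cur <- s
    if (nrow(events)) for (j in seq_len(nrow(events))) {
      at <- s + events$off[j] - 1L
      if (at <= cur) next
      ilen <- sample(1:3, 1L)
      if (events$type[j] == "D") {
        if (at + ilen > e) next
        push(at - cur, "M")
        seq_parts <- c(seq_parts, paste(ref_chars[cur:(at - 1L)],
                                        collapse = ""))
        push(ilen, "D")
        cur <- at + ilen
      } else {
        push(at - cur, "M")
        seq_parts <- c(seq_parts,
                       paste(ref_chars[cur:(at - 1L)], collapse = ""),
                       paste(sample(bases, ilen, TRUE), collapse = ""))
        push(ilen, "I")
        cur <- at
      }
    }
    if (cur <= e) {
      push(e - cur + 1L, "M")
      seq_parts <- c(seq_parts, paste(ref_chars[cur:e], collapse = ""))
    }
  }
  seq <- paste(seq_parts, collapse = "")
  if (noise$sub_rate > 0) {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < noise$sub_rate)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), "")
      seq <- paste(chars, collapse = "")
    }
  }
  list(pos = segs$start[1],
       cigar = paste0(ops_len, ops_chr, collapse = ""),
       seq = seq)
}

#' Write simulated alignments as SAM
#'
#' Emits a valid SAM file (header with the construct as reference) that
#' round-trips through [read_alignments()].
#'
#' @param sim Result of [simulate_alignments()], or its `alignments`
#'   data.frame.
#' @param construct The `minigene_construct` used as reference.
#' @param path Output `.sam` path.
#' @export
write_sam <- function(sim, construct, path) {
  aln <- if (is.data.frame(sim)) sim else sim$alignments
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", construct$name, "\tLN:",
                  premrna_length(construct)))
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                aln$cigar, "*", 0L, 0L, aln$seq,
                strrep("I", nchar(aln$seq)), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate spliced reads as FASTQ with a truth table
#'
#' The read sequences are the spliced transcript sequences of the simulated
#' alignments (noise included); useful for exercising aligner-independent
#' tooling.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Integer seed.
#' @param path Optional FASTQ output path.
#' @return List with `reads` (`data.frame`: `qname`, `label`, `seq`) and,
#'   if `path` is given, the path written.
#' @export
simulate_reads <- function(scenario, seed = 1L, path = NULL) {
  sim <- simulate_alignments(scenario, seed)
  reads <- data.frame(qname = sim$truth$qname, label = sim$truth$label,
                      seq = sim$alignments$seq, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    ss <- Biostrings::DNAStringSet(reads$seq)
    names(ss) <- reads$qname
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = qual)
  }
  list(reads = reads, path = path)
}

#' Synthetic genomic geometry for the short-read pseudoexon check
#'
#' Synthetic stand-in coordinates (minus strand) for a pseudoexon and its
#' two flanking exons, used by [simulate_sj_counts()]; not the real loci.
#'
#' @return List of three `genomic_interval`s: `exon_5p`, `pe`, `exon_3p`.
#' @export
fixture_sj_geometry <- function() {
  list(exon_5p = genomic_interval("chr1", 94540000, 94540100, "-"),
       pe = genomic_interval("chr1", 94533500, 94533626, "-"),
       exon_3p = genomic_interval("chr1", 94530000, 94530150, "-"))
}

#' Simulate a short-read splice-junction count file
#'
#' The number of pseudoexon-including molecules is Binomial(depth,
#' inclusion_rate); each inclusion junction is then captured independently
#' with probability `capture` (split-read thinning), while the remaining
#' molecules support the skipping junction. Junctions with zero counts are
#' omitted from the file, as short-read aligners do.
#'
#' @param depth Total number of molecules spanning the region.
#' @param inclusion_rate True pseudoexon inclusion rate in `[0, 1]`.
#' @param seed Integer seed.
#' @param capture Per-junction capture probability for included molecules.
#' @param read_len Read length used to bound the sampled overhangs.
#' @param geometry Genomic geometry (see [fixture_sj_geometry()]).
#' @param path Optional output path for the 9-column SJ.out.tab file.
#' @return List with `counts` (named vector `j_in_5`, `j_in_3`, `j_skip`),
#'   `records` (`data.frame` of emitted SJ lines) and `path`.
#' @export
simulate_sj_counts <- function(depth, inclusion_rate, seed = 1L,
                               capture = 1, read_len = 100L,
                               geometry = fixture_sj_geometry(),
                               path = NULL) {
  stopifnot(depth > 0, inclusion_rate >= 0, inclusion_rate <= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n_inc <- stats::rbinom(1L, depth, inclusion_rate)
  n_skip <- depth - n_inc
  j5 <- stats::rbinom(1L, n_inc, capture)
  j3 <- stats::rbinom(1L, n_inc, capture)
  g <- geometry
  intr <- function(left, right) c(left$end + 1L, right$start - 1L)
  rows <- list(
    c(intr(g$pe, g$exon_5p), j5, 0L),
    c(intr(g$exon_3p, g$pe), j3, 0L),
    c(intr(g$exon_3p, g$exon_5p), n_skip, 1L))
  recs <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = g$pe$chrom, intron_start = r[1], intron_end = r[2],
               strand = 2L, motif = 2L, annotated = r[4],
               n_unique = r[3], n_multi = 0L,
               max_overhang = sample(seq_len(read_len), 1L),
               stringsAsFactors = FALSE)))
  recs <- recs[recs$n_unique > 0L, , drop = FALSE]
  recs <- recs[order(recs$intron_start, recs$intron_end), , drop = FALSE]
  rownames(recs) <- NULL
  if (!is.null(path))
    utils::write.table(recs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  list(counts = c(j_in_5 = j5, j_in_3 = j3, j_skip = n_skip),
       records = recs, path = path)
}
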