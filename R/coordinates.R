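# Coordinate algebra between HGVS-style c. positions with intronic offsets,
# genomic positions on a stranded reference, and construct-local positions.

#' Create an intronic c. position
#'
#' Represents an HGVS-style cDNA position with an intronic offset, e.g.
#' `c.1555-5882` (5882 bases before the exon starting at coding position 1555)
#' or `c.1554+4787` (4787 bases after the exon ending at coding position 1554).
#' An optional substitution allele (`ref`, `alt`) may be attached.
#'
#' @param anchor Coding-cDNA base number the offset is anchored to (>= 1).
#' @param offset Signed intronic offset; positive after an exon end, negative
#'   before an exon start. Zero means exonic.
#' @param ref,alt Optional reference/alternate nucleotides for a substitution.
#' @return An object of class `cnomen`.
#' @examples
#' cnomen(1555, -5882, "C", "A")
#' @export
cnomen <- function(anchor, offset, ref = NA_character_, alt = NA_character_) {
  anchor <- as.integer(anchor)
  offset <- as.integer(offset)
  stopifnot(length(anchor) == 1L, length(offset) == 1L)
  if (is.na(anchor) || anchor < 1L)
    stop("'anchor' must be a coding position >= 1")
  for (b in c(ref, alt)) {
    if (!is.na(b) && !b %in% c("A", "C", "G", "T"))
      stop("allele bases must be one of A/C/G/T, got '", b, "'")
  }
  structure(list(anchor = anchor, offset = offset,
                 ref = as.character(ref), alt = as.character(alt)),
            class = "cnomen")
}

#' @export
format.cnomen <- function(x, ...) {
  off <- if (x$offset == 0L) "" else sprintf("%+d", x$offset)
  allele <- if (!is.na(x$ref)) paste0(x$ref, ">", x$alt) else ""
  paste0("c.", x$anchor, off, allele)
}

#' @export
print.cnomen <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse an HGVS-like c. position or complex allele
#'
#' Accepts plain intronic positions (`"c.1555-5923"`), substitutions
#' (`"c.1555-5882C>A"`), and complex alleles in square-bracket notation
#' (`"c.[1555-5882C>A;1555-5784C>G]"`). Complex alleles preserve the order of
#' their members. Only substitutions are supported inside complex alleles.
#'
#' @param text Character scalar to parse.
#' @return A `cnomen` object, or a list of `cnomen` for a complex allele.
#' @examples
#' parse_cnomen("c.1555-5882C>A")
#' parse_cnomen("c.[1555-5882C>A;1555-5784C>G]")
#' @export
parse_cnomen <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  # strip optional transcript accession prefix, e.g. "NM_000350.2:c...."
  txt <- sub("^[A-Za-z_0-9.]+:(?=c\\.)", "", txt, perl = TRUE)
  if (!startsWith(txt, "c."))
    stop("cannot parse '", text, "': expected prefix 'c.'")
  body <- substring(txt, 3L)
  if (startsWith(body, "[")) {
    if (!endsWith(body, "]"))
      stop("cannot parse '", text, "': unterminated '[' allele list")
    inner <- substring(body, 2L, nchar(body) - 1L)
    parts <- strsplit(inner, ";", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("complex allele '", text, "' must contain at least two positions")
    return(lapply(parts, parse_cnomen_body, context = text))
  }
  parse_cnomen_body(body, context = text)
}

parse_cnomen_body <- function(body, context = body) {
  m <- regexec("^([0-9]+)([+-][0-9]+)?(?:([ACGT])>([ACGT]))?$", body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L)
    stop("cannot parse c. position: offending token '", body,
         "' in '", context, "'")
  anchor <- as.integer(g[2])
  offset <- if (nzchar(g[3])) as.integer(g[3]) else 0L
  ref <- if (nzchar(g[4])) g[4] else NA_character_
  alt <- if (nzchar(g[5])) g[5] else NA_character_
  cnomen(anchor, offset, ref, alt)
}

#' Create a 1-based inclusive genomic interval
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' interval_length(genomic_interval("chr1", 94531516, 94538459, "-"))
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid interval: start (", start, ") > end (", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Length of a genomic interval in bp
#'
#' @param iv A `genomic_interval`.
#' @return Integer length `end - start + 1`.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1L
}

# Transcript-sense index of an intronic position within its intron:
# position +k (after the upstream exon) has index k; position -k (before the
# downstream exon) has index N - k + 1, where N is the intron length.
intron_index <- function(p, intron_length, donor_anchor, acceptor_anchor) {
  stopifnot(inherits(p, "cnomen"))
  if (p$offset > 0L) {
    if (p$anchor != donor_anchor)
      stop("position ", format(p), " is outside the mapped intron ",
           "(expected '+' anchor c.", donor_anchor, ")")
    i <- p$offset
  } else if (p$offset < 0L) {
    if (p$anchor != acceptor_anchor)
      stop("position ", format(p), " is outside the mapped intron ",
           "(expected '-' anchor c.", acceptor_anchor, ")")
    i <- intron_length + p$offset + 1L
  } else {
    stop("position ", format(p), " is exonic (offset 0), not intronic")
  }
  if (i < 1L || i > intron_length)
    stop("position ", format(p), " lies outside the ", intron_length,
         " bp intron")
  i
}

#' Anchor map between c. positions and genomic coordinates
#'
#' Fixes the correspondence between one intronic c. position and one genomic
#' coordinate on a stranded reference, together with the intron length, which
#' is sufficient to convert any position within the intron. Round-trip
#' conversion through the map is the identity.
#'
#' @param cnomen_anchor A `cnomen` intronic position.
#' @param genomic_anchor 1-based genomic coordinate of that position.
#' @param gene_strand `"+"` or `"-"` (strand the gene is transcribed from).
#' @param intron_length Total length of the intron in bp.
#' @return An object of class `anchor_map`.
#' @examples
#' am <- anchor_map(parse_cnomen("c.1555-2643"), 94531516, "-", 14372)
#' cnomen_to_genomic(parse_cnomen("c.1555-5882"), am)  # 94534755
#' @export
anchor_map <- function(cnomen_anchor, genomic_anchor, gene_strand,
                       intron_length) {
  stopifnot(inherits(cnomen_anchor, "cnomen"))
  if (!gene_strand %in% c("+", "-")) stop("gene_strand must be '+' or '-'")
  intron_length <- as.integer(intron_length)
  stopifnot(intron_length >= 1L)
  if (cnomen_anchor$offset > 0L) {
    donor_anchor <- cnomen_anchor$anchor
    acceptor_anchor <- cnomen_anchor$anchor + 1L
  } else if (cnomen_anchor$offset < 0L) {
    acceptor_anchor <- cnomen_anchor$anchor
    donor_anchor <- cnomen_anchor$anchor - 1L
  } else {
    stop("anchor must be intronic (non-zero offset)")
  }
  map <- structure(list(cnomen_anchor = cnomen_anchor,
                        genomic_anchor = as.integer(genomic_anchor),
                        gene_strand = gene_strand,
                        intron_length = intron_length,
                        donor_anchor = donor_anchor,
                        acceptor_anchor = acceptor_anchor),
                   class = "anchor_map")
  map$anchor_index <- intron_index(cnomen_anchor, intron_length,
                                   donor_anchor, acceptor_anchor)
  map
}

#' Convert an intronic c. position to a genomic coordinate
#'
#' On the minus strand, moving in transcript direction (increasing intron
#' index) decreases the genomic coordinate.
#'
#' @param p A `cnomen` position inside the mapped intron.
#' @param map An [anchor_map()].
#' @return Integer genomic coordinate (1-based).
#' @export
cnomen_to_genomic <- function(p, map) {
  stopifnot(inherits(map, "anchor_map"))
  i <- intron_index(p, map$intron_length, map$donor_anchor,
                    map$acceptor_anchor)
  d <- i - map$anchor_index
  if (map$gene_strand == "+") map$genomic_anchor + d else map$genomic_anchor - d
}

#' Convert a genomic coordinate to an intronic c. position
#'
#' Positions in the 5' half of the intron are reported with `+` offsets from
#' the upstream exon; positions in the 3' half with `-` offsets from the
#' downstream exon (the HGVS nearest-exon convention).
#'
#' @param g Integer genomic coordinate.
#' @param map An [anchor_map()].
#' @return A `cnomen` position.
#' @export
genomic_to_cnomen <- function(g, map) {
  stopifnot(inherits(map, "anchor_map"))
  d <- if (map$gene_strand == "+") g - map$genomic_anchor
       else map$genomic_anchor - g
  i <- map$anchor_index + d
  if (i < 1L || i > map$intron_length)
    stop("genomic position ", g, " lies outside the mapped intron")
  index_to_cnomen(i, map$intron_length, map$donor_anchor, map$acceptor_anchor)
}

index_to_cnomen <- function(i, intron_length, donor_anchor, acceptor_anchor) {
  if (i <= ceiling(intron_length / 2))
    cnomen(donor_anchor, i)
  else
    cnomen(acceptor_anchor, i - intron_length - 1L)
}

#' Distance and span length between two intronic positions
#'
#' `cnomen_span_length(a, b, ...)` is the number of bases in the inclusive
#' transcript-sense span from `a` to `b`; `cnomen_distance` is the signed
#' index difference `b - a`. The intron length is only required when the two
#' positions use different anchors (`+` vs `-` offsets).
#'
#' @param a,b `cnomen` positions within one intron, `a` 5' of `b`.
#' @param intron_length Intron length in bp (optional if anchors agree).
#' @return Integer bp.
#' @export
cnomen_span_length <- function(a, b, intron_length = NULL) {
  cnomen_distance(a, b, intron_length) + 1L
}

#' @rdname cnomen_span_length
#' @export
cnomen_distance <- function(a, b, intron_length = NULL) {
  stopifnot(inherits(a, "cnomen"), inherits(b, "cnomen"))
  same_form <- sign(a$offset) == sign(b$offset) && a$anchor == b$anchor
  if (same_form) return(b$offset - a$offset)
  if (is.null(intron_length))
    stop("intron_length is required to compare positions with different anchors")
  da <- min(a$anchor, b$anchor); aa <- max(a$anchor, b$anchor)
  intron_index(b, intron_length, da, aa) - intron_index(a, intron_length, da, aa)
}

#' Define a minigene construct
#'
#' A minigene construct consists of ordered backbone exons with a genomic
#' insert cloned between two of them. The insert is described both as a
#' genomic interval and as a c.-position span (its transcript-sense 5' and 3'
#' ends); the two descriptions must agree in length.
#'
#' @param name Construct name.
#' @param backbone_exons `data.frame` with columns `name` and `length` (bp),
#'   in transcript order.
#' @param insert_interval `genomic_interval` of the insert.
#' @param insert_span List of two `cnomen` positions: transcript-sense 5' and
#'   3' ends of the insert.
#' @param intron_length Length of the host intron in bp.
#' @param insert_after Number of backbone exons preceding the insert.
#' @return An object of class `minigene_construct`.
#' @export
minigene_construct <- function(name, backbone_exons, insert_interval,
                               insert_span, intron_length, insert_after = 1L) {
  stopifnot(is.data.frame(backbone_exons),
            all(c("name", "length") %in% names(backbone_exons)),
            inherits(insert_interval, "genomic_interval"),
            length(insert_span) == 2L)
  backbone_exons$length <- as.integer(backbone_exons$length)
  stopifnot(all(backbone_exons$length >= 1L))
  insert_after <- as.integer(insert_after)
  if (insert_after < 1L || insert_after >= nrow(backbone_exons))
    stop("insert must fall strictly between backbone exons")
  intron_length <- as.integer(intron_length)
  a5 <- insert_span[[1]]; a3 <- insert_span[[2]]
  glen <- interval_length(insert_interval)
  clen <- cnomen_span_length(a5, a3, intron_length)
  if (glen != clen)
    stop("insert genomic length (", glen, ") does not match its c. span (",
         clen, " bp)")
  da <- min(a5$anchor, a3$anchor); aa <- max(a5$anchor, a3$anchor)
  i5 <- intron_index(a5, intron_length, da, aa)
  # genomic coordinate of the insert 5' end depends on strand
  g5 <- if (insert_interval$strand == "-") insert_interval$end
        else insert_interval$start
  map <- anchor_map(a5, g5, insert_interval$strand, intron_length)
  structure(list(name = name,
                 backbone_exons = backbone_exons,
                 insert = insert_interval,
                 insert_span = insert_span,
                 insert_length = glen,
                 insert_after = insert_after,
                 intron_length = intron_length,
                 donor_anchor = da, acceptor_anchor = aa,
                 span_start_index = i5,
                 anchor_map = map),
            class = "minigene_construct")
}

#' @export
print.minigene_construct <- function(x, ...) {
  cat("minigene construct '", x$name, "'\n", sep = "")
  cat("  backbone exons:",
      paste0(x$backbone_exons$name, " (", x$backbone_exons$length, " bp)",
             collapse = ", "), "\n")
  cat("  insert: ", x$insert$chrom, ":", x$insert$start, "-", x$insert$end,
      " (", x$insert$strand, "), ", x$insert_length, " bp, ",
      format(x$insert_span[[1]]), "..", format(x$insert_span[[2]]),
      "\n", sep = "")
  invisible(x)
}

#' Backbone spliced length of a construct
#' @param construct A `minigene_construct`.
#' @return Integer bp (sum of backbone exon lengths).
#' @export
backbone_length <- function(construct) {
  sum(construct$backbone_exons$length)
}

#' Map a c. position to the 1-based transcript-sense insert position
#'
#' The insert 5' end maps to position 1; positions increase in transcript
#' direction up to the insert length.
#'
#' @param p A `cnomen` position within the insert span.
#' @param construct A `minigene_construct`.
#' @return Integer position in `1..insert_length`.
#' @examples
#' fx <- build_fixture_construct()
#' construct_position(parse_cnomen("c.1555-5923"), fx$construct)  # 3664
#' @export
construct_position <- function(p, construct) {
  stopifnot(inherits(construct, "minigene_construct"))
  i <- intron_index(p, construct$intron_length, construct$donor_anchor,
                    construct$acceptor_anchor)
  pos <- i - construct$span_start_index + 1L
  if (pos < 1L || pos > construct$insert_length)
    stop("position ", format(p), " lies outside the insert span")
  pos
}

#' Map a transcript-sense insert position back to a c. position
#' @param pos Integer position in `1..insert_length`.
#' @param construct A `minigene_construct`.
#' @return A `cnomen` position.
#' @export
construct_to_cnomen <- function(pos, construct) {
  stopifnot(inherits(construct, "minigene_construct"))
  pos <- as.integer(pos)
  if (pos < 1L || pos > construct$insert_length)
    stop("insert position ", pos, " out of range 1..",
         construct$insert_length)
  i <- pos + construct$span_start_index - 1L
  index_to_cnomen(i, construct$intron_length, construct$donor_anchor,
                  construct$acceptor_anchor)
}

#' Offset of the insert within the construct pre-mRNA
#'
#' Number of backbone-exon bases preceding the insert; insert position `k`
#' corresponds to pre-mRNA position `insert_offset(construct) + k`.
#'
#' @param construct A `minigene_construct`.
#' @return Integer bp.
#' @export
insert_offset <- function(construct) {
  sum(construct$backbone_exons$length[seq_len(construct$insert_after)])
}

#' Total pre-mRNA (unspliced) length of the construct
#' @param construct A `minigene_construct`.
#' @return Integer bp.
#' @export
premrna_length <- function(construct) {
  backbone_length(construct) + construct$insert_length
}

#' Map a c. position to the construct pre-mRNA coordinate
#' @param p A `cnomen` position within the insert span.
#' @param construct A `minigene_construct`.
#' @return Integer pre-mRNA position.
#' @export
premrna_position <- function(p, construct) {
  insert_offset(construct) + construct_position(p, construct)
}

# pre-mRNA intervals of the backbone exons, in transcript order
backbone_exon_intervals <- function(construct) {
  ex <- construct$backbone_exons
  n <- nrow(ex)
  starts <- integer(n); ends <- integer(n)
  cursor <- 0L
  for (k in seq_len(n)) {
    if (k == construct$insert_after + 1L) cursor <- cursor + construct$insert_length
    starts[k] <- cursor + 1L
    ends[k] <- cursor + ex$length[k]
    cursor <- ends[k]
  }
  data.frame(name = ex$name, start = starts, end = ends,
             length = ex$length, stringsAsFactors = FALSE)
}

#' Define a transcript model over a construct
#'
#' A transcript is the ordered set of backbone exons plus zero or more
#' pseudoexons from the insert, each given as a transcript-sense c. span.
#'
#' @param id Transcript identifier (e.g. `"T1"`).
#' @param construct A `minigene_construct`.
#' @param pseudoexons Named list; each element is a list with fields `name`
#'   and `span` (list of two `cnomen`: acceptor then donor position). May be
#'   empty for the backbone-only transcript.
#' @param effect Label describing the effect on the transcript, e.g. `"WT"`,
#'   `"out-of-frame"`, `"in-frame-stop"`.
#' @return An object of class `transcript_model` with a `segments`
#'   data.frame (pre-mRNA coordinates, transcript order).
#' @export
transcript_model <- function(id, construct, pseudoexons = list(),
                             effect = "WT") {
  stopifnot(inherits(construct, "minigene_construct"))
  off <- insert_offset(construct)
  ex <- backbone_exon_intervals(construct)
  pe_rows <- lapply(pseudoexons, function(pe) {
    s <- construct_position(pe$span[[1]], construct)
    e <- construct_position(pe$span[[2]], construct)
    if (s > e) stop("pseudoexon '", pe$name, "' span is reversed")
    data.frame(name = pe$name, start = off + s, end = off + e,
               length = e - s + 1L, stringsAsFactors = FALSE)
  })
  pe_df <- if (length(pe_rows)) do.call(rbind, pe_rows) else
    ex[0, c("name", "start", "end", "length")]
  ex$kind <- "backbone"
  if (nrow(pe_df)) pe_df$kind <- "pseudoexon"
  segs <- rbind(ex, pe_df)
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  if (any(segs$start[-1] <= segs$end[-nrow(segs)]))
    stop("transcript '", id, "' has overlapping segments")
  structure(list(id = id, segments = segs, effect = effect,
                 construct_name = construct$name),
            class = "transcript_model")
}

#' Spliced length of a transcript model
#' @param t A `transcript_model`.
#' @return Integer bp (sum of segment lengths).
#' @examples
#' fx <- build_fixture_construct()
#' transcript_length(fx$catalog$models[["T4"]])  # 420
#' @export
transcript_length <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  if (nrow(t$segments) == 0L) stop("transcript '", t$id, "' has no segments")
  sum(t$segments$length)
}

#' Canonical junction chain of a transcript model
#'
#' @param t A `transcript_model`.
#' @return `data.frame` with columns `donor` (pre-mRNA position of the last
#'   exonic base) and `acceptor` (first exonic base of the next segment).
#' @export
canonical_chain <- function(t) {
  segs <- t$segments
  n <- nrow(segs)
  if (n < 2L)
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  keep <- segs$start[-1] - segs$end[-n] > 1L
  data.frame(donor = segs$end[-n][keep], acceptor = segs$start[-1][keep])
}

#' Predicted RT-PCR amplicon length on a transcript
#'
#' Computes the spliced amplicon length between a forward primer 5' end and a
#' reverse primer 3'-most template position. Positions may be given on the
#' spliced transcript itself (`coords = "spliced"`) or on the construct
#' pre-mRNA (`coords = "premrna"`), in which case they are mapped through the
#' transcript's segments; a pre-mRNA position falling in a segment the
#' transcript lacks yields a "no product" result (`NA` with attribute
#' `reason`), not an error.
#'
#' @param t A `transcript_model`.
#' @param fwd_start,rev_end Primer positions (see `coords`).
#' @param coords Coordinate system of the primer positions.
#' @return Integer bp, or `NA` (attribute `reason = "no product"`).
#' @export
predicted_amplicon_length <- function(t, fwd_start, rev_end,
                                      coords = c("spliced", "premrna")) {
  coords <- match.arg(coords)
  stopifnot(inherits(t, "transcript_model"))
  len <- transcript_length(t)
  if (coords == "premrna") {
    fwd_start <- spliced_position(t, fwd_start)
    rev_end <- spliced_position(t, rev_end)
    if (is.na(fwd_start) || is.na(rev_end))
      return(structure(NA_integer_, reason = "no product"))
  }
  fwd_start <- as.integer(fwd_start); rev_end <- as.integer(rev_end)
  if (fwd_start < 1L || rev_end > len)
    stop("primer positions outside spliced transcript (length ", len, ")")
  if (fwd_start > rev_end)
    stop("fwd_start must be <= rev_end")
  rev_end - fwd_start + 1L
}

# map a pre-mRNA position to a spliced position on transcript t
# (NA if the position is not contained in any segment)
spliced_position <- function(t, pos) {
  segs <- t$segments
  cum <- cumsum(segs$length) - segs$length
  hit <- which(pos >= segs$start & pos <= segs$end)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(cum[hit[1]] + (pos - segs$start[hit[1]]) + 1L)
}

#' Read or write a construct definition as YAML
#'
#' The configuration carries the construct name, backbone exons, the insert's
#' genomic interval and c. span, and the host intron length.
#'
#' @param path File path.
#' @return `load_construct` returns a `minigene_construct`.
#' @export
load_construct <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("name", "backbone_exons", "insert")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("construct config is missing fields: ", paste(missing, collapse = ", "))
  ex <- do.call(rbind, lapply(cfg$backbone_exons, function(e)
    data.frame(name = e$name, length = as.integer(e$length),
               stringsAsFactors = FALSE)))
  ins <- cfg$insert
  minigene_construct(
    name = cfg$name,
    backbone_exons = ex,
    insert_interval = genomic_interval(ins$chrom, ins$start, ins$end,
                                       ins$strand),
    insert_span = list(parse_cnomen(ins$cnomen_start),
                       parse_cnomen(ins$cnomen_end)),
    intron_length = ins$intron_length,
    insert_after = if (is.null(cfg$insert_after)) 1L else cfg$insert_after)
}

#' @rdname load_construct
#' @param construct A `minigene_construct` to serialise.
#' @export
write_construct <- function(construct, path) {
  stopifnot(inherits(construct, "minigene_construct"))
  cfg <- list(
    name = construct$name,
    backbone_exons = lapply(seq_len(nrow(construct$backbone_exons)),
      function(k) list(name = construct$backbone_exons$name[k],
                       length = construct$backbone_exons$length[k])),
    insert = list(chrom = construct$insert$chrom,
                  start = construct$insert$start,
                  end = construct$insert$end,
                  strand = construct$insert$strand,
                  cnomen_start = format(construct$insert_span[[1]]),
                  cnomen_end = format(construct$insert_span[[2]]),
                  intron_length = construct$intron_length),
    insert_after = construct$insert_after)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export intervals as BED
#'
#' Writes 1-based inclusive intervals as 0-based half-open BED lines.
#'
#' @param df `data.frame` with columns `chrom`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  out <- data.frame(chrom = df$chrom,
                    start = as.integer(df$start) - 1L,
                    end = as.integer(df$end),
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
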