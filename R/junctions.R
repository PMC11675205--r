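# Reading spliced alignments against the construct reference and extracting
# per-read splice-junction chains with QC filters.

#' Read spliced alignments from SAM or BAM
#'
#' Uses Rsamtools; plain-text SAM files are converted to BAM on the fly.
#' All records are returned (including unmapped/secondary/supplementary);
#' filtering and counting happen in [extract_junction_chains()]. Junction
#' coordinates are reference coordinates, so reverse-strand alignments need
#' no special handling.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return `data.frame` with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  data.frame(qname = res$qname,
             flag = as.integer(res$flag),
             rname = as.character(res$rname),
             pos = as.integer(res$pos),
             mapq = as.integer(res$mapq),
             cigar = as.character(res$cigar),
             stringsAsFactors = FALSE)
}

# tokenize one CIGAR string into (lengths, ops)
parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string: '", cigar, "'")
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

# cursor walk over reference-consuming ops for one read
walk_read <- function(pos, cigar, min_skip, promote_deletion_ge) {
  cg <- parse_cigar(cigar)
  cur <- pos
  donors <- integer(0); acceptors <- integer(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (len < 1L) stop("non-positive CIGAR op length in '", cigar, "'")
    if (op %in% c("M", "=", "X")) {
      cur <- cur + len
    } else if (op == "N") {
      if (len >= min_skip) {
        donors <- c(donors, cur - 1L)
        acceptors <- c(acceptors, cur + len)
      }
      cur <- cur + len
    } else if (op == "D") {
      # long-read aligners sometimes encode short skips as deletions
      if (len >= promote_deletion_ge) {
        donors <- c(donors, cur - 1L)
        acceptors <- c(acceptors, cur + len)
      }
      cur <- cur + len
    }
    # I, S, H, P do not consume reference
  }
  list(donor = donors, acceptor = acceptors, start = pos, end = cur - 1L)
}

#' Extract splice-junction chains from alignments
#'
#' Walks the reference-consuming CIGAR operations of each mapped primary
#' alignment. Every skip (`N`) of at least `min_skip` bp becomes a junction
#' (donor = last exonic base before the gap, acceptor = first exonic base
#' after it); deletions of at least `promote_deletion_ge` bp are promoted to
#' junctions. Unmapped, secondary and supplementary records are skipped and
#' counted, never an error.
#'
#' @param aln `data.frame` from [read_alignments()] (or
#'   [simulate_alignments()]).
#' @param min_skip Minimum skip length treated as a junction (bp).
#' @param promote_deletion_ge Deletions at least this long are promoted to
#'   junctions (bp).
#' @return An object of class `junction_chains`: list with `reads`
#'   (per-read `data.frame`: `qname`, `mapq`, `start`, `end`,
#'   `n_junctions`), `junctions` (`data.frame`: `read`, `donor`,
#'   `acceptor`, in read order), and `counters` (skipped-record counts).
#' @export
extract_junction_chains <- function(aln, min_skip = 30L,
                                    promote_deletion_ge = 30L) {
  stopifnot(is.data.frame(aln),
            all(c("qname", "flag", "pos", "mapq", "cigar") %in% names(aln)))
  unmapped <- bitwAnd(aln$flag, 4L) > 0L
  secondary <- bitwAnd(aln$flag, 256L) > 0L
  supplementary <- bitwAnd(aln$flag, 2048L) > 0L
  keep <- !(unmapped | secondary | supplementary)
  counters <- c(total = nrow(aln),
                unmapped = sum(unmapped),
                secondary = sum(secondary & !unmapped),
                supplementary = sum(supplementary & !unmapped & !secondary),
                used = sum(keep))
  sub <- aln[keep, , drop = FALSE]
  walks <- lapply(seq_len(nrow(sub)), function(i)
    walk_read(sub$pos[i], sub$cigar[i], min_skip, promote_deletion_ge))
  nj <- vapply(walks, function(w) length(w$donor), 1L)
  reads <- data.frame(qname = sub$qname,
                      mapq = sub$mapq,
                      start = vapply(walks, `[[`, 1L, "start"),
                      end = vapply(walks, `[[`, 1L, "end"),
                      n_junctions = nj,
                      stringsAsFactors = FALSE)
  junctions <- data.frame(
    read = rep(seq_len(nrow(sub)), nj),
    donor = unlist(lapply(walks, `[[`, "donor")),
    acceptor = unlist(lapply(walks, `[[`, "acceptor")))
  if (nrow(junctions) && any(junctions$donor >= junctions$acceptor))
    stop("internal error: junction donor >= acceptor")
  structure(list(reads = reads, junctions = junctions, counters = counters),
            class = "junction_chains")
}

#' @export
print.junction_chains <- function(x, ...) {
  cat("junction chains for", nrow(x$reads), "reads (",
      nrow(x$junctions), "junctions )\n")
  cat("  record counters:",
      paste(names(x$counters), x$counters, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' QC-filter junction chains
#'
#' A read passes if its mapping quality is at least `min_mapq` and its
#' aligned span covers at least `min_terminal_flank` bases of both the first
#' and the last backbone exon of the construct (full-length amplicons).
#'
#' @param chains A `junction_chains` object.
#' @param construct A `minigene_construct`.
#' @param min_mapq Minimum mapping quality.
#' @param min_terminal_flank Minimum coverage of each terminal exon (bp).
#' @return The `junction_chains` object with `reads$qc_pass` (logical) and
#'   `reads$qc_reason` (`"pass"`, `"mapq"` or `"terminal coverage"`) added.
#' @export
qc_filter <- function(chains, construct, min_mapq = 10L,
                      min_terminal_flank = 20L) {
  stopifnot(inherits(chains, "junction_chains"),
            inherits(construct, "minigene_construct"))
  ex <- backbone_exon_intervals(construct)
  first <- ex[1, ]; last <- ex[nrow(ex), ]
  r <- chains$reads
  cov_first <- pmin(r$end, first$end) - pmax(r$start, first$start) + 1L
  cov_last <- pmin(r$end, last$end) - pmax(r$start, last$start) + 1L
  mapq_ok <- r$mapq >= min_mapq
  term_ok <- cov_first >= min_terminal_flank & cov_last >= min_terminal_flank
  r$qc_pass <- mapq_ok & term_ok
  r$qc_reason <- ifelse(!mapq_ok, "mapq",
                        ifelse(!term_ok, "terminal coverage", "pass"))
  chains$reads <- r
  chains
}
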