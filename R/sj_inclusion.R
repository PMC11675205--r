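# Short-read splice-junction count files (9-column SJ.out.tab dialect) and
# pseudoexon inclusion estimates from split-read counts.

#' Read a 9-column splice-junction count file (SJ.out.tab dialect)
#'
#' Columns: chromosome; intron start and end (1-based, first and last
#' intronic base); strand code (0 undefined, 1 `+`, 2 `-`); intron motif
#' code; annotated flag; uniquely-mapping read count; multi-mapping read
#' count; maximum spliced overhang (bp). Records failing the filters are
#' dropped and counted in the `dropped` attribute.
#'
#' @param path File path.
#' @param min_unique Minimum unique-read count to retain a record.
#' @param min_overhang Minimum maximum-overhang to retain a record.
#' @return `data.frame` with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `motif`, `annotated`, `n_unique`, `n_multi`, `max_overhang`;
#'   attribute `dropped` holds filter counts.
#' @export
read_sj_file <- function(path, min_unique = 1L, min_overhang = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(0), intron_start = integer(0),
                      intron_end = integer(0), strand = integer(0),
                      motif = integer(0), annotated = integer(0),
                      n_unique = integer(0), n_multi = integer(0),
                      max_overhang = integer(0))
    attr(out, "dropped") <- c(min_unique = 0L, min_overhang = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed SJ line ", which(nf != 9L)[1], ": expected 9 columns, ",
         "found ", nf[nf != 9L][1])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.integer))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1L)
  bad <- which(rowSums(is.na(num)) > 0L)
  if (length(bad))
    stop("malformed SJ line ", bad[1], ": non-integer field")
  out <- data.frame(chrom = m[, 1],
                    intron_start = num[, 1], intron_end = num[, 2],
                    strand = num[, 3], motif = num[, 4],
                    annotated = num[, 5], n_unique = num[, 6],
                    n_multi = num[, 7], max_overhang = num[, 8],
                    stringsAsFactors = FALSE)
  if (any(out$intron_start > out$intron_end))
    stop("malformed SJ line ", which(out$intron_start > out$intron_end)[1],
         ": intron start > end")
  if (any(out$n_unique < 0L | out$n_multi < 0L))
    stop("negative read counts in SJ file")
  drop_u <- out$n_unique < min_unique
  drop_o <- !drop_u & out$max_overhang < min_overhang
  res <- out[!(drop_u | drop_o), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- c(min_unique = sum(drop_u),
                            min_overhang = sum(drop_o))
  res
}

#' Pseudoexon inclusion estimate from split-read counts
#'
#' Given the split-read counts supporting the junction from the upstream
#' exon into the pseudoexon (`j_in_5`), from the pseudoexon into the
#' downstream exon (`j_in_3`), and the pseudoexon-skipping junction between
#' the two flanking exons (`j_skip`), the inclusion rate is bounded by
#' `100 * min(j_in_5, j_in_3) / denom` and `100 * max(j_in_5, j_in_3) /
#' denom` with `denom = j_skip + max(j_in_5, j_in_3)` (the two inclusion
#' junctions evidence the same molecules, so the larger one joins the
#' denominator). A PSI-style point estimator using the mean of the two
#' inclusion counts is available via `estimator = "psi"`.
#'
#' @param j_in_5,j_in_3,j_skip Non-negative split-read counts.
#' @param estimator `"range"` (default) or `"psi"`.
#' @return An object of class `inclusion_estimate` with fields `low`,
#'   `high` (percent), the supporting counts and a `detected` flag. With no
#'   inclusion or skip evidence at all the estimate is (0, 0), undetected.
#' @examples
#' pseudoexon_inclusion(5, 12, 993)  # 0.5 - 1.2 %
#' @export
pseudoexon_inclusion <- function(j_in_5, j_in_3, j_skip,
                                 estimator = c("range", "psi")) {
  estimator <- match.arg(estimator)
  counts <- c(j_in_5 = j_in_5, j_in_3 = j_in_3, j_skip = j_skip)
  if (any(is.na(counts)) || any(counts < 0))
    stop("split-read counts must be non-negative")
  detected <- (j_in_5 + j_in_3) > 0
  if (estimator == "range") {
    denom <- j_skip + max(j_in_5, j_in_3)
    if (denom == 0) {
      low <- high <- 0
    } else {
      low <- 100 * min(j_in_5, j_in_3) / denom
      high <- 100 * max(j_in_5, j_in_3) / denom
    }
  } else {
    inc <- mean(c(j_in_5, j_in_3))
    denom <- j_skip + inc
    low <- high <- if (denom == 0) 0 else 100 * inc / denom
  }
  structure(list(low = low, high = high,
                 j_in_5 = j_in_5, j_in_3 = j_in_3, j_skip = j_skip,
                 detected = detected, estimator = estimator),
            class = "inclusion_estimate")
}

#' @export
print.inclusion_estimate <- function(x, ...) {
  if (!x$detected) {
    cat("pseudoexon inclusion: not detected\n")
  } else {
    cat(sprintf("pseudoexon inclusion: %.1f-%.1f%% (j_in_5=%d, j_in_3=%d, j_skip=%d)\n",
                x$low, x$high, x$j_in_5, x$j_in_3, x$j_skip))
  }
  invisible(x)
}

#' Locate pseudoexon inclusion/skipping junctions in SJ records
#'
#' Matches records by exact intron-boundary coordinates, strand-aware. The
#' flanking exons are given in transcript sense (5' then 3'); on the minus
#' strand the transcript-5' exon is the one with the higher genomic
#' coordinates.
#'
#' @param records `data.frame` from [read_sj_file()].
#' @param pe `genomic_interval` of the pseudoexon.
#' @param exon_5p,exon_3p `genomic_interval`s of the flanking exons in
#'   transcript sense; all three spans must share a chromosome and must not
#'   overlap.
#' @return Named integer vector `(j_in_5, j_in_3, j_skip)` of unique-mapper
#'   counts (0 for junctions absent from the file).
#' @export
locate_pseudoexon_junctions <- function(records, pe, exon_5p, exon_3p) {
  stopifnot(inherits(pe, "genomic_interval"),
            inherits(exon_5p, "genomic_interval"),
            inherits(exon_3p, "genomic_interval"))
  if (length(unique(c(pe$chrom, exon_5p$chrom, exon_3p$chrom))) != 1L)
    stop("pseudoexon and flanking exons must share a chromosome")
  spans <- list(exon_5p, pe, exon_3p)
  for (i in 1:2) for (k in (i + 1):3) {
    if (spans[[i]]$start <= spans[[k]]$end &&
        spans[[k]]$start <= spans[[i]]$end)
      stop("pseudoexon and flanking exon spans overlap")
  }
  minus <- pe$strand == "-"
  # intron between genomic-left exon and genomic-right feature:
  intr <- function(left, right) c(left$end + 1L, right$start - 1L)
  if (!minus) {
    j5 <- intr(exon_5p, pe); j3 <- intr(pe, exon_3p)
    js <- intr(exon_5p, exon_3p)
  } else {
    j5 <- intr(pe, exon_5p); j3 <- intr(exon_3p, pe)
    js <- intr(exon_3p, exon_5p)
  }
  lookup <- function(b) {
    hit <- records$chrom == pe$chrom & records$intron_start == b[1] &
      records$intron_end == b[2]
    if (any(hit)) sum(records$n_unique[hit]) else 0L
  }
  c(j_in_5 = lookup(j5), j_in_3 = lookup(j3), j_skip = lookup(js))
}
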