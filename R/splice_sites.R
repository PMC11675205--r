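# Position-frequency-matrix scoring of donor/acceptor splice sites and the
# candidate splice-site registry used for junction correction.

#' Create a splice-site position frequency matrix
#'
#' Weights are per-position base frequencies; the raw score of a window is the
#' sum of the weights of its observed bases, and the transformed score
#' min-max-normalises the raw score to a percent:
#' `100 * (raw - min_possible) / (max_possible - min_possible)`.
#' A log-odds variant of the raw score (against a uniform background) is
#' available via the `scoring` switch of [score_site()].
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @param weights 4 x W numeric matrix, rows named A, C, G, T; columns are
#'   window positions. All weights must be non-negative.
#' @param n_exonic Number of exonic positions in the window (at the window
#'   start for a donor, at the window end for an acceptor). The window must
#'   cover the invariant GT (donor) / AG (acceptor) dinucleotide.
#' @return An object of class `splice_matrix`.
#' @export
splice_matrix <- function(kind, weights, n_exonic) {
  kind <- match.arg(kind, c("donor", "acceptor"))
  weights <- as.matrix(weights)
  if (!identical(rownames(weights), c("A", "C", "G", "T")))
    stop("weights must have rows named A, C, G, T (in that order)")
  if (any(weights < 0)) stop("weights must be non-negative")
  W <- ncol(weights)
  n_exonic <- as.integer(n_exonic)
  n_intronic <- W - n_exonic
  if (n_intronic < 2L)
    stop("window must include at least the invariant splice dinucleotide")
  # index of the junction edge within the window:
  # donor edge = last exonic base; acceptor edge = first exonic base
  edge <- if (kind == "donor") n_exonic else n_intronic + 1L
  structure(list(kind = kind, weights = weights, n_exonic = n_exonic,
                 width = W, edge = edge,
                 min_raw = sum(apply(weights, 2, min)),
                 max_raw = sum(apply(weights, 2, max))),
            class = "splice_matrix")
}

#' Per-position argmax (consensus) sequence of a splice matrix
#' @param m A `splice_matrix`.
#' @return Character scalar of length `m$width`.
#' @export
consensus_sequence <- function(m) {
  stopifnot(inherits(m, "splice_matrix"))
  paste(rownames(m$weights)[apply(m$weights, 2, which.max)], collapse = "")
}

#' Score one splice-site window
#'
#' @param seq_window Nucleotide string whose length equals the matrix width.
#' @param m A `splice_matrix`.
#' @param ambiguous Policy for non-ACGT bases: `"zero"` assigns zero weight,
#'   `"error"` fails. Never silent.
#' @param scoring `"frequency"` (sum of weights; default) or `"logodds"`
#'   (sum of log2 of weight/background with uniform background; only the raw
#'   score differs, the transformed percent is always the min-max-normalised
#'   frequency score).
#' @return List with `raw` and `transformed` (percent in `[0, 100]`).
#' @export
score_site <- function(seq_window, m, ambiguous = c("zero", "error"),
                       scoring = c("frequency", "logodds")) {
  ambiguous <- match.arg(ambiguous)
  scoring <- match.arg(scoring)
  stopifnot(inherits(m, "splice_matrix"))
  chars <- strsplit(toupper(seq_window), "")[[1]]
  if (length(chars) != m$width)
    stop("window length ", length(chars), " does not match matrix width ",
         m$width)
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx) && ambiguous == "error")
    stop("ambiguous base '", chars[which(is.na(idx))[1]], "' in window")
  w <- m$weights[cbind(idx, seq_len(m$width))]
  w[is.na(w)] <- 0
  raw_freq <- sum(w)
  raw <- if (scoring == "logodds") {
    bg <- colSums(m$weights) / 4
    sum(log2(pmax(w, 1e-9) / pmax(bg, 1e-9)))
  } else raw_freq
  span <- m$max_raw - m$min_raw
  list(raw = raw,
       transformed = if (span > 0) 100 * (raw_freq - m$min_raw) / span else 0)
}

#' Scan a sequence for splice sites above a threshold
#'
#' Reports every window position whose transformed score is at least
#' `threshold`, at the junction-edge convention: the position of the last
#' exonic base for donors, of the first exonic base for acceptors.
#'
#' @param seq Nucleotide string (length >= matrix width).
#' @param m A `splice_matrix`.
#' @param threshold Minimum transformed score (percent).
#' @return `data.frame` with columns `kind`, `pos`, `raw`, `transformed`,
#'   `provenance` (`"predicted"`).
#' @export
scan_sites <- function(seq, m, threshold = 70) {
  stopifnot(inherits(m, "splice_matrix"))
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  W <- m$width
  if (n < W) stop("sequence shorter than matrix window (", W, " nt)")
  idx <- match(chars, c("A", "C", "G", "T"))
  nwin <- n - W + 1L
  raw <- numeric(nwin)
  for (j in seq_len(W)) {
    col <- m$weights[, j]
    wj <- col[idx[j:(j + nwin - 1L)]]
    wj[is.na(wj)] <- 0
    raw <- raw + wj
  }
  span <- m$max_raw - m$min_raw
  transformed <- if (span > 0) 100 * (raw - m$min_raw) / span else
    rep(0, nwin)
  keep <- which(transformed >= threshold)
  data.frame(kind = rep(m$kind, length(keep)),
             pos = keep + m$edge - 1L,
             raw = raw[keep],
             transformed = transformed[keep],
             provenance = rep("predicted", length(keep)),
             stringsAsFactors = FALSE)
}

#' Read / write a splice matrix as a tab-separated table
#'
#' The file is a TSV with a `base` column (A/C/G/T) and one numeric column
#' per window position, preceded by two comment lines
#' `#kind <donor|acceptor>` and `#exonic <n>`.
#'
#' @param path File path.
#' @return `read_splice_matrix` returns a `splice_matrix`.
#' @export
read_splice_matrix <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "[ \t]+")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (!all(c("kind", "exonic") %in% names(meta)))
    stop("splice matrix file must carry '#kind' and '#exonic' headers")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  w <- as.matrix(tab[, -1, drop = FALSE])
  rownames(w) <- tab[[1]]
  colnames(w) <- NULL
  splice_matrix(meta[["kind"]], w[c("A", "C", "G", "T"), , drop = FALSE],
                as.integer(meta[["exonic"]]))
}

#' @rdname read_splice_matrix
#' @param m A `splice_matrix` to serialise.
#' @export
write_splice_matrix <- function(m, path) {
  stopifnot(inherits(m, "splice_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#kind", m$kind), paste("#exonic", m$n_exonic)), con)
  tab <- data.frame(base = rownames(m$weights), m$weights, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged default donor/acceptor matrices
#'
#' Generic human-like base-frequency matrices: donor window 9 nt (3 exonic +
#' 6 intronic, invariant GT), acceptor window 16 nt (14 intronic + 2 exonic,
#' invariant AG).
#'
#' @return Named list with elements `donor` and `acceptor`.
#' @export
default_splice_matrices <- function() {
  list(
    donor = read_splice_matrix(system.file("extdata", "donor_matrix.tsv",
                                           package = "minisplice",
                                           mustWork = TRUE)),
    acceptor = read_splice_matrix(system.file("extdata", "acceptor_matrix.tsv",
                                              package = "minisplice",
                                              mustWork = TRUE)))
}

#' Build the candidate splice-site registry for a construct
#'
#' The registry holds the construct's annotated backbone exon boundary sites
#' plus any predicted or user-supplied cryptic sites, each at the
#' junction-edge convention on construct pre-mRNA coordinates. Adding the
#' same (kind, position) twice is idempotent (the higher score is kept);
#' the same position with conflicting kinds is an error.
#'
#' @param construct A `minigene_construct`.
#' @param predicted Optional `data.frame` as returned by [scan_sites()].
#' @param user_sites Optional `data.frame` with columns `kind`, `pos` and
#'   optionally `score`; provenance is recorded as `"user"`.
#' @return An object of class `site_registry`.
#' @export
build_registry <- function(construct, predicted = NULL, user_sites = NULL) {
  stopifnot(inherits(construct, "minigene_construct"))
  ex <- backbone_exon_intervals(construct)
  n <- nrow(ex)
  ann <- rbind(
    data.frame(kind = "donor", pos = ex$end[-n], score = 100,
               provenance = "annotated", stringsAsFactors = FALSE),
    data.frame(kind = "acceptor", pos = ex$start[-1], score = 100,
               provenance = "annotated", stringsAsFactors = FALSE))
  sites <- ann
  if (!is.null(predicted) && nrow(predicted)) {
    p <- data.frame(kind = predicted$kind, pos = predicted$pos,
                    score = predicted$transformed, provenance = "predicted",
                    stringsAsFactors = FALSE)
    sites <- rbind(sites, p)
  }
  if (!is.null(user_sites) && nrow(user_sites)) {
    u <- data.frame(kind = user_sites$kind, pos = user_sites$pos,
                    score = if ("score" %in% names(user_sites))
                      user_sites$score else NA_real_,
                    provenance = "user", stringsAsFactors = FALSE)
    sites <- rbind(sites, u)
  }
  if (any(sites$pos < 1L | sites$pos > premrna_length(construct)))
    stop("registry sites must lie within the construct pre-mRNA")
  # conflicting kind at one position is ambiguous and refused
  tab <- unique(sites[, c("kind", "pos")])
  dup <- tab$pos[duplicated(tab$pos)]
  if (length(dup))
    stop("conflicting site kinds at position(s): ",
         paste(unique(dup), collapse = ", "))
  # idempotent de-duplication per (kind, pos): keep the best-scoring record
  sites <- sites[order(sites$kind, sites$pos, -xtfrm(sites$score)), ]
  sites <- sites[!duplicated(sites[, c("kind", "pos")]), ]
  sites <- sites[order(sites$kind, sites$pos), ]
  rownames(sites) <- NULL
  structure(list(sites = sites, construct_name = construct$name),
            class = "site_registry")
}

#' @export
print.site_registry <- function(x, ...) {
  cat("splice-site registry for construct '", x$construct_name, "' (",
      nrow(x$sites), " sites)\n", sep = "")
  print(x$sites)
  invisible(x)
}

#' Sites of one kind from a registry
#' @param registry A `site_registry`.
#' @param kind `"donor"` or `"acceptor"`.
#' @return `data.frame` of sites, sorted by position.
#' @export
registry_sites <- function(registry, kind) {
  stopifnot(inherits(registry, "site_registry"))
  registry$sites[registry$sites$kind == kind, , drop = FALSE]
}

#' Export registry sites as BED
#' @param registry A `site_registry`.
#' @param path Output file.
#' @param chrom Chromosome/reference name to write (default the construct).
#' @export
write_registry_bed <- function(registry, path, chrom = NULL) {
  s <- registry$sites
  if (is.null(chrom)) chrom <- registry$construct_name
  write_bed(data.frame(chrom = chrom, start = s$pos, end = s$pos,
                       name = paste0(s$kind, "_", s$provenance),
                       score = ifelse(is.na(s$score), 0, s$score)),
            path)
}
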