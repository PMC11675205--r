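# ESE/ESS motif profiling of reference vs variant sequence: overlapping
# hexamer counting and threshold PWM scanning, with per-variant deltas.

#' Create a hexamer motif set
#'
#' @param label `"ESE"` or `"ESS"` (or any other resource label).
#' @param kmers Character vector of 6-mers over A/C/G/T.
#' @return An object of class `hexamer_set`.
#' @export
hexamer_set <- function(label, kmers) {
  kmers <- toupper(kmers)
  if (length(kmers) && (any(nchar(kmers) != 6L) ||
                        any(grepl("[^ACGT]", kmers))))
    stop("all hexamers must be 6-mers over the ACGT alphabet")
  structure(list(label = label, kmers = unique(kmers)), class = "hexamer_set")
}

#' Read a one-hexamer-per-line motif list
#' @param path File path.
#' @param label Resource label (default: file name without extension).
#' @return A `hexamer_set`.
#' @export
read_hexamers <- function(path, label = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- trimws(lines)
  hexamer_set(label, lines[nzchar(lines)])
}

#' Load the packaged synthetic ESE/ESS hexamer sets
#'
#' Small synthetic motif sets for demonstrations and tests; real published
#' hexamer resources can be supplied in the same one-per-line format.
#'
#' @return Named list with elements `ese` and `ess`.
#' @export
default_hexamer_sets <- function() {
  list(ese = read_hexamers(system.file("extdata", "ese_hexamers_synthetic.txt",
                                       package = "minisplice", mustWork = TRUE),
                           label = "ESE"),
       ess = read_hexamers(system.file("extdata", "ess_hexamers_synthetic.txt",
                                       package = "minisplice", mustWork = TRUE),
                           label = "ESS"))
}

#' Count overlapping hexamer-set hits in a sequence
#'
#' Every sliding 6-mer window is counted, overlaps included.
#'
#' @param seq Nucleotide string.
#' @param set A `hexamer_set`.
#' @return Integer count (0, with a warning, if `seq` is shorter than 6 nt).
#' @examples
#' count_hexamers("AAAAAAA", hexamer_set("ESE", "AAAAAA"))  # 2
#' @export
count_hexamers <- function(seq, set) {
  stopifnot(inherits(set, "hexamer_set"))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6L) {
    warning("sequence shorter than 6 nt; hexamer count is 0")
    return(0L)
  }
  if (length(set$kmers) == 0L) return(0L)
  starts <- seq_len(n - 5L)
  wins <- substring(seq, starts, starts + 5L)
  sum(wins %in% set$kmers)
}

#' ESE/ESS hit counts and their ratio
#'
#' @param seq Nucleotide string.
#' @param ese,ess `hexamer_set` objects.
#' @return List with `ese_count`, `ess_count`, `ratio` and `defined`. When
#'   `ess_count` is 0 the ratio is `Inf` (or `NA` if both counts are 0) and
#'   `defined` is `FALSE`; no error is raised.
#' @export
ese_ess_ratio <- function(seq, ese, ess) {
  a <- count_hexamers(seq, ese)
  b <- count_hexamers(seq, ess)
  if (b > 0L) {
    list(ese_count = a, ess_count = b, ratio = a / b, defined = TRUE)
  } else {
    list(ese_count = a, ess_count = b,
         ratio = if (a > 0L) Inf else NA_real_, defined = FALSE)
  }
}

#' Create a threshold-scanned motif matrix
#'
#' @param name Motif name (e.g. a serine/arginine-rich factor motif).
#' @param weights 4 x W numeric matrix, rows named A, C, G, T.
#' @param threshold Score threshold; must lie within the attainable range.
#' @return An object of class `motif_matrix`.
#' @export
motif_matrix <- function(name, weights, threshold) {
  weights <- as.matrix(weights)
  if (!identical(rownames(weights), c("A", "C", "G", "T")))
    stop("weights must have rows named A, C, G, T")
  lo <- sum(apply(weights, 2, min)); hi <- sum(apply(weights, 2, max))
  if (threshold < lo || threshold > hi)
    stop("threshold ", threshold, " outside attainable score range [",
         lo, ", ", hi, "]")
  structure(list(name = name, weights = weights, threshold = threshold,
                 width = ncol(weights)),
            class = "motif_matrix")
}

# start positions (1-based) of windows scoring >= threshold
scan_motif <- function(seq, mm) {
  stopifnot(inherits(mm, "motif_matrix"))
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars); W <- mm$width
  if (n < W) return(integer(0))
  idx <- match(chars, c("A", "C", "G", "T"))
  nwin <- n - W + 1L
  sc <- numeric(nwin)
  for (j in seq_len(W)) {
    wj <- mm$weights[, j][idx[j:(j + nwin - 1L)]]
    wj[is.na(wj)] <- 0
    sc <- sc + wj
  }
  which(sc >= mm$threshold)
}

# apply substitution variants (insert-local positions) to a sequence,
# verifying the reference base at each position
apply_variants_seq <- function(seq, positions, ref, alt) {
  chars <- strsplit(seq, "")[[1]]
  for (k in seq_along(positions)) {
    p <- positions[k]
    if (p < 1L || p > length(chars))
      stop("variant position ", p, " outside the sequence")
    if (!is.na(ref[k]) && chars[p] != ref[k])
      stop("reference base mismatch at position ", p, ": expected ",
           ref[k], ", found ", chars[p])
    if (is.na(alt[k])) stop("variant at position ", p, " has no alt allele")
    chars[p] <- alt[k]
  }
  paste(chars, collapse = "")
}

#' Motif profile delta between reference and variant sequence
#'
#' Applies one or more substitutions (a complex allele is applied jointly)
#' and compares motif content between the reference and variant sequence over
#' windows restricted to the variant neighbourhood: for hexamers, all 6-mer
#' windows overlapping any variant base (`flank = 5`); for motif matrices,
#' hits whose window overlaps any variant base, compared hit-by-hit.
#'
#' @param ref_seq Reference nucleotide string (transcript-sense insert
#'   sequence when `construct` is supplied).
#' @param variants A `cnomen` with alleles, a list of such (complex allele),
#'   or a `data.frame` with columns `pos`, `ref`, `alt` giving positions
#'   directly on `ref_seq`.
#' @param construct Optional `minigene_construct` used to map `cnomen`
#'   variants onto `ref_seq` via [construct_position()].
#' @param flank Hexamer flank in bp (default 5: every 6-mer overlapping a
#'   variant base).
#' @param ese,ess `hexamer_set` resources (default: packaged synthetic sets).
#' @param matrices Optional named list of `motif_matrix` objects.
#' @return An object of class `delta_profile`: per-resource reference/variant
#'   counts and signed deltas (`variant - reference`), the windowed ESE/ESS
#'   ratio pair, and per-matrix gained/lost hit positions.
#' @export
variant_motif_delta <- function(ref_seq, variants, construct = NULL,
                                flank = 5L,
                                ese = default_hexamer_sets()$ese,
                                ess = default_hexamer_sets()$ess,
                                matrices = list()) {
  v <- normalise_variants(variants, construct)
  ref_seq <- toupper(ref_seq)
  var_seq <- apply_variants_seq(ref_seq, v$pos, v$ref, v$alt)
  n <- nchar(ref_seq)

  # hexamer start positions overlapping any variant +/- flank
  starts <- sort(unique(unlist(lapply(v$pos, function(p)
    seq(max(1L, p - flank), min(n - 5L, p))))))
  starts <- starts[starts >= 1L & starts <= n - 5L]
  count_in <- function(seq, set) {
    if (length(starts) == 0L || length(set$kmers) == 0L) return(0L)
    sum(substring(seq, starts, starts + 5L) %in% set$kmers)
  }
  ese_ref <- count_in(ref_seq, ese); ese_var <- count_in(var_seq, ese)
  ess_ref <- count_in(ref_seq, ess); ess_var <- count_in(var_seq, ess)
  ratio_pair <- list(
    reference = if (ess_ref > 0) ese_ref / ess_ref else
      if (ese_ref > 0) Inf else NA_real_,
    variant = if (ess_var > 0) ese_var / ess_var else
      if (ese_var > 0) Inf else NA_real_)

  matrix_hits <- lapply(matrices, function(mm) {
    hr <- scan_motif(ref_seq, mm)
    hv <- scan_motif(var_seq, mm)
    ov <- function(h) h[vapply(h, function(s)
      any(v$pos >= s & v$pos <= s + mm$width - 1L), logical(1))]
    hr <- ov(hr); hv <- ov(hv)
    list(name = mm$name, ref_hits = hr, var_hits = hv,
         gained = setdiff(hv, hr), lost = setdiff(hr, hv),
         delta = length(hv) - length(hr))
  })

  structure(list(
    variants = v,
    windows = starts,
    ese = list(reference = ese_ref, variant = ese_var,
               delta = ese_var - ese_ref),
    ess = list(reference = ess_ref, variant = ess_var,
               delta = ess_var - ess_ref),
    ratio = ratio_pair,
    matrices = matrix_hits), class = "delta_profile")
}

normalise_variants <- function(variants, construct) {
  if (inherits(variants, "cnomen")) variants <- list(variants)
  if (is.data.frame(variants)) {
    stopifnot(all(c("pos", "ref", "alt") %in% names(variants)))
    return(data.frame(pos = as.integer(variants$pos),
                      ref = toupper(variants$ref),
                      alt = toupper(variants$alt),
                      stringsAsFactors = FALSE))
  }
  if (is.list(variants) && all(vapply(variants, inherits, TRUE, "cnomen"))) {
    if (is.null(construct))
      stop("a 'construct' is required to map cnomen variants to the sequence")
    return(data.frame(
      pos = vapply(variants, construct_position, 1L, construct = construct),
      ref = vapply(variants, function(p) p$ref, ""),
      alt = vapply(variants, function(p) p$alt, ""),
      stringsAsFactors = FALSE))
  }
  stop("unsupported 'variants' specification")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat("motif delta profile over", length(x$windows), "hexamer windows\n")
  cat(sprintf("  ESE: ref %d, var %d, delta %+d\n",
              x$ese$reference, x$ese$variant, x$ese$delta))
  cat(sprintf("  ESS: ref %d, var %d, delta %+d\n",
              x$ess$reference, x$ess$variant, x$ess$delta))
  cat("  ESE/ESS ratio: ref ", format(x$ratio$reference), ", var ",
      format(x$ratio$variant), "\n", sep = "")
  for (m in x$matrices)
    cat(sprintf("  matrix %s: delta %+d (gained %d, lost %d)\n",
                m$name, m$delta, length(m$gained), length(m$lost)))
  invisible(x)
}

#' Write a delta profile as JSON
#' @param profile A `delta_profile`.
#' @param path Output file.
#' @export
write_delta_profile <- function(profile, path) {
  stopifnot(inherits(profile, "delta_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
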