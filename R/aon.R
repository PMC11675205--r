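# Antisense oligonucleotide candidate evaluation: sequence properties,
# complementarity to the target window, and overlap annotations.

#' Create an AON candidate
#'
#' @param id Candidate identifier.
#' @param seq DNA sequence (ACGT; the oligonucleotide as ordered 5'->3').
#' @param target_start Optional intended 1-based start of the target window
#'   on the construct pre-mRNA.
#' @param chemistry Free-text chemistry label (metadata only), e.g.
#'   `"2'-MOE-PTO"`.
#' @return An object of class `aon_candidate`.
#' @export
aon_candidate <- function(id, seq, target_start = NA_integer_,
                          chemistry = NA_character_) {
  seq <- toupper(seq)
  if (nchar(seq) < 1L || grepl("[^ACGT]", seq))
    stop("AON sequence must be a non-empty ACGT string")
  structure(list(id = id, seq = seq,
                 target_start = as.integer(target_start),
                 chemistry = chemistry),
            class = "aon_candidate")
}

#' Read AON candidates from FASTA
#' @param path FASTA file; record names become candidate ids.
#' @return List of `aon_candidate` objects.
#' @export
read_aon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i)
    aon_candidate(names(ss)[i], as.character(ss[[i]])))
}

#' GC content of a sequence, in percent (1 decimal)
#' @param seq ACGT string.
#' @return `100 * (#G + #C) / length`, rounded to 1 decimal.
#' @examples
#' gc_percent("ACAAGCTGCAGTAGCAGCAGG")  # 57.1
#' @export
gc_percent <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 1L || grepl("[^ACGT]", seq))
    stop("sequence must be a non-empty ACGT string")
  chars <- strsplit(seq, "")[[1]]
  round(100 * sum(chars %in% c("G", "C")) / length(chars), 1)
}

# Allawi & SantaLucia (1997) unified nearest-neighbour parameters,
# dH in kcal/mol, dS in cal/(mol K)
nn_params <- function() {
  dinuc <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  dH <- c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0)
  dS <- c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4, -19.9)
  names(dH) <- names(dS) <- dinuc
  # complete the 16-entry table via reverse complements
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T")) {
    d <- paste0(a, b)
    if (!d %in% names(dH)) {
      dH[d] <- dH[rc(d)]
      dS[d] <- dS[rc(d)]
    }
  }
  list(dH = dH, dS = dS)
}

#' Theoretical melting temperature of an oligonucleotide
#'
#' Three standard models are offered:
#' * `wallace`: Tm = 2(A+T) + 4(G+C) (short oligos, rule of thumb);
#' * `basic_gc`: Tm = 64.9 + 41 (GC - 16.4) / length;
#' * `nearest_neighbor`: unified nearest-neighbour thermodynamics
#'   (Allawi-SantaLucia DNA parameters) with entropic salt correction
#'   dS += 0.368 (N-1) ln([Na+]) and Tm = 1000 dH / (dS + R ln(C_T/4)) -
#'   273.15, where C_T/4 is approximated by `dnac1 - dnac2/2`.
#'
#' @param seq ACGT string.
#' @param method One of `"wallace"`, `"basic_gc"`, `"nearest_neighbor"`.
#' @param Na Sodium concentration in mM (nearest-neighbour only).
#' @param dnac1,dnac2 Strand concentrations in nM (nearest-neighbour only).
#' @return Temperature in degrees Celsius, with attribute `method`.
#' @export
melting_temperature <- function(seq,
                                method = c("wallace", "basic_gc",
                                           "nearest_neighbor"),
                                Na = 50, dnac1 = 25, dnac2 = 25) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (nchar(seq) < 1L || grepl("[^ACGT]", seq))
    stop("sequence must be a non-empty ACGT string")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  gc <- sum(chars %in% c("G", "C"))
  tm <- switch(method,
    wallace = 2 * (n - gc) + 4 * gc,
    basic_gc = 64.9 + 41 * (gc - 16.4) / n,
    nearest_neighbor = {
      p <- nn_params()
      din <- paste0(chars[-n], chars[-1])
      dH <- sum(p$dH[din])
      dS <- sum(p$dS[din])
      for (term in chars[c(1L, n)]) {
        if (term %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
        else { dH <- dH + 0.1; dS <- dS - 2.8 }
      }
      dS <- dS + 0.368 * (n - 1) * log(Na * 1e-3)
      k <- (dnac1 - dnac2 / 2) * 1e-9
      1000 * dH / (dS + 1.987 * log(k)) - 273.15
    })
  structure(tm, method = method)
}

#' Check AON binding to its target window
#'
#' The verdict is `TRUE` iff the reverse complement of the AON equals the
#' target window (the AON is antisense to the pre-mRNA). Overlap
#' annotations list any variant positions and registry splice sites covered
#' by the window.
#'
#' @param aon An `aon_candidate`.
#' @param target_seq Construct pre-mRNA sequence (or any reference the
#'   coordinates refer to).
#' @param target_start 1-based start of the target window on `target_seq`
#'   (defaults to the candidate's `target_start`).
#' @param registry Optional `site_registry` for splice-site annotations.
#' @param variants Optional variants (`cnomen` list or `data.frame` with
#'   `pos`; see [variant_motif_delta()]); `construct` is required to map
#'   `cnomen` variants and to place insert coordinates on the pre-mRNA.
#' @param construct Optional `minigene_construct`.
#' @return List with `complementary` (logical), `window` (start/end),
#'   and `annotations` (character vector).
#' @export
check_binding <- function(aon, target_seq, target_start = NULL,
                          registry = NULL, variants = NULL,
                          construct = NULL) {
  stopifnot(inherits(aon, "aon_candidate"))
  if (is.null(target_start)) target_start <- aon$target_start
  if (is.na(target_start)) stop("target_start is required")
  len <- nchar(aon$seq)
  end <- target_start + len - 1L
  if (target_start < 1L || end > nchar(target_seq))
    stop("AON (", len, " nt at ", target_start,
         ") extends beyond the target region")
  window <- toupper(substr(target_seq, target_start, end))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(aon$seq)))
  ann <- character(0)
  if (!is.null(variants)) {
    if (inherits(variants, "cnomen")) variants <- list(variants)
    v <- normalise_variants(variants, construct)
    if (is.data.frame(variants)) {
      # positions given directly on target_seq coordinates
      vpos <- v$pos
      vlab <- as.character(v$pos)
    } else {
      vpos <- v$pos + if (!is.null(construct)) insert_offset(construct) else 0L
      vlab <- vapply(variants, format, "")
    }
    hit <- vpos >= target_start & vpos <= end
    ann <- c(ann, paste("covers", vlab[hit]))
  }
  if (!is.null(registry)) {
    s <- registry$sites
    hit <- s$pos >= target_start & s$pos <= end
    if (any(hit)) {
      lab <- s[hit, , drop = FALSE]
      site_lab <- vapply(seq_len(nrow(lab)), function(i) {
        p <- lab$pos[i]
        cn <- if (!is.null(construct) &&
                  p > insert_offset(construct) &&
                  p <= insert_offset(construct) + construct$insert_length)
          format(construct_to_cnomen(p - insert_offset(construct), construct))
        else as.character(p)
        paste0("covers ", lab$kind[i], " ", cn)
      }, "")
      ann <- c(ann, site_lab)
    }
  }
  list(complementary = identical(rc, window),
       window = c(start = target_start, end = end),
       annotations = ann)
}

#' Evaluate an AON candidate
#'
#' @param aon An `aon_candidate`.
#' @param tm_method Melting-temperature model (see
#'   [melting_temperature()]).
#' @param ... Further arguments passed to [check_binding()] when a target
#'   sequence is supplied via `target_seq`.
#' @param target_seq Optional target sequence for the binding check.
#' @return An `aon_report` list: `length`, `gc` (percent, 1 decimal),
#'   `tm` (degrees C) with its method, binding results (if requested) and
#'   guideline flags.
#' @export
aon_report <- function(aon, tm_method = "nearest_neighbor",
                       target_seq = NULL, ...) {
  stopifnot(inherits(aon, "aon_candidate"))
  tm <- melting_temperature(aon$seq, tm_method)
  rep <- structure(list(id = aon$id, seq = aon$seq,
                        length = nchar(aon$seq),
                        gc = gc_percent(aon$seq),
                        tm = as.numeric(tm),
                        tm_method = attr(tm, "method"),
                        chemistry = aon$chemistry,
                        binding = NULL),
                   class = "aon_report")
  if (!is.null(target_seq))
    rep$binding <- check_binding(aon, target_seq, ...)
  rep$flags <- guideline_flags(rep)
  rep
}

#' Guideline flags for an AON report
#'
#' Default policy encodes common AON design ranges: length within
#' `[18, 25]` nt and GC content within `[40, 60]` percent.
#'
#' @param report An `aon_report`.
#' @param length_range,gc_range Two-element numeric ranges.
#' @return Named character vector of `"pass"` / `"warn"` flags.
#' @export
guideline_flags <- function(report, length_range = c(18, 25),
                            gc_range = c(40, 60)) {
  c(length = if (report$length >= length_range[1] &&
                 report$length <= length_range[2]) "pass" else "warn",
    gc = if (report$gc >= gc_range[1] && report$gc <= gc_range[2])
      "pass" else "warn")
}

#' @export
print.aon_report <- function(x, ...) {
  cat(sprintf("%s: %d bp, GC %.1f%%, Tm %.1f C (%s)\n", x$id, x$length,
              x$gc, x$tm, x$tm_method))
  if (!is.null(x$binding)) {
    cat("  complementary:", x$binding$complementary, "\n")
    for (a in x$binding$annotations) cat("  ", a, "\n")
  }
  cat("  flags:", paste(names(x$flags), x$flags, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}
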