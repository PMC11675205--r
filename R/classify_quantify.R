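# Junction correction against the site registry, chain classification
# against a transcript catalog, quantification, and condition comparison.

#' Junction correction policy
#'
#' Each raw junction endpoint is snapped to a registry site of the matching
#' kind within `window` bp. Candidates are ranked by: membership in a
#' catalog junction (when a catalog is supplied), then smaller shift, then
#' higher site score, then the more upstream position. Ranking the shift
#' before the score guarantees that correction is idempotent: an endpoint
#' already sitting on the preferred site class never moves again.
#'
#' @param window Maximum snap distance in bp (default 10).
#' @return An object of class `correction_policy`.
#' @export
correction_policy <- function(window = 10L) {
  window <- as.integer(window)
  if (is.na(window) || window < 0L) stop("window must be >= 0")
  structure(list(window = window), class = "correction_policy")
}

# snap a vector of endpoint positions to sites; returns snapped pos (NA if
# no candidate within window) and the applied shift
snap_positions <- function(pos, sites, window, catalog_pos = integer(0)) {
  n <- length(pos)
  if (n == 0L)
    return(list(snapped = integer(0), shift = integer(0)))
  if (nrow(sites) == 0L)
    return(list(snapped = rep(NA_integer_, n), shift = rep(NA_integer_, n)))
  sp <- sites$pos
  sc <- ifelse(is.na(sites$score), 0, sites$score)
  in_cat <- sp %in% catalog_pos
  # composite penalty; lower is better; ordering:
  # catalog membership >> |shift| >> score >> upstream position
  D <- outer(pos, sp, "-")
  A <- abs(D)
  P <- t(t(A * 1e4) + (!in_cat) * 1e9 + (100 - sc) * 10 + sp * 1e-6)
  P[A > window] <- Inf
  best <- max.col(-P, ties.method = "first")
  hit <- P[cbind(seq_len(n), best)] < Inf
  snapped <- ifelse(hit, sp[best], NA_integer_)
  list(snapped = as.integer(snapped),
       shift = as.integer(snapped - pos))
}

#' Correct junction chains against a splice-site registry
#'
#' Snaps every donor endpoint to the nearest acceptable registry donor and
#' every acceptor endpoint to the nearest acceptable registry acceptor,
#' within the policy window. A chain with any endpoint lacking a candidate
#' within the window is flagged uncorrectable (a value, not an error).
#'
#' @param chains A `junction_chains` object (see
#'   [extract_junction_chains()]).
#' @param registry A `site_registry`.
#' @param policy A [correction_policy()].
#' @param catalog Optional `transcript_catalog`; its canonical junction
#'   endpoints are preferred snap targets.
#' @return The `junction_chains` object with corrected junction columns
#'   (`donor_c`, `acceptor_c`, `shift_donor`, `shift_acceptor`) and a
#'   `reads$correctable` flag added.
#' @export
correct_chains <- function(chains, registry, policy = correction_policy(),
                           catalog = NULL) {
  stopifnot(inherits(chains, "junction_chains"),
            inherits(registry, "site_registry"),
            inherits(policy, "correction_policy"))
  cat_d <- integer(0); cat_a <- integer(0)
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "transcript_catalog"))
    cat_d <- unique(unlist(lapply(catalog$chains, `[[`, "donor")))
    cat_a <- unique(unlist(lapply(catalog$chains, `[[`, "acceptor")))
  }
  j <- chains$junctions
  don <- snap_positions(j$donor, registry_sites(registry, "donor"),
                        policy$window, cat_d)
  acc <- snap_positions(j$acceptor, registry_sites(registry, "acceptor"),
                        policy$window, cat_a)
  j$donor_c <- don$snapped
  j$acceptor_c <- acc$snapped
  j$shift_donor <- don$shift
  j$shift_acceptor <- acc$shift
  chains$junctions <- j
  ok_j <- !is.na(j$donor_c) & !is.na(j$acceptor_c)
  bad_reads <- unique(j$read[!ok_j])
  chains$reads$correctable <- !(seq_len(nrow(chains$reads)) %in% bad_reads)
  chains
}

chain_signature <- function(donor, acceptor) {
  paste(paste0(donor, ":", acceptor), collapse = "|")
}

#' Build a transcript catalog
#'
#' Maps each transcript model to its canonical junction chain and an event
#' tag set (`"WT"` for the backbone-only transcript, otherwise the names of
#' its pseudoexons). Canonical chains must be distinct.
#'
#' @param models Named list of `transcript_model` objects.
#' @param construct The `minigene_construct` the models were built on.
#' @return An object of class `transcript_catalog`.
#' @export
transcript_catalog <- function(models, construct) {
  stopifnot(length(models) > 0L,
            all(vapply(models, inherits, TRUE, "transcript_model")))
  ids <- vapply(models, `[[`, "", "id")
  names(models) <- ids
  chains <- lapply(models, canonical_chain)
  sigs <- vapply(chains, function(ch) chain_signature(ch$donor, ch$acceptor),
                 "")
  if (anyDuplicated(sigs))
    stop("canonical junction chains are not distinct")
  tags <- lapply(models, function(m) {
    pe <- m$segments$name[m$segments$kind == "pseudoexon"]
    if (length(pe)) pe else "WT"
  })
  structure(list(models = models, chains = chains, signatures = sigs,
                 tags = tags, construct_name = construct$name),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("transcript catalog (", length(x$models), " transcripts) on '",
      x$construct_name, "'\n", sep = "")
  for (id in names(x$models))
    cat(sprintf("  %s: %d bp, tags [%s], chain %s\n", id,
                transcript_length(x$models[[id]]),
                paste(x$tags[[id]], collapse = "+"),
                x$signatures[[id]]))
  invisible(x)
}

#' Classify corrected chains against a transcript catalog
#'
#' A QC-passing read is assigned the transcript whose canonical junction
#' chain exactly equals its corrected chain; uncorrectable and unmatched
#' chains are labelled `"other"`. Reads failing QC are excluded.
#'
#' @param chains A corrected, QC-filtered `junction_chains` object.
#' @param catalog A `transcript_catalog`.
#' @return `data.frame` of QC-passing reads with a `label` column.
#' @export
classify_chains <- function(chains, catalog) {
  stopifnot(inherits(chains, "junction_chains"),
            inherits(catalog, "transcript_catalog"))
  r <- chains$reads
  if (is.null(r$qc_pass))
    stop("chains must be QC-filtered first (see qc_filter)")
  if (is.null(r$correctable))
    stop("chains must be corrected first (see correct_chains)")
  j <- chains$junctions
  sig <- rep("", nrow(r))
  ok <- !is.na(j$donor_c) & !is.na(j$acceptor_c)
  if (nrow(j) && any(ok)) {
    parts <- split(paste0(j$donor_c[ok], ":", j$acceptor_c[ok]), j$read[ok])
    sig[as.integer(names(parts))] <-
      vapply(parts, paste, "", collapse = "|")
  }
  label <- names(catalog$signatures)[match(sig, catalog$signatures)]
  label[is.na(label) | !r$correctable] <- "other"
  out <- r[r$qc_pass, , drop = FALSE]
  out$label <- label[r$qc_pass]
  rownames(out) <- NULL
  out
}

#' Quantify relative transcript abundances
#'
#' Relative abundance is the percentage of ALL QC-passing reads assigned to
#' each transcript; unclassified (`"other"`) reads stay in the denominator.
#'
#' @param classified `data.frame` from [classify_chains()] (needs a `label`
#'   column), or a character vector of labels.
#' @param catalog A `transcript_catalog`.
#' @return A `quant_table`: `data.frame` with columns `transcript_id`,
#'   `count`, `abundance` (percent), one row per catalog transcript plus
#'   `"other"`.
#' @export
quantify <- function(classified, catalog) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  labels <- if (is.data.frame(classified)) classified$label else classified
  if (length(labels) == 0L)
    stop("no QC-passing reads to quantify")
  ids <- c(names(catalog$models), "other")
  unknown <- setdiff(unique(labels), ids)
  if (length(unknown))
    stop("labels outside the catalog: ", paste(unknown, collapse = ", "))
  counts <- table(factor(labels, levels = ids))
  out <- data.frame(transcript_id = ids,
                    count = as.integer(counts),
                    abundance = 100 * as.integer(counts) / length(labels),
                    stringsAsFactors = FALSE)
  structure(out, class = c("quant_table", "data.frame"),
            catalog_ids = names(catalog$models))
}

#' Assemble a quant table from known abundances
#'
#' Useful for entering published relative-abundance columns for comparison.
#'
#' @param transcript_id Character vector of transcript ids.
#' @param abundance Percent abundances (same length).
#' @param count Optional read counts.
#' @return A `quant_table`.
#' @export
quant_table <- function(transcript_id, abundance, count = NA_integer_) {
  stopifnot(length(transcript_id) == length(abundance))
  out <- data.frame(transcript_id = as.character(transcript_id),
                    count = as.integer(count),
                    abundance = as.numeric(abundance),
                    stringsAsFactors = FALSE)
  structure(out, class = c("quant_table", "data.frame"),
            catalog_ids = setdiff(out$transcript_id, "other"))
}

#' @export
print.quant_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$abundance <- round(y$abundance, 2)  # rounding in reports only
  print(y)
  invisible(x)
}

#' Compare two quant tables (condition B minus condition A)
#'
#' @param a,b `quant_table` objects over the same catalog. Transcripts
#'   absent from one table are treated as 0%.
#' @return `data.frame` with columns `transcript_id`, `abundance_a`,
#'   `abundance_b`, `delta` (`b - a`).
#' @export
compare_quant <- function(a, b) {
  stopifnot(inherits(a, "quant_table"), inherits(b, "quant_table"))
  ca <- attr(a, "catalog_ids"); cb <- attr(b, "catalog_ids")
  if (!setequal(ca, cb))
    stop("quant tables come from different catalogs")
  ids <- union(a$transcript_id, b$transcript_id)
  va <- a$abundance[match(ids, a$transcript_id)]
  vb <- b$abundance[match(ids, b$transcript_id)]
  va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
  data.frame(transcript_id = ids, abundance_a = va, abundance_b = vb,
             delta = vb - va, stringsAsFactors = FALSE)
}

#' Summed abundance of transcripts carrying an event tag
#'
#' @param qt A `quant_table`.
#' @param catalog The `transcript_catalog` the table was computed against.
#' @param tag Event tag to match (e.g. a pseudoexon name, or `"WT"`); a
#'   transcript contributes if the tag is among its tags.
#' @return Numeric summed percent.
#' @export
group_abundance <- function(qt, catalog, tag) {
  stopifnot(inherits(qt, "quant_table"),
            inherits(catalog, "transcript_catalog"))
  known <- unique(unlist(catalog$tags))
  if (!tag %in% known)
    stop("unknown event tag '", tag, "'; known tags: ",
         paste(known, collapse = ", "))
  hit <- names(catalog$tags)[vapply(catalog$tags, function(tt) tag %in% tt,
                                    TRUE)]
  sum(qt$abundance[qt$transcript_id %in% hit])
}

#' Read / write a quant table as TSV
#'
#' Abundances are written at full precision; rounding is a display concern.
#'
#' @param qt A `quant_table`.
#' @param path File path.
#' @return `read_quant_table` returns a `quant_table`.
#' @export
write_quant_table <- function(qt, path) {
  utils::write.table(as.data.frame(qt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "abundance") %in% names(df)))
  quant_table(df$transcript_id, df$abundance,
              if ("count" %in% names(df)) df$count else NA_integer_)
}
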