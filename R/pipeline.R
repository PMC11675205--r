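# End-to-end orchestration: config-driven quantification and comparison
# runs with machine-readable reports.

#' Validate and normalise a run configuration
#'
#' A run configuration (a named list, or a YAML file path) carries input
#' paths and policy parameters:
#' * `alignments`: SAM/BAM path;
#' * `construct`: construct YAML path (see [load_construct()]) or a
#'   `minigene_construct`;
#' * `pseudoexons`: list of `{name, start, end}` (c. strings) defining
#'   candidate pseudoexons;
#' * `transcripts`: list of `{id, pseudoexons, effect}` defining the
#'   catalog (a transcript with no pseudoexons is the backbone);
#' * `sites`: optional TSV with extra registry sites (`kind`, `pos`,
#'   optional `score`);
#' * parameters `window`, `min_skip`, `promote_deletion_ge`, `min_mapq`,
#'   `min_terminal_flank`, each defaulting to the package defaults.
#'
#' @param config Named list or YAML path.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  errs <- character(0)
  if (is.null(config$alignments))
    errs <- c(errs, "missing 'alignments'")
  else if (!file.exists(config$alignments))
    errs <- c(errs, paste0("alignments file not found: ", config$alignments))
  if (is.null(config$construct))
    errs <- c(errs, "missing 'construct'")
  else if (is.character(config$construct) && !file.exists(config$construct))
    errs <- c(errs, paste0("construct file not found: ", config$construct))
  if (!is.null(config$sites) && is.character(config$sites) &&
      !file.exists(config$sites))
    errs <- c(errs, paste0("sites file not found: ", config$sites))
  if (length(errs))
    stop("invalid run config:\n  ", paste(errs, collapse = "\n  "))
  defaults <- list(window = 10L, min_skip = 30L, promote_deletion_ge = 30L,
                   min_mapq = 10L, min_terminal_flank = 20L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  structure(config, class = "run_config")
}

config_catalog <- function(config, construct) {
  pes <- lapply(config$pseudoexons, function(pe)
    list(name = pe$name, span = list(parse_cnomen(pe$start),
                                     parse_cnomen(pe$end))))
  names(pes) <- vapply(pes, `[[`, "", "name")
  models <- lapply(config$transcripts, function(tr)
    transcript_model(tr$id, construct, pes[unlist(tr$pseudoexons)],
                     effect = if (is.null(tr$effect)) "" else tr$effect))
  transcript_catalog(models, construct)
}

#' Run the quantification pipeline from a configuration
#'
#' Reads the alignments, extracts and QC-filters junction chains, corrects
#' them against the registry, classifies against the catalog and
#' quantifies relative abundances. Deterministic given its inputs.
#'
#' @param config A [run_config()] (list or YAML path).
#' @param out_dir Optional output directory; if given, writes
#'   `quant_table.tsv` and `run_report.json`.
#' @return List with `quant` (the `quant_table`), `classified` (per-read
#'   labels) and `report` (parameters, QC counters, correction stats,
#'   input checksums).
#' @export
run_quantify <- function(config, out_dir = NULL) {
  config <- run_config(config)
  construct <- if (inherits(config$construct, "minigene_construct"))
    config$construct else load_construct(config$construct)
  catalog <- config_catalog(config, construct)
  user_sites <- NULL
  if (!is.null(config$sites))
    user_sites <- utils::read.delim(config$sites, stringsAsFactors = FALSE)
  # catalog junction endpoints are always candidate snap targets
  chain_df <- do.call(rbind, catalog$chains)
  cat_sites <- rbind(
    data.frame(kind = "donor", pos = unique(chain_df$donor),
               score = NA_real_),
    data.frame(kind = "acceptor", pos = unique(chain_df$acceptor),
               score = NA_real_))
  if (!is.null(user_sites)) {
    if (!"score" %in% names(user_sites)) user_sites$score <- NA_real_
    cat_sites <- rbind(user_sites[, c("kind", "pos", "score")], cat_sites)
  }
  user_sites <- cat_sites
  registry <- build_registry(construct, user_sites = user_sites)

  aln <- read_alignments(config$alignments)
  chains <- extract_junction_chains(aln, min_skip = config$min_skip,
                                    promote_deletion_ge =
                                      config$promote_deletion_ge)
  chains <- qc_filter(chains, construct, min_mapq = config$min_mapq,
                      min_terminal_flank = config$min_terminal_flank)
  chains <- correct_chains(chains, registry,
                           correction_policy(config$window), catalog)
  classified <- classify_chains(chains, catalog)
  quant <- quantify(classified, catalog)

  j <- chains$junctions
  report <- list(
    package_version = as.character(utils::packageVersion("minisplice")),
    parameters = config[c("window", "min_skip", "promote_deletion_ge",
                          "min_mapq", "min_terminal_flank")],
    inputs = list(alignments = unname(tools::md5sum(config$alignments))),
    records = as.list(chains$counters),
    qc = list(passed = sum(chains$reads$qc_pass),
              failed = sum(!chains$reads$qc_pass),
              reasons = as.list(table(
                chains$reads$qc_reason[!chains$reads$qc_pass]))),
    correction = list(
      junctions = nrow(j),
      snapped = sum(!is.na(j$donor_c) & !is.na(j$acceptor_c)),
      uncorrectable_reads = sum(!chains$reads$correctable),
      mean_abs_shift = if (nrow(j)) mean(abs(c(j$shift_donor,
                                               j$shift_acceptor)),
                                         na.rm = TRUE) else NA_real_))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_quant_table(quant, file.path(out_dir, "quant_table.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(quant = quant, classified = classified, report = report)
}

#' Compare two quantification tables
#'
#' @param table_a,table_b `quant_table` objects or TSV paths written by
#'   [write_quant_table()] (condition A = reference, B = variant/treated).
#' @param out Optional TSV path for the comparison (with the delta column).
#' @return The comparison `data.frame` from [compare_quant()].
#' @export
run_compare <- function(table_a, table_b, out = NULL) {
  a <- if (is.character(table_a)) read_quant_table(table_a) else table_a
  b <- if (is.character(table_b)) read_quant_table(table_b) else table_b
  cmp <- compare_quant(a, b)
  if (!is.null(out))
    utils::write.table(cmp, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cmp
}
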