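#' Pipeline run configuration
#'
#' @param source_path,target_path FASTA paths for the source (e.g. IPI) and
#'   target (e.g. UniProtKB complete proteome) databases.
#' @param source_dialect,target_dialect Header dialects (see [read_fasta()]).
#' @param missed_cleavages Missed cleavages for the headline digest
#'   (default 0).
#' @param min_peptide_length Optional length bound for the headline digest;
#'   the headline search-space comparison is conventionally unfiltered
#'   (`NULL`).
#' @param detect_min_length Detectability bound: a peptide counts towards
#'   remaining detectable sequence only when at least this long (default 7).
#' @param evidence_min_length Length filter applied to lost peptides before
#'   evidence lookup (default 7: peptides of six or fewer residues are
#'   removed).
#' @param evidence_paths Optional named list of evidence TSV paths
#'   (`peptideatlas`, `gpmdb`, `pride`); when `NULL` the evidence stage is
#'   skipped.
#' @param pride_min_experiments PRIDE inclusion threshold (default 5).
#' @param xref_keys Cross-reference namespaces used by logical mapping.
#' @param out_dir Output directory for the report bundle (created if
#'   missing).
#' @return A `run_config` object.
#' @export
run_config <- function(source_path, target_path,
                       source_dialect = "ipi", target_dialect = "uniprot",
                       missed_cleavages = 0L, min_peptide_length = NULL,
                       detect_min_length = 7L, evidence_min_length = 7L,
                       evidence_paths = NULL, pride_min_experiments = 5L,
                       xref_keys = c("SWISS-PROT", "TREMBL"),
                       out_dir = ".") {
  for (p in c(source_path, target_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (!is.null(evidence_paths)) {
    stopifnot(is.list(evidence_paths),
              all(names(evidence_paths) %in% c("peptideatlas", "gpmdb", "pride")))
    for (p in unlist(evidence_paths)) {
      if (!file.exists(p)) stop("evidence table not found: ", p, call. = FALSE)
    }
  }
  structure(list(source_path = source_path, target_path = target_path,
                 source_dialect = source_dialect, target_dialect = target_dialect,
                 missed_cleavages = as.integer(missed_cleavages),
                 min_peptide_length = min_peptide_length,
                 detect_min_length = as.integer(detect_min_length),
                 evidence_min_length = as.integer(evidence_min_length),
                 evidence_paths = evidence_paths,
                 pride_min_experiments = as.integer(pride_min_experiments),
                 xref_keys = xref_keys, out_dir = out_dir),
            class = "run_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full database-transition analysis
#'
#' Chains every stage: read both databases, map source identifiers onto the
#' target by cross-references and by exact sequence identity, digest both
#' databases, compare the distinct search spaces, compute the detectability
#' report for proteins affected by lost peptides and — when evidence tables
#' are supplied — the evidence Venn partition and inclusion candidates.
#' Writes a deterministic TSV report bundle to `config$out_dir`:
#' `mapping_summary.tsv`, `search_space.tsv`, `detectability.tsv`
#' (+ `venn.tsv`, `inclusion_candidates.tsv` with evidence) and a
#' `summary.tsv` echoing every headline statistic. Re-running with identical
#' inputs yields byte-identical files.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with all intermediate results (`source`,
#'   `target`, `mapping`, `comparison`, `detectability`, `evidence`,
#'   `summary`, `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- if (quiet) function(...) invisible() else pipeline_log
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_("read", "source %s (%s dialect)", config$source_path, config$source_dialect)
  source <- read_fasta(config$source_path, config$source_dialect)
  log_("read", "%d source records", db_size(source))
  target <- read_fasta(config$target_path, config$target_dialect)
  log_("read", "%d target records", db_size(target))

  log_("mapping", "logical + sequence classification")
  out_log <- map_database(source, target, "logical", xref_keys = config$xref_keys)
  out_seq <- map_database(source, target, "sequence")
  mapping_summary <- dplyr::bind_rows(summarize_mapping(out_log),
                                      summarize_mapping(out_seq))

  params <- digestion_params(missed_cleavages = config$missed_cleavages,
                             min_length = config$min_peptide_length)
  log_("digestion", "tryptic digest (mc=%d)", config$missed_cleavages)
  src_digest <- digest_database(source, params)
  tgt_digest <- digest_database(target, params)
  log_("digestion", "source %d/%d, target %d/%d (total/distinct)",
       src_digest$total_count, length(src_digest$distinct),
       tgt_digest$total_count, length(tgt_digest$distinct))

  comparison <- compare_search_space(src_digest, tgt_digest)
  log_("search_space", "%d lost peptides (%.1f%%)",
       length(comparison$lost), 100 * comparison$lost_fraction)

  detect_params <- digestion_params(missed_cleavages = config$missed_cleavages,
                                    min_length = config$detect_min_length)
  detect <- detectability_report(source, src_digest, tgt_digest$distinct,
                                 detect_params)
  log_("detectability", "%d affected proteins, %d not represented at all",
       detect$affected_count, detect$count_zero)

  evidence <- NULL
  lost_filtered <- filter_by_length(comparison$lost, config$evidence_min_length)
  if (!is.null(config$evidence_paths)) {
    log_("evidence", "%d of %d lost peptides pass the length filter",
         length(lost_filtered), length(comparison$lost))
    tables <- lapply(seq_along(config$evidence_paths), function(i) {
      read_evidence_table(config$evidence_paths[[i]],
                          names(config$evidence_paths)[i])
    })
    names(tables) <- names(config$evidence_paths)
    records <- annotate_evidence(lost_filtered, tables)
    venn <- venn_partition(records)
    candidates <- inclusion_candidates(
      records,
      inclusion_criteria(pride_min_experiments = config$pride_min_experiments),
      peptide_parents(src_digest))
    evidence <- list(records = records, venn = venn, candidates = candidates)
    log_("evidence", "%d inclusion candidates affecting %d proteins",
         length(candidates$peptides), length(candidates$proteins))
  }

  summary_rows <- tibble::tibble(
    metric = c("source_records", "target_records",
               "logical_mapped", "logical_multiple", "logical_none",
               "sequence_mapped", "sequence_multiple", "sequence_none",
               "source_total_peptides", "source_distinct_peptides",
               "target_total_peptides", "target_distinct_peptides",
               "source_redundancy", "target_redundancy",
               "lost_peptides", "lost_fraction",
               "affected_proteins", "proteins_le_50pct", "proteins_le_10pct",
               "proteins_not_represented",
               "lost_peptides_length_filtered", "evidence_retention_fraction"),
    value = c(db_size(source), db_size(target),
              mapping_summary$count[1:3], mapping_summary$count[4:6],
              src_digest$total_count, length(src_digest$distinct),
              tgt_digest$total_count, length(tgt_digest$distinct),
              redundancy(src_digest), redundancy(tgt_digest),
              length(comparison$lost), comparison$lost_fraction,
              detect$affected_count, detect$count_le_50pct,
              detect$count_le_10pct, detect$count_zero,
              length(lost_filtered),
              if (length(comparison$lost) > 0L)
                length(lost_filtered) / length(comparison$lost) else 1)
  )
  if (!is.null(evidence)) {
    summary_rows <- dplyr::bind_rows(summary_rows, tibble::tibble(
      metric = c("evidence_all_three", "inclusion_candidate_peptides",
                 "inclusion_affected_proteins"),
      value = c(evidence$venn$count[evidence$venn$in_peptideatlas &
                                      evidence$venn$in_gpmdb &
                                      evidence$venn$in_pride],
                length(evidence$candidates$peptides),
                length(evidence$candidates$proteins))))
  }

  files <- file.path(config$out_dir,
                     c("mapping_summary.tsv", "search_space.tsv",
                       "detectability.tsv", "summary.tsv"))
  write_tsv_report(mapping_summary, files[1L])
  write_tsv_report(tibble::tibble(
    metric = c("source_total", "source_distinct", "target_total",
               "target_distinct", "lost", "lost_fraction"),
    value = c(comparison$source_total, comparison$source_distinct_count,
              comparison$target_total, comparison$target_distinct_count,
              length(comparison$lost), comparison$lost_fraction)), files[2L])
  write_tsv_report(detect$records, files[3L])
  if (!is.null(evidence)) {
    venn_file <- file.path(config$out_dir, "venn.tsv")
    cand_file <- file.path(config$out_dir, "inclusion_candidates.tsv")
    write_tsv_report(evidence$venn[, c("region", "count")], venn_file)
    write_tsv_report(evidence$candidates$table, cand_file)
    files <- c(files[1:3], venn_file, cand_file, files[4L])
  }
  write_tsv_report(summary_rows, file.path(config$out_dir, "summary.tsv"))

  invisible(list(source = source, target = target,
                 mapping = list(logical = out_log, sequence = out_seq,
                                summary = mapping_summary),
                 source_digest = src_digest, target_digest = tgt_digest,
                 comparison = comparison, detectability = detect,
                 evidence = evidence, summary = summary_rows, files = files))
}
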