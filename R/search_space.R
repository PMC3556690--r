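#' Peptides lost in a database transition
#'
#' A lost peptide is a distinct peptide present in the source database's
#' digest but absent from the target database's digest. Both digests must use
#' identical digestion parameters.
#'
#' @param source,target `digest_summary` objects, or plain character vectors
#'   of distinct peptides (in which case no parameter check is possible).
#' @return Character vector of lost peptides (sorted).
#' @export
lost_peptides <- function(source, target) {
  if (inherits(source, "digest_summary") && inherits(target, "digest_summary")) {
    if (!params_equal(source$params, target$params)) {
      stop("digestion parameters differ between source and target digests",
           call. = FALSE)
    }
    source <- source$distinct
    target <- target$distinct
  }
  stopifnot(is.character(source), is.character(target))
  sort(setdiff(source, target))
}

#' Compare the theoretical search spaces of two digests
#'
#' @param source_summary,target_summary `digest_summary` objects built with
#'   identical [digestion_params()].
#' @return A `search_space_comparison`: list with `source_total`,
#'   `source_distinct_count`, `target_total`, `target_distinct_count`,
#'   `lost` (sorted character vector) and
#'   `lost_fraction = |lost| / source_distinct_count`.
#' @export
compare_search_space <- function(source_summary, target_summary) {
  stopifnot(inherits(source_summary, "digest_summary"),
            inherits(target_summary, "digest_summary"))
  lost <- lost_peptides(source_summary, target_summary)
  structure(
    list(source_total = source_summary$total_count,
         source_distinct_count = length(source_summary$distinct),
         target_total = target_summary$total_count,
         target_distinct_count = length(target_summary$distinct),
         lost = lost,
         lost_fraction = length(lost) / length(source_summary$distinct)),
    class = "search_space_comparison"
  )
}

#' @export
print.search_space_comparison <- function(x, ...) {
  cat(sprintf(paste0("<search_space_comparison>\n",
                     "  source: %d total, %d distinct\n",
                     "  target: %d total, %d distinct\n",
                     "  lost:   %d distinct peptides (%.1f%%)\n"),
              x$source_total, x$source_distinct_count,
              x$target_total, x$target_distinct_count,
              length(x$lost), 100 * x$lost_fraction))
  invisible(x)
}

coverage_fraction <- function(protein_length, occ, target_distinct, min_length) {
  qual <- (occ$end - occ$start + 1L) >= min_length
  hit <- qual & (occ$peptide %in% target_distinct)
  covered <- logical(protein_length)
  if (any(hit)) {
    for (j in which(hit)) covered[occ$start[j]:occ$end[j]] <- TRUE
  }
  sum(covered)
}

#' Remaining detectable sequence of one protein
#'
#' The fraction of a protein's residues covered by its digest peptides that
#' are still present in the target database's search space. Only peptides of
#' at least `detect_params$min_length` residues qualify as detectable;
#' coverage is the union of residue positions (1-based, closed intervals), so
#' overlapping peptides from missed cleavages are not double counted.
#'
#' @param record A one-row slice of a `protein_db`'s records.
#' @param occurrences The record's rows of a `digest_summary`'s
#'   `occurrences` tibble.
#' @param target_distinct Character vector of the target's distinct peptides.
#' @param detect_params [digestion_params()] carrying the detectability
#'   length bound (`min_length`; `NULL` means 1).
#' @return A tibble row: `accession`, `length`, `detectable_residues`,
#'   `fraction`.
#' @export
protein_detectability <- function(record, occurrences, target_distinct,
                                  detect_params = digestion_params(min_length = 7)) {
  acc <- record$accession[[1L]]
  if (nrow(occurrences) > 0L && !all(occurrences$accession == acc)) {
    stop("occurrences carry a foreign accession (expected '", acc, "')",
         call. = FALSE)
  }
  min_len <- if (is.null(detect_params$min_length)) 1L else detect_params$min_length
  n <- nchar(record$sequence[[1L]])
  det <- coverage_fraction(n, occurrences, target_distinct, min_len)
  tibble::tibble(accession = acc, length = n,
                 detectable_residues = det, fraction = det / n)
}

#' Detectability report over proteins affected by lost peptides
#'
#' A protein is affected when at least one of its qualifying peptides
#' (length >= the detectability bound) is absent from the target's distinct
#' set. For every affected protein the remaining detectable fraction is
#' computed; the report tallies how many affected proteins retain at most
#' 50%, at most 10%, and exactly 0% detectable sequence (the latter are not
#' represented in the target at all).
#'
#' @param db The source `protein_db`.
#' @param summary Its `digest_summary` (same database).
#' @param target_distinct Character vector of target distinct peptides.
#' @param detect_params [digestion_params()] with the detectability bound.
#' @return A `detectability_report`: list with `affected_count`,
#'   `count_le_50pct`, `count_le_10pct`, `count_zero` and a `records`
#'   tibble (one row per affected protein, database order).
#' @export
detectability_report <- function(db, summary, target_distinct,
                                 detect_params = digestion_params(min_length = 7)) {
  stopifnot(inherits(db, "protein_db"), inherits(summary, "digest_summary"))
  min_len <- if (is.null(detect_params$min_length)) 1L else detect_params$min_length

  occ <- summary$occurrences
  qual <- (occ$end - occ$start + 1L) >= min_len
  lost_occ <- qual & !(occ$peptide %in% target_distinct)
  affected <- unique(occ$accession[lost_occ])
  affected <- db$records$accession[db$records$accession %in% affected]

  occ_by_acc <- split(seq_len(nrow(occ)), occ$accession)
  rows <- lapply(affected, function(acc) {
    i <- match(acc, db$records$accession)
    protein_detectability(db$records[i, ], occ[occ_by_acc[[acc]], ],
                          target_distinct, detect_params)
  })
  records <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(accession = character(0), length = integer(0),
                   detectable_residues = integer(0), fraction = double(0))

  structure(
    list(affected_count = nrow(records),
         count_le_50pct = sum(records$fraction <= 0.5),
         count_le_10pct = sum(records$fraction <= 0.1),
         count_zero = sum(records$fraction == 0),
         records = records),
    class = "detectability_report"
  )
}

#' @export
print.detectability_report <- function(x, ...) {
  cat(sprintf(paste0("<detectability_report> %d affected proteins; ",
                     "%d at <=50%%, %d at <=10%%, %d not represented at all\n"),
              x$affected_count, x$count_le_50pct, x$count_le_10pct, x$count_zero))
  invisible(x)
}
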