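#' Build an exact-sequence index of a target database
#'
#' Identifier mapping by 100% sequence identity guarantees that a mapped
#' identifier refers to the same protein sequence. The index keys every
#' distinct target sequence to the (sorted) accessions carrying exactly that
#' sequence.
#'
#' @param target A non-empty `protein_db`.
#' @return A `sequence_index`: named list, sequence -> sorted accessions.
#' @export
build_sequence_index <- function(target) {
  stopifnot(inherits(target, "protein_db"))
  if (nrow(target$records) == 0L) stop("empty target database", call. = FALSE)
  idx <- lapply(split(target$records$accession, target$records$sequence), sort)
  structure(idx, class = "sequence_index")
}

mapping_status <- function(targets) {
  if (length(targets) == 0L) "none" else if (length(targets) == 1L) "mapped" else "multiple"
}

#' Map one record by exact sequence identity
#'
#' @param record A one-row slice of a `protein_db`'s `records` tibble (or any
#'   list with `accession` and `sequence`).
#' @param index A [build_sequence_index()] result.
#' @return A list with `source_accession`, `algorithm = "sequence"`,
#'   `status` (mapped/multiple/none) and sorted `targets`.
#' @export
sequence_map <- function(record, index) {
  stopifnot(inherits(index, "sequence_index"))
  pos <- match(record$sequence[[1L]], names(index))
  targets <- if (is.na(pos)) character(0) else index[[pos]]
  list(source_accession = record$accession[[1L]], algorithm = "sequence",
       status = mapping_status(targets), targets = targets)
}

logical_candidates <- function(xrefs, xref_keys) {
  cand <- unlist(xrefs[intersect(names(xrefs), xref_keys)], use.names = FALSE)
  if (is.null(cand)) cand <- character(0)
  # isoform suffixes (e.g. O95793-1) collapse to the parent accession, so
  # several isoforms of one entry count as a single candidate
  sort(unique(sub("-[0-9]+$", "", cand)))
}

#' Map one record by its embedded cross-references
#'
#' "Logical" mapping uses the cross-references stored on each source entry.
#' Only the UniProtKB namespaces (`SWISS-PROT`, `TREMBL`) can name a target
#' accession; Ensembl/RefSeq/Vega/H-Inv references never map. Isoform
#' suffixes are stripped before intersecting with the target accession set.
#'
#' @param record A one-row slice of a source `protein_db`'s records.
#' @param target The target `protein_db`.
#' @param xref_keys Cross-reference namespaces consulted.
#' @return A list with `source_accession`, `algorithm = "logical"`, `status`
#'   and sorted `targets`.
#' @export
logical_map <- function(record, target,
                        xref_keys = c("SWISS-PROT", "TREMBL")) {
  stopifnot(inherits(target, "protein_db"))
  cand <- logical_candidates(record$xrefs[[1L]], xref_keys)
  targets <- intersect(cand, target$records$accession)
  list(source_accession = record$accession[[1L]], algorithm = "logical",
       status = mapping_status(targets), targets = targets)
}

#' Map every source record onto the target database
#'
#' Classifies each source identifier as `mapped` (exactly one target),
#' `multiple` (one-to-many) or `none`, under the chosen algorithm.
#'
#' @param source,target `protein_db` objects.
#' @param algorithm `"logical"` (cross-reference based) or `"sequence"`
#'   (100% sequence identity).
#' @param xref_keys Namespaces consulted by the logical algorithm.
#' @return A tibble with columns `source_accession`, `algorithm`, `status`
#'   and list-column `targets` (sorted accessions), one row per source
#'   record in database order.
#' @export
map_database <- function(source, target,
                         algorithm = c("logical", "sequence"),
                         xref_keys = c("SWISS-PROT", "TREMBL")) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(source, "protein_db"), inherits(target, "protein_db"))
  if (nrow(target$records) == 0L) stop("empty target database", call. = FALSE)

  if (algorithm == "sequence") {
    index <- build_sequence_index(target)
    targets <- unname(index[source$records$sequence])
    targets <- lapply(targets, function(x) if (is.null(x)) character(0) else x)
  } else {
    targets <- lapply(source$records$xrefs, function(xr) {
      intersect(logical_candidates(xr, xref_keys), target$records$accession)
    })
  }
  tibble::tibble(
    source_accession = source$records$accession,
    algorithm = algorithm,
    status = vapply(targets, mapping_status, character(1L)),
    targets = targets
  )
}

#' Summarize mapping outcomes
#'
#' @param outcomes A [map_database()] tibble (single algorithm).
#' @return A `mapping_summary` tibble: one row per status
#'   (mapped, multiple, none) with `algorithm`, `count` and `fraction`;
#'   fractions sum to 1.
#' @export
summarize_mapping <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0L)
  if (length(unique(outcomes$algorithm)) != 1L) {
    stop("outcomes mix mapping algorithms; summarize one at a time",
         call. = FALSE)
  }
  counts <- table(factor(outcomes$status, levels = c("mapped", "multiple", "none")))
  tibble::tibble(
    algorithm = outcomes$algorithm[1L],
    status = names(counts),
    count = as.integer(counts),
    fraction = as.integer(counts) / nrow(outcomes)
  )
}

#' Flatten mapping outcomes for a TSV report
#' @param outcomes A [map_database()] tibble.
#' @return Tibble with `targets` joined by `";"`.
#' @export
flatten_outcomes <- function(outcomes) {
  tibble::tibble(
    source_accession = outcomes$source_accession,
    algorithm = outcomes$algorithm,
    status = outcomes$status,
    targets = vapply(outcomes$targets, paste, character(1L), collapse = ";")
  )
}
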