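#' Inclusion criteria for repository-backed peptides
#'
#' A lost peptide is proposed for inclusion in the target database when it is
#' reported as proteotypic by PeptideAtlas or GPMDB, or was identified in at
#' least `pride_min_experiments` distinct PRIDE experiments (default 5).
#'
#' @param accept_peptideatlas_proteotypic,accept_gpmdb_proteotypic Accept a
#'   proteotypic flag from the respective repository.
#' @param pride_min_experiments Minimum PRIDE experiment count (>= 1).
#' @return An `inclusion_criteria` object.
#' @export
inclusion_criteria <- function(accept_peptideatlas_proteotypic = TRUE,
                               accept_gpmdb_proteotypic = TRUE,
                               pride_min_experiments = 5L) {
  pride_min_experiments <- as.integer(pride_min_experiments)
  stopifnot(pride_min_experiments >= 1L)
  structure(list(accept_peptideatlas_proteotypic = isTRUE(accept_peptideatlas_proteotypic),
                 accept_gpmdb_proteotypic = isTRUE(accept_gpmdb_proteotypic),
                 pride_min_experiments = pride_min_experiments),
            class = "inclusion_criteria")
}

#' Annotate lost peptides with repository evidence
#'
#' Missing table rows mean "no evidence" (proteotypic `FALSE`, experiment
#' count 0), never an error: repository snapshots are inherently partial.
#' Input peptides must already be length-filtered (>= 7 residues), since
#' shorter peptides are not confidently identifiable.
#'
#' @param lost_filtered Character vector of lost peptides, length >= 7 each.
#' @param tables Named list with any of `peptideatlas`, `gpmdb`, `pride`
#'   `evidence_table`s (may be empty or partial).
#' @return Tibble sorted by peptide with columns `peptide`,
#'   `proteotypic_peptideatlas`, `proteotypic_gpmdb`,
#'   `pride_experiment_count`.
#' @export
annotate_evidence <- function(lost_filtered, tables = list()) {
  stopifnot(is.character(lost_filtered))
  if (any(nchar(lost_filtered) <= 6L)) {
    stop("peptides of six or fewer residues must be filtered out before ",
         "evidence annotation", call. = FALSE)
  }
  for (tab in tables) stopifnot(inherits(tab, "evidence_table"))
  pep <- sort(unique(lost_filtered))

  flag_from <- function(repo) {
    tab <- tables[[repo]]
    if (is.null(tab)) return(rep(FALSE, length(pep)))
    i <- match(pep, tab$rows$peptide)
    out <- tab$rows$proteotypic[i]
    out[is.na(i)] <- FALSE
    out
  }
  counts <- {
    tab <- tables[["pride"]]
    if (is.null(tab)) rep(0L, length(pep)) else {
      i <- match(pep, tab$rows$peptide)
      out <- tab$rows$experiment_count[i]
      out[is.na(i)] <- 0L
      out
    }
  }
  tibble::tibble(peptide = pep,
                 proteotypic_peptideatlas = flag_from("peptideatlas"),
                 proteotypic_gpmdb = flag_from("gpmdb"),
                 pride_experiment_count = counts)
}

#' Three-way Venn partition of repository evidence
#'
#' Presence means a proteotypic flag for PeptideAtlas/GPMDB and an experiment
#' count of at least `pride_presence_min` (default 1) for PRIDE; this
#' presence threshold is deliberately distinct from the inclusion threshold.
#' Every peptide falls in exactly one of the 8 regions.
#'
#' @param records An [annotate_evidence()] tibble.
#' @param pride_presence_min Minimum PRIDE experiment count that counts as
#'   presence.
#' @return Tibble of 8 rows: logical columns `in_peptideatlas`, `in_gpmdb`,
#'   `in_pride`, a `region` label, and `count`; counts sum to `nrow(records)`.
#' @export
venn_partition <- function(records, pride_presence_min = 1L) {
  stopifnot(is.data.frame(records))
  pa <- records$proteotypic_peptideatlas
  gp <- records$proteotypic_gpmdb
  pr <- records$pride_experiment_count >= pride_presence_min

  grid <- expand.grid(in_pride = c(FALSE, TRUE), in_gpmdb = c(FALSE, TRUE),
                      in_peptideatlas = c(FALSE, TRUE))
  grid <- grid[, c("in_peptideatlas", "in_gpmdb", "in_pride")]
  counts <- integer(8L)
  cell <- 1L + 4L * pa + 2L * gp + 1L * pr
  tab <- tabulate(cell, nbins = 8L)
  # grid rows are ordered pride-fastest with pa slowest: same binary order
  counts <- tab[1L + 4L * grid$in_peptideatlas + 2L * grid$in_gpmdb + grid$in_pride]
  region <- apply(grid, 1L, function(g) {
    on <- c("peptideatlas", "gpmdb", "pride")[as.logical(g)]
    if (length(on) == 0L) "none" else paste(on, collapse = "+")
  })
  tibble::tibble(in_peptideatlas = grid$in_peptideatlas,
                 in_gpmdb = grid$in_gpmdb,
                 in_pride = grid$in_pride,
                 region = region,
                 count = as.integer(counts))
}

#' Map each distinct peptide to its parent proteins
#'
#' @param summary A `digest_summary`.
#' @return Named list: peptide -> sorted unique parent accessions.
#' @export
peptide_parents <- function(summary) {
  stopifnot(inherits(summary, "digest_summary"))
  lapply(split(summary$occurrences$accession, summary$occurrences$peptide),
         function(a) sort(unique(a)))
}

#' Apply the inclusion criteria to annotated lost peptides
#'
#' @param records An [annotate_evidence()] tibble.
#' @param criteria An [inclusion_criteria()] object.
#' @param peptide_to_proteins A [peptide_parents()] map derived from the
#'   source digest.
#' @return A list with `peptides` (sorted candidate peptides), `proteins`
#'   (sorted accessions of all their parents) and a `table` tibble
#'   (`peptide`, `reason`, `proteins` `';'`-joined) for reporting.
#' @export
inclusion_candidates <- function(records, criteria = inclusion_criteria(),
                                 peptide_to_proteins) {
  stopifnot(is.data.frame(records), inherits(criteria, "inclusion_criteria"))
  pa_ok <- criteria$accept_peptideatlas_proteotypic & records$proteotypic_peptideatlas
  gp_ok <- criteria$accept_gpmdb_proteotypic & records$proteotypic_gpmdb
  pr_ok <- records$pride_experiment_count >= criteria$pride_min_experiments
  is_cand <- pa_ok | gp_ok | pr_ok

  cand <- records[is_cand, , drop = FALSE]
  reason <- mapply(function(a, g, p) {
    paste(c("peptideatlas_proteotypic", "gpmdb_proteotypic", "pride_experiments")[
      c(a, g, p)], collapse = ";")
  }, pa_ok[is_cand], gp_ok[is_cand], pr_ok[is_cand])
  reason <- as.character(reason)

  pos <- match(cand$peptide, names(peptide_to_proteins))
  if (anyNA(pos)) {
    stop("candidate peptide(s) missing from the peptide-to-protein map: ",
         paste(cand$peptide[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  parents <- peptide_to_proteins[pos]
  ord <- order(cand$peptide)
  list(
    peptides = cand$peptide[ord],
    proteins = sort(unique(unlist(parents, use.names = FALSE))),
    table = tibble::tibble(
      peptide = cand$peptide,
      reason = reason,
      proteins = vapply(parents, paste, character(1L), collapse = ";")
    )[ord, ]
  )
}
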