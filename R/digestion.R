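#' Digestion parameters
#'
#' @param enzyme Only `"trypsin"` is supported: cleavage C-terminal of K/R,
#'   suppressed when the next residue is proline (Keil rule).
#' @param missed_cleavages Maximum number of retained internal cleavage sites
#'   per peptide (non-negative; default 0).
#' @param min_length,max_length Optional inclusive peptide-length bounds,
#'   applied after fragment enumeration.
#' @return A `digestion_params` object.
#' @export
digestion_params <- function(enzyme = "trypsin", missed_cleavages = 0L,
                             min_length = NULL, max_length = NULL) {
  enzyme <- match.arg(enzyme, "trypsin")
  missed_cleavages <- as.integer(missed_cleavages)
  stopifnot(length(missed_cleavages) == 1L, missed_cleavages >= 0L)
  if (!is.null(min_length)) {
    min_length <- as.integer(min_length)
    stopifnot(min_length >= 1L)
  }
  if (!is.null(max_length)) {
    max_length <- as.integer(max_length)
    stopifnot(max_length >= 1L)
    if (!is.null(min_length) && min_length > max_length) {
      stop("min_length must be <= max_length", call. = FALSE)
    }
  }
  structure(list(enzyme = enzyme, missed_cleavages = missed_cleavages,
                 min_length = min_length, max_length = max_length),
            class = "digestion_params")
}

params_equal <- function(a, b) {
  identical(unclass(a), unclass(b))
}

#' Tryptic cleavage sites of a sequence
#'
#' A cut position `i` (1-based) means a cleavage between residues `i` and
#' `i + 1`. Trypsin cuts after K or R unless the following residue is proline
#' (Keil rule); ambiguity codes (B, J, O, U, X, Z) are never cleavage sites
#' and never suppress cleavage.
#'
#' @param sequence Non-empty uppercase amino-acid string.
#' @return Integer vector of cut positions (possibly empty).
#' @examples
#' cleavage_sites("AKRPCK") # 2: R at 3 is blocked by P, K at 6 is terminal
#' @export
cleavage_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  i[(chars[i] == "K" | chars[i] == "R") & chars[i + 1L] != "P"]
}

#' In silico tryptic digest of one sequence
#'
#' Fragments are the substrings between consecutive cleavage sites (plus the
#' termini); the result contains every concatenation of
#' `1 ... missed_cleavages + 1` consecutive fragments. Length bounds are
#' applied last. Output is ordered by start, then end.
#'
#' @param sequence Non-empty uppercase amino-acid string.
#' @param params A [digestion_params()] object.
#' @return A tibble with columns `start`, `end` (1-based, closed) and
#'   `peptide`.
#' @examples
#' digest_protein("MKWVR", digestion_params(missed_cleavages = 1))
#' @export
digest_protein <- function(sequence, params = digestion_params()) {
  stopifnot(inherits(params, "digestion_params"))
  cuts <- cleavage_sites(sequence)
  n <- nchar(sequence)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  nf <- length(starts)
  mc <- params$missed_cleavages

  out_start <- integer(0)
  out_end <- integer(0)
  for (i in seq_len(nf)) {
    kmax <- min(mc, nf - i)
    out_start <- c(out_start, rep.int(starts[i], kmax + 1L))
    out_end <- c(out_end, ends[i:(i + kmax)])
  }
  len <- out_end - out_start + 1L
  keep <- rep(TRUE, length(len))
  if (!is.null(params$min_length)) keep <- keep & len >= params$min_length
  if (!is.null(params$max_length)) keep <- keep & len <= params$max_length
  idx <- which(keep)
  tibble::tibble(start = out_start[idx], end = out_end[idx],
                 peptide = if (length(idx) > 0L)
                   substring(sequence, out_start[idx], out_end[idx])
                 else character(0))
}

#' Digest every record of a database
#'
#' @param db A `protein_db`.
#' @param params A [digestion_params()] object.
#' @return A `digest_summary`: list with `params`, `total_count` (peptide
#'   occurrences over all proteins), `distinct` (character vector of unique
#'   peptide sequences) and `occurrences` (tibble `accession`, `start`,
#'   `end`, `peptide` in database order).
#' @export
digest_database <- function(db, params = digestion_params()) {
  stopifnot(inherits(db, "protein_db"))
  if (nrow(db$records) == 0L) stop("empty database", call. = FALSE)
  per <- vector("list", nrow(db$records))
  for (i in seq_len(nrow(db$records))) {
    occ <- tryCatch(digest_protein(db$records$sequence[i], params),
                    error = function(e) {
                      stop("record '", db$records$accession[i], "': ",
                           conditionMessage(e), call. = FALSE)
                    })
    occ$accession <- db$records$accession[i]
    per[[i]] <- occ
  }
  occurrences <- dplyr::bind_rows(per)[, c("accession", "start", "end", "peptide")]
  structure(
    list(params = params,
         total_count = nrow(occurrences),
         distinct = unique(occurrences$peptide),
         occurrences = occurrences),
    class = "digest_summary"
  )
}

#' @export
print.digest_summary <- function(x, ...) {
  cat(sprintf("<digest_summary> %d peptides in total, %d distinct (%.1f%%), mc=%d\n",
              x$total_count, length(x$distinct),
              100 * length(x$distinct) / max(1L, x$total_count),
              x$params$missed_cleavages))
  invisible(x)
}

#' Peptide redundancy of a digest
#'
#' The ratio of distinct peptide sequences to total peptide occurrences, the
#' standard summary of how redundant a database's theoretical search space is.
#'
#' @param summary A `digest_summary`.
#' @return Fraction in (0, 1].
#' @export
redundancy <- function(summary) {
  stopifnot(inherits(summary, "digest_summary"))
  if (summary$total_count == 0L) stop("digest has zero peptides", call. = FALSE)
  length(summary$distinct) / summary$total_count
}

#' Keep peptides of at least a minimum length
#'
#' Peptides of six or fewer residues are conventionally dropped before
#' evidence lookup because they are too short to be confidently identified in
#' standard MS pipelines (`min_length = 7`).
#'
#' @param peptides Character vector of peptide sequences.
#' @param min_length Minimum length to keep (>= 1).
#' @return The qualifying subset, in input order.
#' @export
filter_by_length <- function(peptides, min_length) {
  min_length <- as.integer(min_length)
  stopifnot(min_length >= 1L)
  peptides[nchar(peptides) >= min_length]
}
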