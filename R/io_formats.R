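#' Parse an IPI-dialect FASTA header
#'
#' IPI headers look like
#' `IPI:IPI00000001.2|SWISS-PROT:O95793-1|ENSEMBL:ENSP00000360922 Tax_Id=9606 ...`.
#' The pipe-separated tokens before the first space carry the entry's
#' cross-references into other protein databases; `Tax_Id=` in the free-text
#' part carries the NCBI taxon. Cross-reference accessions are kept verbatim,
#' including isoform suffixes such as `O95793-1`; collapsing isoforms is the
#' mapping stage's concern.
#'
#' @param header Header string with the leading `>` already removed.
#' @return A list with elements `accession` (version-stripped), `version`
#'   (integer or `NA`), `xrefs` (named list of character vectors),
#'   `taxon` (integer or `NA`) and `description`.
#' @examples
#' h <- "IPI:IPI00000005.1|REFSEQ:NP_059347 Tax_Id=9606 GTP-binding protein"
#' parse_ipi_header(h)$xrefs
#' @export
parse_ipi_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  if (!startsWith(header, "IPI:IPI")) {
    stop("not an IPI-dialect header (missing 'IPI:' prefix): ",
         substr(header, 1L, 60L), call. = FALSE)
  }
  sp <- regexpr(" ", header, fixed = TRUE)
  if (sp == -1L) {
    idpart <- header
    rest <- ""
  } else {
    idpart <- substr(header, 1L, sp - 1L)
    rest <- substr(header, sp + 1L, nchar(header))
  }
  tokens <- strsplit(idpart, "|", fixed = TRUE)[[1L]]
  acc_full <- sub("^IPI:", "", tokens[1L])
  dot <- regexpr("\\.[0-9A-Za-z]*$", acc_full)
  if (dot == -1L) {
    accession <- acc_full
    version <- NA_integer_
  } else {
    accession <- substr(acc_full, 1L, dot - 1L)
    vtxt <- substr(acc_full, dot + 1L, nchar(acc_full))
    if (!grepl("^[0-9]+$", vtxt)) {
      stop("non-integer IPI version suffix '", vtxt, "' in header: ",
           substr(header, 1L, 60L), call. = FALSE)
    }
    version <- as.integer(vtxt)
  }

  xrefs <- list()
  for (tok in tokens[-1L]) {
    colon <- regexpr(":", tok, fixed = TRUE)
    if (colon == -1L) {
      stop("malformed cross-reference token '", tok, "' in IPI header",
           call. = FALSE)
    }
    db <- substr(tok, 1L, colon - 1L)
    accs <- strsplit(substr(tok, colon + 1L, nchar(tok)), ";", fixed = TRUE)[[1L]]
    accs <- accs[nzchar(accs)]
    xrefs[[db]] <- unique(c(xrefs[[db]], accs))
  }

  taxon <- NA_integer_
  m <- regmatches(rest, regexpr("Tax_Id=[0-9]+", rest))
  if (length(m) == 1L) {
    taxon <- as.integer(sub("Tax_Id=", "", m))
    rest <- sub("Tax_Id=[0-9]+ ?", "", rest)
  }

  list(accession = accession, version = version, xrefs = xrefs,
       taxon = taxon, description = trimws(rest))
}

#' Parse a UniProtKB-dialect FASTA header
#'
#' UniProtKB headers are `sp|ACCESSION|ENTRY_NAME Description ...` for
#' reviewed (Swiss-Prot) and `tr|...` for unreviewed (TrEMBL) entries.
#'
#' @param header Header string with the leading `>` already removed.
#' @return A list with elements `accession`, `entry_name`, `review_status`
#'   (`"reviewed"` or `"unreviewed"`) and `description`.
#' @examples
#' parse_uniprot_header("sp|P01111|RASN_HUMAN GTPase NRas OS=Homo sapiens")
#' @export
parse_uniprot_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  fields <- strsplit(header, "|", fixed = TRUE)[[1L]]
  if (length(fields) < 3L || !(fields[1L] %in% c("sp", "tr"))) {
    stop("not a UniProtKB-dialect header (expected 'sp|ACC|ID' or 'tr|ACC|ID'): ",
         substr(header, 1L, 60L), call. = FALSE)
  }
  tail_part <- paste(fields[3:length(fields)], collapse = "|")
  sp <- regexpr(" ", tail_part, fixed = TRUE)
  if (sp == -1L) {
    entry_name <- tail_part
    description <- ""
  } else {
    entry_name <- substr(tail_part, 1L, sp - 1L)
    description <- trimws(substr(tail_part, sp + 1L, nchar(tail_part)))
  }
  list(accession = fields[2L], entry_name = entry_name,
       review_status = if (fields[1L] == "sp") "reviewed" else "unreviewed",
       description = description)
}

parse_plain_header <- function(header) {
  sp <- regexpr(" ", header, fixed = TRUE)
  if (sp == -1L) {
    list(accession = header, description = "")
  } else {
    list(accession = substr(header, 1L, sp - 1L),
         description = trimws(substr(header, sp + 1L, nchar(header))))
  }
}

#' Construct a protein database in code
#'
#' Programmatic counterpart of [read_fasta()], mainly useful for small
#' hand-built databases.
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Uppercase amino-acid sequences (same length as
#'   `accession`).
#' @param xrefs Optional list (one element per record) of named lists of
#'   cross-reference accessions.
#' @param description,review_status,taxon,version,entry_name Optional
#'   per-record metadata, recycled to the record count.
#' @param name,release Database name and release label.
#' @return A `protein_db`.
#' @examples
#' db <- protein_db(c("A", "B"), c("MKWVR", "AAAA"))
#' db_size(db)
#' @export
protein_db <- function(accession, sequence, xrefs = NULL, description = "",
                       review_status = "not-applicable", taxon = NA_integer_,
                       version = NA_integer_, entry_name = NA_character_,
                       name = "in-memory", release = NA_character_) {
  n <- length(accession)
  stopifnot(length(sequence) == n)
  if (is.null(xrefs)) xrefs <- rep(list(list()), n)
  new_protein_db(
    tibble::tibble(accession = accession,
                   version = as.integer(version),
                   entry_name = entry_name,
                   description = description,
                   sequence = toupper(sequence),
                   taxon = as.integer(taxon),
                   review_status = review_status,
                   xrefs = xrefs),
    name = name, release = release
  )
}

new_protein_db <- function(records, name = NA_character_, release = NA_character_) {
  stopifnot(is.data.frame(records))
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in database: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- !grepl("^[A-Z]+$", records$sequence)
  if (any(bad)) {
    stop("record(s) with empty or non A-Z sequence: ",
         paste(records$accession[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, release = release, records = tibble::as_tibble(records)),
    class = "protein_db"
  )
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db> %s (release %s): %d records\n",
              x$name, x$release, nrow(x$records)))
  invisible(x)
}

#' Number of records in a protein database
#' @param db A `protein_db`.
#' @return Integer record count.
#' @export
db_size <- function(db) {
  stopifnot(inherits(db, "protein_db"))
  nrow(db$records)
}

#' Read a protein FASTA file into a `protein_db`
#'
#' Sequences are uppercased and trailing `*` (stop) characters are stripped at
#' read time; all downstream comparisons are exact character equality on the
#' normalised sequences. Record order is preserved.
#'
#' @param path FASTA file path.
#' @param dialect Header dialect: `"ipi"` (`IPI:IPInnnnnnnn.v|DB:acc|...`),
#'   `"uniprot"` (`sp|ACC|ID` / `tr|ACC|ID`), or `"plain"`
#'   (`>accession description`).
#' @param name,release Optional database name and release label.
#' @return A `protein_db`: a list with `name`, `release` and a `records`
#'   tibble holding `accession`, `version`, `entry_name`, `description`,
#'   `sequence`, `taxon`, `review_status` and a list-column `xrefs`.
#' @export
read_fasta <- function(path, dialect = c("ipi", "uniprot", "plain"),
                       name = basename(path), release = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)

  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(seqs)
  sequences <- unname(toupper(sub("\\*+$", "", as.character(seqs))))
  # line number of each '>' header, for parse diagnostics
  header_lines <- grep("^>", readLines(path, warn = FALSE))

  n <- length(headers)
  acc <- character(n); ver <- rep(NA_integer_, n)
  entry <- rep(NA_character_, n); desc <- character(n)
  taxon <- rep(NA_integer_, n)
  review <- rep("not-applicable", n)
  xrefs <- vector("list", n)

  for (i in seq_len(n)) {
    p <- tryCatch(
      switch(dialect,
             ipi = parse_ipi_header(headers[i]),
             uniprot = parse_uniprot_header(headers[i]),
             plain = parse_plain_header(headers[i])),
      error = function(e) {
        stop(sprintf("line %d of %s: %s",
                     header_lines[i], path, conditionMessage(e)),
             call. = FALSE)
      })
    acc[i] <- p$accession
    desc[i] <- p$description
    if (dialect == "ipi") {
      ver[i] <- p$version
      taxon[i] <- p$taxon
      xrefs[[i]] <- p$xrefs
    } else {
      xrefs[[i]] <- list()
    }
    if (dialect == "uniprot") {
      entry[i] <- p$entry_name
      review[i] <- p$review_status
    }
    if (!nzchar(sequences[i])) {
      stop("empty sequence for record '", acc[i], "' in ", path, call. = FALSE)
    }
  }

  new_protein_db(
    tibble::tibble(accession = acc, version = ver, entry_name = entry,
                   description = desc, sequence = sequences,
                   taxon = taxon, review_status = review, xrefs = xrefs),
    name = name, release = release
  )
}

ipi_header <- function(rec) {
  acc <- if (is.na(rec$version)) rec$accession else
    sprintf("%s.%d", rec$accession, rec$version)
  xr <- rec$xrefs[[1L]]
  xtok <- vapply(names(xr), function(db) {
    paste0(db, ":", paste(xr[[db]], collapse = ";"))
  }, character(1L))
  idpart <- paste(c(paste0("IPI:", acc), xtok), collapse = "|")
  tax <- if (is.na(rec$taxon)) "" else sprintf(" Tax_Id=%d", rec$taxon)
  desc <- if (nzchar(rec$description)) paste0(" ", rec$description) else ""
  paste0(idpart, tax, desc)
}

uniprot_header <- function(rec) {
  prefix <- if (identical(rec$review_status, "reviewed")) "sp" else "tr"
  entry <- if (is.na(rec$entry_name)) paste0(rec$accession, "_UNK") else rec$entry_name
  desc <- if (nzchar(rec$description)) paste0(" ", rec$description) else ""
  sprintf("%s|%s|%s%s", prefix, rec$accession, entry, desc)
}

#' Write a `protein_db` back to FASTA
#'
#' Headers are reconstructed in the requested dialect, so a database read with
#' [read_fasta()] round-trips: accessions, sequences and cross-references are
#' reproduced exactly.
#'
#' @param db A `protein_db`.
#' @param path Output path.
#' @param dialect Header dialect to emit (see [read_fasta()]).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, dialect = c("ipi", "uniprot", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(db, "protein_db"))
  headers <- vapply(seq_len(nrow(db$records)), function(i) {
    rec <- db$records[i, ]
    switch(dialect,
           ipi = ipi_header(rec),
           uniprot = uniprot_header(rec),
           plain = {
             d <- if (nzchar(rec$description)) paste0(" ", rec$description) else ""
             paste0(rec$accession, d)
           })
  }, character(1L))
  x <- Biostrings::AAStringSet(db$records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a peptide-evidence table
#'
#' Evidence tables are local snapshots of peptide-level evidence in the major
#' proteomics repositories. PeptideAtlas and GPMDB report whether a peptide is
#' proteotypic (highly representative for its parent protein and reproducibly
#' detected); PRIDE reports in how many distinct experiments a peptide was
#' identified.
#'
#' @param path TSV file with header `peptide<TAB>proteotypic`
#'   (peptideatlas/gpmdb) or `peptide<TAB>experiment_count` (pride).
#' @param repository One of `"peptideatlas"`, `"gpmdb"`, `"pride"`.
#' @return An `evidence_table`: list with `repository` and a `rows` tibble
#'   keyed by uppercased peptide.
#' @export
read_evidence_table <- function(path,
                                repository = c("peptideatlas", "gpmdb", "pride")) {
  repository <- match.arg(repository)
  if (!file.exists(path)) stop("evidence table not found: ", path, call. = FALSE)
  value_col <- if (repository == "pride") "experiment_count" else "proteotypic"

  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!identical(names(tab), c("peptide", value_col))) {
    stop(sprintf("bad header for %s table %s: expected 'peptide\\t%s', found '%s'",
                 repository, path, value_col, paste(names(tab), collapse = "\\t")),
         call. = FALSE)
  }
  pep <- toupper(tab$peptide)
  if (anyDuplicated(pep)) {
    stop("duplicate peptide key(s) in ", path, ": ",
         paste(unique(pep[duplicated(pep)]), collapse = ", "), call. = FALSE)
  }
  if (repository == "pride") {
    if (!all(grepl("^[0-9]+$", tab[[value_col]]))) {
      stop("experiment_count must be a non-negative integer in ", path,
           call. = FALSE)
    }
    rows <- tibble::tibble(peptide = pep,
                           experiment_count = as.integer(tab[[value_col]]))
  } else {
    v <- tolower(tab[[value_col]])
    if (!all(v %in% c("0", "1", "true", "false"))) {
      stop("proteotypic must be one of 0/1/true/false in ", path, call. = FALSE)
    }
    rows <- tibble::tibble(peptide = pep,
                           proteotypic = v %in% c("1", "true"))
  }
  structure(list(repository = repository, rows = rows),
            class = "evidence_table")
}

#' Write an `evidence_table` to TSV
#' @param table An `evidence_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(table, path) {
  stopifnot(inherits(table, "evidence_table"))
  rows <- table$rows
  if ("proteotypic" %in% names(rows)) {
    rows$proteotypic <- tolower(as.character(rows$proteotypic))
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Write a report table as TSV
#'
#' Deterministic output: rows in the given order, UTF-8, tab-separated with a
#' header line; double columns are rendered with 4 decimal places.
#'
#' @param rows A data frame (possibly zero rows) whose columns are the report
#'   columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  rows <- tibble::as_tibble(rows)
  for (col in names(rows)) {
    if (is.double(rows[[col]]) && !is.integer(rows[[col]])) {
      rows[[col]] <- sprintf("%.4f", rows[[col]])
    }
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}
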