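AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the paired-database generator
#'
#' The generator emulates a source database in IPI header dialect and a
#' target database in UniProtKB dialect with planted, manifest-recorded
#' structure: exact shared copies, point-mutated shared proteins, source-only
#' ("lost") proteins, target-only proteins, duplicated target sequences
#' (forcing one-to-many sequence mappings), multi-cross-reference source
#' entries (forcing one-to-many logical mappings) and dangling
#' cross-references (forcing no logical mapping). Defaults are sized so that
#' the logical mapping outcome proportions resemble a real human-scale
#' database transition (roughly 73% mapped, 8% multiple, 20% none) at desk
#' scale.
#'
#' @param n_shared Exact shared copies (>= 1 when generating a pair).
#' @param n_mutated_shared Shared proteins whose target copy carries one
#'   recorded point substitution, creating partial peptide loss.
#' @param n_lost Source-only proteins; their whole tryptic search space is
#'   lost and their detectable fraction is 0.
#' @param n_target_only Target-only proteins.
#' @param n_duplicate_sequence_pairs Source proteins whose sequence occurs
#'   under two target accessions.
#' @param n_multi_xref Source proteins cross-referencing two valid targets.
#' @param n_bad_xref Source proteins cross-referencing an absent accession
#'   (their sequence is still present in the target).
#' @param protein_length_range Inclusive residue-length range (min >= 20).
#' @param evidence_fractions Named fractions `pa_proteotypic` and
#'   `gpmdb_proteotypic`: probability that a lost peptide is reported as
#'   proteotypic by the respective repository.
#' @param pride_presence Probability that a lost peptide occurs in PRIDE at
#'   all.
#' @param pride_count_range Inclusive experiment-count range for peptides
#'   present in PRIDE.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_shared = 140L,
                             n_mutated_shared = 10L,
                             n_lost = 40L,
                             n_target_only = 30L,
                             n_duplicate_sequence_pairs = 10L,
                             n_multi_xref = 17L,
                             n_bad_xref = 3L,
                             protein_length_range = c(60L, 600L),
                             evidence_fractions = c(pa_proteotypic = 0.002,
                                                    gpmdb_proteotypic = 0.003),
                             pride_presence = 0.04,
                             pride_count_range = c(1L, 8L),
                             seed = 1L) {
  counts <- c(n_shared = n_shared, n_mutated_shared = n_mutated_shared,
              n_lost = n_lost, n_target_only = n_target_only,
              n_duplicate_sequence_pairs = n_duplicate_sequence_pairs,
              n_multi_xref = n_multi_xref, n_bad_xref = n_bad_xref)
  stopifnot(all(counts >= 0L))
  protein_length_range <- as.integer(protein_length_range)
  stopifnot(length(protein_length_range) == 2L,
            protein_length_range[1L] >= 20L,
            protein_length_range[1L] <= protein_length_range[2L])
  stopifnot(all(c("pa_proteotypic", "gpmdb_proteotypic") %in%
                  names(evidence_fractions)),
            all(evidence_fractions >= 0), all(evidence_fractions <= 1),
            pride_presence >= 0, pride_presence <= 1)
  pride_count_range <- as.integer(pride_count_range)
  stopifnot(length(pride_count_range) == 2L, pride_count_range[1L] >= 0L,
            pride_count_range[1L] <= pride_count_range[2L])
  structure(list(n_shared = as.integer(n_shared),
                 n_mutated_shared = as.integer(n_mutated_shared),
                 n_lost = as.integer(n_lost),
                 n_target_only = as.integer(n_target_only),
                 n_duplicate_sequence_pairs = as.integer(n_duplicate_sequence_pairs),
                 n_multi_xref = as.integer(n_multi_xref),
                 n_bad_xref = as.integer(n_bad_xref),
                 protein_length_range = protein_length_range,
                 evidence_fractions = evidence_fractions,
                 pride_presence = pride_presence,
                 pride_count_range = pride_count_range,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw a random protein sequence
#'
#' Residues are drawn uniformly from the 20 standard amino acids, so K and R
#' together occur at ~10% and tryptic fragments average ~10 residues —
#' comparable to real proteomes. Uses the current RNG state; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param length Residue count (>= 20).
#' @return Uppercase amino-acid string.
#' @export
generate_protein_sequence <- function(length) {
  length <- as.integer(length)
  if (length < 20L) stop("synthetic proteins must be >= 20 residues", call. = FALSE)
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

# draw a sequence not seen before (tracked in environment `used`)
draw_unique_sequence <- function(len_range, used) {
  repeat {
    len <- sample(seq.int(len_range[1L], len_range[2L]), 1L)
    s <- generate_protein_sequence(len)
    if (is.null(used[[s]])) {
      used[[s]] <- TRUE
      return(s)
    }
  }
}

empty_records <- function() {
  tibble::tibble(accession = character(0), version = integer(0),
                 entry_name = character(0), description = character(0),
                 sequence = character(0), taxon = integer(0),
                 review_status = character(0), xrefs = list())
}

source_record <- function(acc, seq, xrefs, desc) {
  tibble::tibble(accession = acc, version = 1L, entry_name = NA_character_,
                 description = desc, sequence = seq, taxon = 9606L,
                 review_status = "not-applicable", xrefs = list(xrefs))
}

target_record <- function(acc, seq, desc, review = "reviewed") {
  tibble::tibble(accession = acc, version = NA_integer_,
                 entry_name = paste0(acc, "_SYNTH"),
                 description = desc, sequence = seq, taxon = 9606L,
                 review_status = review, xrefs = list(list()))
}

# pick a point substitution inside a qualifying (>= 7 residue) tryptic
# peptide that is unique within the protein and leaves the cleavage pattern
# untouched (neither original nor replacement residue is K, R or P)
plant_mutation <- function(seq, min_qual_len = 7L) {
  occ <- digest_protein(seq)
  lens <- occ$end - occ$start + 1L
  unique_pep <- !(occ$peptide %in% occ$peptide[duplicated(occ$peptide)])
  cand <- which(lens >= min_qual_len & unique_pep)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (j in sample(cand)) {
    pos_all <- occ$start[j]:occ$end[j]
    pos_ok <- pos_all[!(chars[pos_all] %in% c("K", "R", "P"))]
    if (length(pos_ok) == 0L) next
    pos <- if (length(pos_ok) == 1L) pos_ok else sample(pos_ok, 1L)
    ref <- chars[pos]
    alt <- sample(setdiff(AA20, c("K", "R", "P", ref)), 1L)
    chars[pos] <- alt
    return(list(mutated = paste(chars, collapse = ""), position = pos,
                ref = ref, alt = alt, peptide_index = j,
                source_peptide = occ$peptide[j]))
  }
  NULL
}

#' Generate a paired source/target database with a truth manifest
#'
#' See [synthetic_config()] for the planted structure. The manifest records
#' every downstream expectation exactly: per-algorithm mapping status
#' counts, the accessions of lost-only proteins, the distinct lost-peptide
#' count, the per-protein detectable fractions of affected proteins (under
#' missed cleavages 0 and detectability bound 7), and the planted point
#' mutations.
#'
#' Construction guarantees backing the manifest: all protein sequences are
#' globally distinct except the planted duplicates and shared copies;
#' lost-only proteins are redrawn until their tryptic peptides are disjoint
#' from the target's distinct set and include at least one peptide of >= 7
#' residues; mutated peptides are verified absent from the target.
#'
#' @param config A [synthetic_config()].
#' @return List with `source` and `target` (`protein_db`) and `manifest`
#'   (a `truth_manifest` list).
#' @export
generate_pair <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_shared < 1L) stop("n_shared must be >= 1", call. = FALSE)

  withr::with_seed(config$seed, {
    used <- new.env(parent = emptyenv())
    lr <- config$protein_length_range
    src_i <- 0L; tgt_i <- 0L
    next_src <- function() { src_i <<- src_i + 1L; sprintf("IPI%08d", src_i) }
    next_tgt <- function() { tgt_i <<- tgt_i + 1L; sprintf("P%05d", tgt_i) }

    src <- list(); tgt <- list()
    add_src <- function(r) src[[length(src) + 1L]] <<- r
    add_tgt <- function(r) tgt[[length(tgt) + 1L]] <<- r

    # exact shared copies; every third one carries isoform-suffixed xrefs
    for (i in seq_len(config$n_shared)) {
      s <- draw_unique_sequence(lr, used)
      ta <- next_tgt()
      xr_acc <- if (i %% 3L == 0L) paste0(ta, "-", 1:2) else ta
      add_src(source_record(next_src(), s,
                            list(`SWISS-PROT` = xr_acc,
                                 ENSEMBL = sprintf("ENSP%011d", i)),
                            "shared protein"))
      add_tgt(target_record(ta, s, "shared protein"))
    }

    # mutated shared: target copy differs by one recorded point substitution
    mut_rows <- list()
    mutated_acc <- character(0)
    mutated_lost_pep <- character(0)
    mutated_frac_num <- list()
    for (i in seq_len(config$n_mutated_shared)) {
      repeat {
        s <- draw_unique_sequence(lr, used)
        mut <- plant_mutation(s)
        if (!is.null(mut) && is.null(used[[mut$mutated]])) break
      }
      used[[mut$mutated]] <- TRUE
      sa <- next_src(); ta <- next_tgt()
      add_src(source_record(sa, s, list(`SWISS-PROT` = ta),
                            "shared protein, diverged in target"))
      add_tgt(target_record(ta, mut$mutated, "diverged copy"))
      mutated_acc <- c(mutated_acc, sa)
      mutated_lost_pep <- c(mutated_lost_pep, mut$source_peptide)
      mut_rows[[i]] <- tibble::tibble(accession = sa, position = mut$position,
                                      ref = mut$ref, alt = mut$alt,
                                      lost_peptide = mut$source_peptide)
      mutated_frac_num[[sa]] <- s
    }

    # duplicated target sequences: sequence mapping must report "multiple"
    for (i in seq_len(config$n_duplicate_sequence_pairs)) {
      s <- draw_unique_sequence(lr, used)
      ta1 <- next_tgt(); ta2 <- next_tgt()
      add_src(source_record(next_src(), s, list(`SWISS-PROT` = ta1),
                            "protein with duplicated target sequence"))
      add_tgt(target_record(ta1, s, "duplicate sequence A"))
      add_tgt(target_record(ta2, s, "duplicate sequence B"))
    }

    # multi-xref: two valid UniProtKB cross-references, logical "multiple"
    for (i in seq_len(config$n_multi_xref)) {
      s <- draw_unique_sequence(lr, used)
      buddy_seq <- draw_unique_sequence(lr, used)
      ta <- next_tgt(); buddy <- next_tgt()
      add_src(source_record(next_src(), s,
                            list(`SWISS-PROT` = ta, TREMBL = buddy),
                            "protein with two cross-references"))
      add_tgt(target_record(ta, s, "multi-xref main"))
      add_tgt(target_record(buddy, buddy_seq, "multi-xref buddy",
                            review = "unreviewed"))
    }

    # dangling xref: accession absent from the target, logical "none"
    for (i in seq_len(config$n_bad_xref)) {
      s <- draw_unique_sequence(lr, used)
      ta <- next_tgt()
      add_src(source_record(next_src(), s,
                            list(`SWISS-PROT` = sprintf("X%05d", i)),
                            "protein with dangling cross-reference"))
      add_tgt(target_record(ta, s, "bad-xref counterpart"))
    }

    # target-only proteins
    for (i in seq_len(config$n_target_only)) {
      add_tgt(target_record(next_tgt(), draw_unique_sequence(lr, used),
                            "target-only protein",
                            review = if (i %% 2L == 0L) "unreviewed" else "reviewed"))
    }

    target <- new_protein_db(dplyr::bind_rows(c(list(empty_records()), tgt)),
                             name = "synthetic-target", release = "synth")
    target_distinct <- digest_database(target)$distinct

    # lost-only proteins: whole search space absent from the target
    lost_acc <- character(0)
    lost_pep <- character(0)
    for (i in seq_len(config$n_lost)) {
      repeat {
        s <- draw_unique_sequence(lr, used)
        occ <- digest_protein(s)
        if (!any(occ$peptide %in% target_distinct) &&
            any(nchar(occ$peptide) >= 7L)) break
      }
      sa <- next_src()
      add_src(source_record(sa, s,
                            list(ENSEMBL = sprintf("ENSP9%010d", i)),
                            "source-only protein"))
      lost_acc <- c(lost_acc, sa)
      lost_pep <- c(lost_pep, occ$peptide)
    }

    # verify planted mutated peptides really are lost (astronomically likely)
    if (any(mutated_lost_pep %in% target_distinct)) {
      stop("internal: a planted mutated peptide collided with the target ",
           "search space; use a different seed", call. = FALSE)
    }

    source <- new_protein_db(dplyr::bind_rows(c(list(empty_records()), src)),
                             name = "synthetic-source", release = "synth")

    # expected detectable fractions (mc = 0, detectability bound 7)
    det_rows <- list()
    for (sa in lost_acc) det_rows[[sa]] <- 0
    for (i in seq_along(mutated_acc)) {
      sa <- mutated_acc[i]
      s <- mutated_frac_num[[sa]]
      occ <- digest_protein(s)
      lens <- nchar(occ$peptide)
      qual_len <- sum(lens[lens >= 7L])
      det_rows[[sa]] <- (qual_len - nchar(mutated_lost_pep[i])) / nchar(s)
    }
    fractions <- tibble::tibble(
      accession = as.character(names(det_rows)),
      fraction = as.double(unlist(det_rows, use.names = FALSE)))
    if (length(det_rows) == 0L) {
      fractions <- tibble::tibble(accession = character(0), fraction = double(0))
    }

    expected_lost <- unique(c(lost_pep, mutated_lost_pep))
    mapping <- tibble::tibble(
      algorithm = rep(c("logical", "sequence"), each = 3L),
      status = rep(c("mapped", "multiple", "none"), 2L),
      count = c(config$n_shared + config$n_mutated_shared +
                  config$n_duplicate_sequence_pairs,
                config$n_multi_xref,
                config$n_bad_xref + config$n_lost,
                config$n_shared + config$n_multi_xref + config$n_bad_xref,
                config$n_duplicate_sequence_pairs,
                config$n_mutated_shared + config$n_lost)
    )

    manifest <- structure(
      list(mapping = mapping,
           lost_only_accessions = lost_acc,
           lost_peptide_count = length(expected_lost),
           lost_peptides = sort(expected_lost),
           detectability = list(
             affected_count = nrow(fractions),
             count_le_50pct = sum(fractions$fraction <= 0.5),
             count_le_10pct = sum(fractions$fraction <= 0.1),
             count_zero = sum(fractions$fraction == 0),
             fractions = fractions),
           mutations = if (length(mut_rows) > 0L) dplyr::bind_rows(mut_rows) else
             tibble::tibble(accession = character(0), position = integer(0),
                            ref = character(0), alt = character(0),
                            lost_peptide = character(0)),
           seed = config$seed),
      class = "truth_manifest")

    list(source = source, target = target, manifest = manifest)
  })
}

#' Generate repository evidence tables for lost peptides
#'
#' Draws per-peptide proteotypic flags (PeptideAtlas, GPMDB) and PRIDE
#' experiment counts from the configured fractions and range, and records
#' the expected Venn region counts and inclusion candidates. Tables list
#' only observed evidence: proteotypic rows with a `TRUE` flag and PRIDE
#' rows with a count of at least 1, mirroring real repository snapshots.
#'
#' @param lost_filtered Character vector of lost peptides, each >= 7
#'   residues.
#' @param config A [synthetic_config()]; evidence draws derive from
#'   `config$seed` (offset so they are independent of database generation).
#' @param criteria [inclusion_criteria()] used for the expected candidate
#'   set.
#' @return List with `tables` (named list of `evidence_table`s) and
#'   `manifest` (expected `venn` tibble, `candidates`, `n_annotated`).
#' @export
generate_evidence <- function(lost_filtered, config = synthetic_config(),
                              criteria = inclusion_criteria()) {
  stopifnot(inherits(config, "synthetic_config"), is.character(lost_filtered))
  if (any(nchar(lost_filtered) <= 6L)) {
    stop("lost peptides must be length-filtered (>= 7) before evidence ",
         "generation", call. = FALSE)
  }
  pep <- sort(unique(lost_filtered))
  n <- length(pep)
  withr::with_seed(config$seed + 7919L, {
    pa <- stats::runif(n) < config$evidence_fractions[["pa_proteotypic"]]
    gp <- stats::runif(n) < config$evidence_fractions[["gpmdb_proteotypic"]]
    present <- stats::runif(n) < config$pride_presence
    rng <- config$pride_count_range
    counts <- integer(n)
    if (any(present)) {
      counts[present] <- if (rng[1L] == rng[2L]) rng[1L] else
        sample(seq.int(rng[1L], rng[2L]), sum(present), replace = TRUE)
    }
  })

  tables <- list(
    peptideatlas = structure(list(repository = "peptideatlas",
                                  rows = tibble::tibble(peptide = pep[pa],
                                                        proteotypic = TRUE)),
                             class = "evidence_table"),
    gpmdb = structure(list(repository = "gpmdb",
                           rows = tibble::tibble(peptide = pep[gp],
                                                 proteotypic = TRUE)),
                      class = "evidence_table"),
    pride = structure(list(repository = "pride",
                           rows = tibble::tibble(peptide = pep[counts > 0L],
                                                 experiment_count = counts[counts > 0L])),
                      class = "evidence_table")
  )

  pr <- counts >= 1L
  cell <- 1L + 4L * pa + 2L * gp + 1L * pr
  tab <- tabulate(cell, nbins = 8L)
  grid <- expand.grid(in_pride = c(FALSE, TRUE), in_gpmdb = c(FALSE, TRUE),
                      in_peptideatlas = c(FALSE, TRUE))
  venn <- tibble::tibble(
    in_peptideatlas = grid$in_peptideatlas,
    in_gpmdb = grid$in_gpmdb,
    in_pride = grid$in_pride,
    count = tab[1L + 4L * grid$in_peptideatlas + 2L * grid$in_gpmdb + grid$in_pride]
  )

  is_cand <- (criteria$accept_peptideatlas_proteotypic & pa) |
    (criteria$accept_gpmdb_proteotypic & gp) |
    (counts >= criteria$pride_min_experiments)

  list(tables = tables,
       manifest = list(venn = venn, candidates = pep[is_cand], n_annotated = n))
}
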