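test_that("sequence generation is length-checked and tryptically realistic", {
  expect_error(withr::with_seed(1, generate_protein_sequence(19)), ">= 20")
  s1 <- withr::with_seed(5, generate_protein_sequence(40))
  s2 <- withr::with_seed(5, generate_protein_sequence(40))
  expect_identical(s1, s2)
  expect_equal(nchar(s1), 40L)
  expect_match(s1, "^[A-Z]+$")

  # ~10% K/R sites: mean mc=0 peptide count of a 100-mer lands in [6, 16]
  counts <- withr::with_seed(6, vapply(1:500, function(i) {
    nrow(digest_protein(generate_protein_sequence(100)))
  }, numeric(1)))
  expect_gt(mean(counts), 6)
  expect_lt(mean(counts), 16)
})

test_that("generated pairs are reproducible and structurally sound", {
  cfg <- synthetic_config(n_shared = 12, n_mutated_shared = 2, n_lost = 4,
                          n_target_only = 3, n_duplicate_sequence_pairs = 2,
                          n_multi_xref = 2, n_bad_xref = 1,
                          protein_length_range = c(40, 150), seed = 31)
  p1 <- generate_pair(cfg)
  p2 <- generate_pair(cfg)
  expect_identical(p1$source$records, p2$source$records)
  expect_identical(p1$target$records, p2$target$records)
  expect_identical(p1$manifest, p2$manifest)

  expect_equal(db_size(p1$source), 12 + 2 + 4 + 2 + 2 + 1)
  expect_equal(db_size(p1$target), 12 + 2 + 3 + 4 + 4 + 1)
  expect_equal(anyDuplicated(p1$source$records$accession), 0L)
  expect_true(all(p1$manifest$lost_only_accessions %in%
                    p1$source$records$accession))
  # every lost-only protein truly contributes no peptide to the target
  tgt_distinct <- digest_database(p1$target)$distinct
  for (acc in p1$manifest$lost_only_accessions) {
    seq <- p1$source$records$sequence[p1$source$records$accession == acc]
    expect_length(intersect(digest_protein(seq)$peptide, tgt_distinct), 0)
  }
  # planted mutations: source and target copies differ at the recorded spot
  for (i in seq_len(nrow(p1$manifest$mutations))) {
    m <- p1$manifest$mutations[i, ]
    src_seq <- p1$source$records$sequence[
      p1$source$records$accession == m$accession]
    expect_equal(substr(src_seq, m$position, m$position), m$ref)
  }
})

test_that("edge configurations plant exactly the promised outcomes", {
  p <- generate_pair(synthetic_config(
    n_shared = 5, n_mutated_shared = 0, n_lost = 0, n_target_only = 0,
    n_duplicate_sequence_pairs = 0, n_multi_xref = 0, n_bad_xref = 0,
    protein_length_range = c(30, 80), seed = 32))
  expect_equal(sum(p$manifest$mapping$count[p$manifest$mapping$status == "mapped"]),
               10L)
  expect_equal(p$manifest$lost_peptide_count, 0L)

  p2 <- generate_pair(synthetic_config(
    n_shared = 3, n_mutated_shared = 0, n_lost = 2, n_target_only = 0,
    n_duplicate_sequence_pairs = 0, n_multi_xref = 0, n_bad_xref = 0,
    protein_length_range = c(30, 80), seed = 33))
  expect_length(p2$manifest$lost_only_accessions, 2)
  expect_equal(p2$manifest$detectability$count_zero, 2L)
  seq_none <- p2$manifest$mapping$count[
    p2$manifest$mapping$algorithm == "sequence" &
      p2$manifest$mapping$status == "none"]
  expect_equal(seq_none, 2L)

  p3 <- generate_pair(synthetic_config(
    n_shared = 2, n_mutated_shared = 0, n_lost = 0, n_target_only = 0,
    n_duplicate_sequence_pairs = 1, n_multi_xref = 0, n_bad_xref = 0,
    protein_length_range = c(30, 80), seed = 34))
  out <- map_database(p3$source, p3$target, "sequence")
  expect_equal(sum(out$status == "multiple"), 1L)

  expect_error(generate_pair(synthetic_config(n_shared = 0)), "n_shared")
})

test_that("evidence generation is seed-deterministic and boundary-exact", {
  pep <- sprintf("PEPTIDESEQ%03d", 1:50)
  cfg <- synthetic_config(evidence_fractions = c(pa_proteotypic = 0.2,
                                                 gpmdb_proteotypic = 0.2),
                          pride_presence = 0.5, pride_count_range = c(1, 8),
                          seed = 35)
  e1 <- generate_evidence(pep, cfg)
  e2 <- generate_evidence(pep, cfg)
  expect_identical(e1$tables$pride$rows, e2$tables$pride$rows)
  expect_identical(e1$manifest, e2$manifest)
  expect_equal(sum(e1$manifest$venn$count), 50L)

  # all-off: everything falls in the empty region, no candidates
  off <- generate_evidence(pep, synthetic_config(
    evidence_fractions = c(pa_proteotypic = 0, gpmdb_proteotypic = 0),
    pride_presence = 0, seed = 36))
  expect_equal(off$manifest$venn$count[!off$manifest$venn$in_peptideatlas &
                                         !off$manifest$venn$in_gpmdb &
                                         !off$manifest$venn$in_pride], 50L)
  expect_length(off$manifest$candidates, 0)

  # all-on at counts >= 5: triple region holds everything, all candidates
  on <- generate_evidence(pep, synthetic_config(
    evidence_fractions = c(pa_proteotypic = 1, gpmdb_proteotypic = 1),
    pride_presence = 1, pride_count_range = c(5, 5), seed = 37))
  expect_equal(on$manifest$venn$count[on$manifest$venn$in_peptideatlas &
                                        on$manifest$venn$in_gpmdb &
                                        on$manifest$venn$in_pride], 50L)
  expect_equal(on$manifest$candidates, sort(pep))

  expect_error(generate_evidence(c("AK", pep), cfg), "length-filtered")
})
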