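target_db <- function(acc, seqs) {
  protein_db(acc, seqs, review_status = "reviewed", name = "tgt")
}

test_that("sequence mapping classifies by exact full-length identity", {
  tgt <- target_db(c("P1", "P2", "P3"), c("MKWVR", "MKWVR", "CCCC"))
  idx <- build_sequence_index(tgt)
  expect_equal(sum(lengths(idx)), 3L)

  rec <- protein_db("IPI1", "CCCC")$records[1, ]
  expect_equal(sequence_map(rec, idx)$status, "mapped")

  rec2 <- protein_db("IPI2", "MKWVR")$records[1, ]
  out2 <- sequence_map(rec2, idx)
  expect_equal(out2$status, "multiple")
  expect_equal(out2$targets, c("P1", "P2"))

  rec3 <- protein_db("IPI3", "MKWVA")$records[1, ]
  out3 <- sequence_map(rec3, idx)
  expect_equal(out3$status, "none")
  expect_length(out3$targets, 0)

  # fragments never match: identity is full length
  rec4 <- protein_db("IPI4", "MKWV")$records[1, ]
  expect_equal(sequence_map(rec4, idx)$status, "none")

  expect_error(build_sequence_index(protein_db(character(0), character(0))),
               "empty")
})

test_that("logical mapping consults UniProtKB xrefs and collapses isoforms", {
  tgt <- target_db(c("P01111", "Q59F99", "O95793"),
                   c("MKWVR", "CCCC", "DDDD"))
  src <- protein_db(
    c("IPI1", "IPI2", "IPI3", "IPI4"),
    c("AAAA", "EEEE", "FFFF", "GGGG"),
    xrefs = list(
      list(`SWISS-PROT` = "P01111"),
      list(`SWISS-PROT` = "P01111", TREMBL = "Q59F99"),
      list(ENSEMBL = "ENSP00000001"),
      list(`SWISS-PROT` = c("O95793-1", "O95793-2"))
    ))
  out <- map_database(src, tgt, "logical")
  expect_equal(out$status, c("mapped", "multiple", "none", "mapped"))
  expect_equal(out$targets[[2]], c("P01111", "Q59F99"))
  expect_equal(out$targets[[4]], "O95793")  # isoforms collapse to one parent
})

test_that("mapping outcomes partition the source and are order-independent", {
  pair <- generate_pair(synthetic_config(n_shared = 20, n_mutated_shared = 3,
                                         n_lost = 5, n_target_only = 4,
                                         n_duplicate_sequence_pairs = 2,
                                         n_multi_xref = 3, n_bad_xref = 2,
                                         protein_length_range = c(40, 150),
                                         seed = 21))
  for (alg in c("logical", "sequence")) {
    out <- map_database(pair$source, pair$target, alg)
    expect_equal(nrow(out), db_size(pair$source))
    expect_equal(anyDuplicated(out$source_accession), 0L)
    smry <- summarize_mapping(out)
    expect_equal(sum(smry$count), db_size(pair$source))
    expect_equal(sum(smry$fraction), 1, tolerance = 1e-9)

    # shuffling source record order must not change any outcome
    shuffled <- pair$source
    perm <- withr::with_seed(7, sample(nrow(shuffled$records)))
    shuffled$records <- shuffled$records[perm, ]
    out2 <- map_database(shuffled, pair$target, alg)
    expect_equal(out2[order(out2$source_accession), ],
                 out[order(out$source_accession), ], ignore_attr = TRUE)
  }
})

test_that("sequence-mapped records share their target's exact sequence", {
  pair <- generate_pair(synthetic_config(n_shared = 15, n_lost = 3,
                                         n_duplicate_sequence_pairs = 2,
                                         protein_length_range = c(40, 120),
                                         seed = 22))
  out <- map_database(pair$source, pair$target, "sequence")
  hit <- out[out$status == "mapped", ]
  for (i in seq_len(nrow(hit))) {
    src_seq <- pair$source$records$sequence[
      pair$source$records$accession == hit$source_accession[i]]
    tgt_seq <- pair$target$records$sequence[
      pair$target$records$accession == hit$targets[[i]]]
    expect_identical(src_seq, tgt_seq)
  }
})

test_that("mapping summaries reject mixed algorithms and tally fractions", {
  out <- tibble::tibble(
    source_accession = c("a", "b", "c", "d"),
    algorithm = "logical",
    status = c("mapped", "none", "none", "multiple"),
    targets = list("P1", character(0), character(0), c("P1", "P2")))
  smry <- summarize_mapping(out)
  expect_equal(smry$fraction[smry$status == "mapped"], 0.25)
  expect_equal(smry$fraction[smry$status == "multiple"], 0.25)
  expect_equal(smry$fraction[smry$status == "none"], 0.5)

  all_mapped <- out[1, ]
  expect_equal(summarize_mapping(all_mapped)$fraction, c(1, 0, 0))

  out$algorithm <- c("logical", "logical", "sequence", "sequence")
  expect_error(summarize_mapping(out), "mix")
})
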