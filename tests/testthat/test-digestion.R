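test_that("cleavage sites follow the Keil rule", {
  expect_equal(cleavage_sites("AAAA"), integer(0))
  expect_equal(cleavage_sites("AKRPCK"), 2L)  # R blocked by P; terminal K
  expect_equal(cleavage_sites("MKWVR"), 2L)   # terminal R never cuts
  expect_equal(cleavage_sites("K"), integer(0))
  expect_equal(cleavage_sites("AKBKXR"), c(2L, 4L))  # ambiguity codes inert
  expect_error(cleavage_sites(""), "empty")
})

test_that("digest enumerates fragments and missed cleavages with coordinates", {
  d0 <- digest_protein("AAAA")
  expect_equal(d0$peptide, "AAAA")
  expect_equal(c(d0$start, d0$end), c(1L, 4L))

  d1 <- digest_protein("AKRPCK")
  expect_equal(d1$peptide, c("AK", "RPCK"))
  expect_equal(d1$start, c(1L, 3L))

  d2 <- digest_protein("MKWVR", digestion_params(missed_cleavages = 1))
  expect_equal(d2$peptide, c("MK", "MKWVR", "WVR"))
  expect_equal(d2$start, c(1L, 1L, 3L))
  expect_equal(d2$end, c(2L, 5L, 5L))

  expect_equal(nrow(digest_protein("MKWVR", digestion_params(min_length = 7))), 0L)
})

test_that("database digests accumulate totals, distinct sets and occurrences", {
  db <- protein_db(c("p1", "p2"), c("AKCA", "AKDA"))
  s <- digest_database(db)
  expect_equal(s$total_count, 4L)
  expect_setequal(s$distinct, c("AK", "CA", "DA"))
  expect_equal(s$occurrences$accession, c("p1", "p1", "p2", "p2"))
  expect_equal(redundancy(s), 3 / 4)

  # duplicated protein doubles the total but not the distinct set
  db2 <- protein_db(c("p1", "p2"), c("AKCA", "AKCA"))
  s2 <- digest_database(db2)
  expect_equal(s2$total_count, 4L)
  expect_setequal(s2$distinct, c("AK", "CA"))
})

test_that("digest matches the brute-force substring oracle", {
  withr::local_seed(401)
  for (rep in 1:150) {
    seq <- random_sequence(sample(1:50, 1),
                           alphabet = strsplit("ACDEFGHIKLMNPRSTVWYXBZ", "")[[1L]])
    for (mc in 0:2) {
      got <- digest_protein(seq, digestion_params(missed_cleavages = mc))
      want <- oracle_digest(seq, mc)
      expect_equal(got$start, want$start, info = paste(seq, mc))
      expect_equal(got$end, want$end, info = paste(seq, mc))
      expect_equal(got$peptide, want$peptide, info = paste(seq, mc))
    }
  }
})

test_that("mc=0 digests satisfy concatenation, internal-residue and count laws", {
  withr::local_seed(402)
  for (rep in 1:40) {
    seq <- random_sequence(sample(20:200, 1))
    occ <- digest_protein(seq)
    expect_equal(paste(occ$peptide, collapse = ""), seq)
    expect_equal(nrow(occ), length(cleavage_sites(seq)) + 1L)
    # K/R strictly inside a peptide only when followed by P in the parent
    for (j in seq_len(nrow(occ))) {
      inner <- substr(occ$peptide[j], 1L, nchar(occ$peptide[j]) - 1L)
      kr <- gregexpr("[KR]", inner)[[1L]]
      for (pos in kr[kr > 0]) {
        expect_equal(substr(seq, occ$start[j] + pos, occ$start[j] + pos), "P")
      }
    }
  }
})

test_that("distinct peptide sets grow monotonically with missed cleavages", {
  withr::local_seed(403)
  db <- protein_db(paste0("p", 1:10),
                   replicate(10, random_sequence(sample(30:120, 1))))
  prev <- digest_database(db, digestion_params(missed_cleavages = 0))$distinct
  for (mc in 1:3) {
    cur <- digest_database(db, digestion_params(missed_cleavages = mc))$distinct
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("length filtering keeps only peptides of at least min_length", {
  expect_setequal(filter_by_length(c("AK", "SAMPLER"), 7), "SAMPLER")
  x <- c("A", "ABCDEF", "ABCDEFG")
  expect_equal(filter_by_length(x, 1), x)
  expect_equal(filter_by_length(c("ABCDEF", "ABCDEFG"), 7), "ABCDEFG")
})
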