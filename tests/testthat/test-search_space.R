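test_that("lost peptides are the source-minus-target distinct set", {
  expect_equal(lost_peptides(c("A", "B", "C"), c("B", "C", "D")), "A")
  expect_equal(lost_peptides(c("A", "B"), c("A", "B")), character(0))
  expect_setequal(lost_peptides(c("A", "B"), c("C")), c("A", "B"))

  src <- digest_database(protein_db("p1", "AAKCCK"))
  tgt <- digest_database(protein_db("q1", "AAKDDK"),
                         digestion_params(missed_cleavages = 1))
  expect_error(lost_peptides(src, tgt), "parameters differ")
})

test_that("search-space comparison satisfies the set laws", {
  src <- digest_database(protein_db(c("p1", "p2"), c("AAKCCK", "DDKEEK")))
  tgt <- digest_database(protein_db(c("q1", "q2"), c("AAKFFK", "DDKEEK")))
  cmp <- compare_search_space(src, tgt)
  expect_setequal(cmp$lost, c("CCK"))
  expect_equal(cmp$lost_fraction, 1 / 4)
  expect_true(all(cmp$lost %in% src$distinct))
  expect_length(intersect(cmp$lost, tgt$distinct), 0)
  # lost(S,T) together with S intersect T reconstructs S
  expect_setequal(c(cmp$lost, intersect(src$distinct, tgt$distinct)),
                  src$distinct)

  cmp2 <- compare_search_space(src, src)
  expect_equal(cmp2$lost_fraction, 0)
})

test_that("per-protein detectability is the residue union of retained peptides", {
  db <- protein_db("p1", "MKWVR")
  s <- digest_database(db)
  rec <- db$records[1, ]
  occ <- s$occurrences

  d <- protein_detectability(rec, occ, target_distinct = "MK",
                             digestion_params(min_length = 1))
  expect_equal(d$detectable_residues, 2L)
  expect_equal(d$fraction, 0.4)

  d0 <- protein_detectability(rec, occ, character(0),
                              digestion_params(min_length = 1))
  expect_equal(d0$fraction, 0)

  d1 <- protein_detectability(rec, occ, c("MK", "WVR"),
                              digestion_params(min_length = 1))
  expect_equal(d1$fraction, 1)

  # detectability bound: the 2-mer no longer qualifies
  d7 <- protein_detectability(rec, occ, c("MK", "WVR"),
                              digestion_params(min_length = 3))
  expect_equal(d7$detectable_residues, 3L)

  occ$accession <- "other"
  expect_error(protein_detectability(rec, occ, "MK"), "foreign")
})

test_that("detectability report thresholds are nested and counted correctly", {
  # fractions 0.6, 0.4, 0.0 under min_length = 1
  db <- protein_db(c("p1", "p2", "p3"),
                   c("AAAAAKCCCK", "AAAKCCCCCK", "DDDDDDDDDD"))
  s <- digest_database(db)
  rep1 <- detectability_report(db, s, c("AAAAAK", "AAAK"),
                               digestion_params(min_length = 1))
  expect_equal(rep1$affected_count, 3L)
  expect_equal(rep1$count_le_50pct, 2L)
  expect_equal(rep1$count_le_10pct, 1L)
  expect_equal(rep1$count_zero, 1L)
  expect_equal(rep1$records$fraction, c(0.6, 0.4, 0.0))
  expect_true(rep1$count_zero <= rep1$count_le_10pct &&
                rep1$count_le_10pct <= rep1$count_le_50pct &&
                rep1$count_le_50pct <= rep1$affected_count)

  # no lost peptides anywhere: all counts zero
  rep2 <- detectability_report(db, s, s$distinct,
                               digestion_params(min_length = 1))
  expect_equal(rep2$affected_count, 0L)
  expect_equal(rep2$count_zero, 0L)
  expect_equal(nrow(rep2$records), 0L)
})

test_that("proteins with full target coverage never enter the report", {
  withr::local_seed(77)
  db <- protein_db(paste0("p", 1:8),
                   replicate(8, random_sequence(sample(30:100, 1))))
  s <- digest_database(db)
  rep <- detectability_report(db, s, s$distinct,
                              digestion_params(min_length = 1))
  expect_equal(rep$affected_count, 0L)
})
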