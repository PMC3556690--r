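# Materialise a synthetic pair (and optional evidence tables) on disk and
# build the matching run_config.
setup_synthetic_run <- function(cfg, dir, with_evidence = TRUE,
                                pride_min_experiments = 5L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- generate_pair(cfg)
  src <- file.path(dir, "source.fasta")
  tgt <- file.path(dir, "target.fasta")
  write_fasta(pair$source, src, "ipi")
  write_fasta(pair$target, tgt, "uniprot")

  ev <- NULL
  evidence_paths <- NULL
  if (with_evidence) {
    lost <- lost_peptides(digest_database(pair$source),
                          digest_database(pair$target))
    ev <- generate_evidence(
      filter_by_length(lost, 7), cfg,
      inclusion_criteria(pride_min_experiments = pride_min_experiments))
    evidence_paths <- list(
      peptideatlas = file.path(dir, "peptideatlas.tsv"),
      gpmdb = file.path(dir, "gpmdb.tsv"),
      pride = file.path(dir, "pride.tsv"))
    for (nm in names(evidence_paths)) {
      write_evidence_table(ev$tables[[nm]], evidence_paths[[nm]])
    }
  }

  config <- run_config(src, tgt, evidence_paths = evidence_paths,
                       pride_min_experiments = pride_min_experiments,
                       out_dir = file.path(dir, "out"))
  list(pair = pair, evidence = ev, config = config)
}

small_cfg <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_shared = 20, n_mutated_shared = 3, n_lost = 5,
                   n_target_only = 4, n_duplicate_sequence_pairs = 2,
                   n_multi_xref = 3, n_bad_xref = 2,
                   protein_length_range = c(40, 150), seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}
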