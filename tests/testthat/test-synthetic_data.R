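test_that("sim_config validates and requires a seed", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, core_mutation_rate = 1.5))
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_precursors, 5L)
})

test_that("identical configs give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(tiny_sim(70), out_dir = d1)
  simulate_dataset(tiny_sim(70), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the sequences
  d3 <- withr::local_tempdir()
  simulate_dataset(tiny_sim(71), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "transcripts_S01.fasta")),
                         readLines(file.path(d3, "transcripts_S01.fasta"))))
})

test_that("make_precursor honors leader modes and mutation controls", {
  cfg0 <- sim_config(seed = 72, core_mutation_rate = 0)
  set.seed(72)
  p <- make_precursor(cfg0, 1L)
  expect_equal(p$core, BARRETTIDE_C_SEQ)
  expect_true(p$signal %in% SIGNAL_MOTIFS)
  expect_equal(substr(p$leader, nchar(p$leader), nchar(p$leader)), "A")

  cfg112 <- sim_config(seed = 72, leader_mode = "long112")
  set.seed(72)
  expect_equal(nchar(make_precursor(cfg112, 1L)$leader), 112L)

  # framework preservation holds at high mutation rates across seeds
  fw <- framework_of(barrettide_c())
  cfg_mut <- sim_config(seed = 73, core_mutation_rate = 0.3,
                        preserve_framework = TRUE)
  set.seed(73)
  for (i in 1:100) {
    core <- make_precursor(cfg_mut, 1L)$core
    expect_equal(framework_of(core)$gap_lengths, fw$gap_lengths)
    expect_equal(framework_of(core)$n_cys, fw$n_cys)
  }
})

test_that("encode_transcript round-trips and records the truth", {
  cfg <- sim_config(seed = 74, n_decoys = 0L)
  set.seed(74)
  for (i in 1:10) {
    prec <- make_precursor(cfg, 1L)
    enc <- encode_transcript(prec, cfg, id = "t")
    tru <- enc$truth
    seq <- enc$record$sequence
    orf <- substr(seq, tru$orf_nt_start + 1L, tru$orf_nt_end)
    if (tru$strand == "-") orf <- revcomp(orf)
    expect_equal(translate_nt(orf), prec$protein)
    # conserved 3'UTR and stop sit right after the ORF
    oriented <- if (tru$strand == "-") revcomp(seq) else seq
    oend <- if (tru$strand == "-") nchar(seq) - tru$orf_nt_start else
      tru$orf_nt_end
    expect_equal(substr(oriented, oend + 1L, oend + 3L), "TGA")
    expect_equal(substr(oriented, oend + 4L, oend + 36L), CONSERVED_UTR3)
    if (tru$polya_len > 0) {
      expect_equal(detect_polya(oriented), tru$polya_len)
    }
  }
  # same protein, different codons under different seeds
  set.seed(75); e1 <- encode_transcript(make_precursor(cfg, 1L), cfg)
  set.seed(76); e2 <- encode_transcript(make_precursor(cfg, 1L), cfg)
  expect_false(identical(e1$record$sequence, e2$record$sequence))
})

test_that("make_peak_list plants exact ions at zero jitter and noise", {
  cfg <- sim_config(seed = 77, mz_jitter_sd = 0, peak_noise_count = 0L,
                    charges = 2L)
  set.seed(77)
  mk <- make_peak_list(list(barrettide_c()), cfg)
  expect_equal(nrow(mk$peak_list$peaks), 1L)
  expect_equal(mk$peak_list$peaks$mz, 1619.6808, tolerance = 1e-4)
  expect_equal(mk$truth$charge, 2L)

  # noise-only peak lists stay inside the scan range and call nothing
  cfgn <- sim_config(seed = 78, peak_noise_count = 1000L)
  set.seed(78)
  noise <- make_peak_list(list(), cfgn)
  expect_equal(nrow(noise$peak_list$peaks), 1000L)
  expect_true(all(noise$peak_list$peaks$mz >= 50 &
                    noise$peak_list$peaks$mz <= 1500))
  calls <- presence_call(
    match_ions(list(theoretical_ions(barrettide_c())), noise$peak_list,
               tolerance = 0.05),
    list(theoretical_ions(barrettide_c())))
  expect_false(any(calls$present))
})

test_that("planted recovery is perfect at mutation 0 and degrades monotonically", {
  rate_recovery <- function(rate, seed) {
    cfg <- sim_config(seed = seed, n_precursors = 3L, n_decoys = 0L,
                      n_samples = 1L, core_mutation_rate = rate,
                      preserve_framework = TRUE, peak_noise_count = 0L)
    ds <- simulate_dataset(cfg)
    hits <- search_transcripts(barrettide_c(), ds$transcripts$S01)
    length(unique(hits$transcript_id)) / nrow(ds$transcripts$S01)
  }
  for (seed in c(80, 81, 82)) {
    r0 <- rate_recovery(0, seed)
    r3 <- rate_recovery(0.3, seed)
    r6 <- rate_recovery(0.6, seed)
    expect_equal(r0, 1)
    expect_true(r0 >= r3)
    expect_true(r3 >= r6)
  }
})
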