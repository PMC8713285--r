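test_that("clean_hit_sequence strips asterisks and dashes, idempotently", {
  expect_equal(clean_hit_sequence("NVV-PC*FC"), "NVVPCFC")
  expect_equal(clean_hit_sequence(""), "")
  expect_equal(clean_hit_sequence("NVVPCFC"), "NVVPCFC")
  set.seed(30)
  for (i in 1:20) {
    raw <- paste(sample(c(names(AA_MONO), "*", "-"), 25, TRUE), collapse = "")
    once <- clean_hit_sequence(raw)
    expect_equal(clean_hit_sequence(once), once)
    expect_false(grepl("[*-]", once))
  }
})

test_that("framework_of extracts inter-cysteine spacings", {
  fw <- framework_of(barrettide_c())
  expect_equal(fw$gap_lengths, c(1L, 10L, 4L))
  expect_equal(fw$n_cys, 4L)
  expect_equal(framework_of("CC")$gap_lengths, 0L)
  expect_error(framework_of("ACA"), "fewer than 2 Cys")
})

test_that("matches_framework enforces exact spacing at any offset", {
  fw <- framework_of(barrettide_c())
  expect_true(matches_framework(BARRETTIDE_C_SEQ, fw))
  broken <- sub("^(....C.)C", "\\1S", BARRETTIDE_C_SEQ)  # C7 -> S
  expect_false(matches_framework(broken, fw))
  expect_true(matches_framework(paste0("GGGG", BARRETTIDE_C_SEQ), fw))
  # slack widens the acceptance window
  # gaps 1, 9, 4: middle gap one residue short of the framework
  shifted <- paste0("AC", "A", "C", strrep("A", 9), "C", strrep("A", 4), "CA")
  expect_false(matches_framework(shifted, fw))
  expect_true(matches_framework(shifted, fw, slack = 1L))
})

test_that("matches_framework(query, framework_of(query)) holds generally", {
  set.seed(31)
  n_ok <- 0L
  while (n_ok < 30L) {
    p <- random_peptide(sample(10:40, 1))
    if (lengths(regmatches(p, gregexpr("C", p))) < 2L) next
    expect_true(matches_framework(p, framework_of(p)))
    n_ok <- n_ok + 1L
  }
})

test_that("locate_core anchors the core within a precursor protein", {
  bc <- barrettide_c()
  set.seed(32)
  leader <- paste0(paste(sample(setdiff(names(AA_MONO), "C"), 18, TRUE),
                         collapse = ""), "A")
  prot <- paste0(SIGNAL_MOTIFS[1], leader, BARRETTIDE_C_SEQ)
  expect_equal(locate_core(prot, bc), c(38L, 69L))
  expect_equal(locate_core(BARRETTIDE_C_SEQ, bc), c(0L, 31L))
  expect_null(locate_core(random_peptide(80), bc))
})

test_that("annotate_precursor segments the printed architecture", {
  cfg <- sim_config(seed = 33, n_precursors = 1L, leader_mode = "short",
                    n_decoys = 0L, n_samples = 1L)
  set.seed(33)
  prec <- make_precursor(cfg, 1L)
  enc <- encode_transcript(prec, cfg, id = "tx")
  orfs <- extract_orfs(enc$record, min_protein_len = 50L)
  orf <- orfs[grepl(prec$core, orfs$protein, fixed = TRUE), ]
  span <- locate_core(orf$protein, barrettide_c())
  ann <- annotate_precursor(orf, span, enc$record)
  expect_equal(nchar(ann$signal), 19L)
  expect_equal(nchar(ann$leader), 19L)
  expect_equal(ann$leader_len_class, "short")
  expect_equal(ann$core, prec$core)
  expect_true(ann$flags[["junction_is_Ala"]])
  expect_true(ann$flags[["stop_is_TGA"]])
  expect_true(ann$flags[["signal_motif"]])
  expect_false(ann$flags[["trailing_residues"]])
  expect_equal(nchar(ann$utr3), 33L)
  expect_equal(ann$polya_len, enc$truth$polya_len)
  # signal+leader+core partitions the ORF protein
  expect_equal(paste0(ann$signal, ann$leader, ann$core), orf$protein)
})

test_that("long leaders and non-Ala junctions are flagged, not dropped", {
  cfg <- sim_config(seed = 34, n_precursors = 1L, leader_mode = "long112",
                    n_decoys = 0L, n_samples = 1L)
  set.seed(34)
  prec <- make_precursor(cfg, 1L)
  expect_equal(nchar(prec$leader), 112L)
  enc <- encode_transcript(prec, cfg, id = "tx")
  orfs <- extract_orfs(enc$record, min_protein_len = 50L)
  orf <- orfs[grepl(prec$core, orfs$protein, fixed = TRUE), ]
  ann <- annotate_precursor(orf, locate_core(orf$protein, barrettide_c()),
                            enc$record)
  expect_equal(nchar(ann$leader), 112L)
  expect_equal(ann$leader_len_class, "long")

  # non-Ala junction: annotation is kept with the flag unset
  prot <- paste0(SIGNAL_MOTIFS[1], strrep("K", 18), "G", BARRETTIDE_C_SEQ)
  orf2 <- list(transcript_id = "t", frame = 1L, nt_start = 0L,
               nt_end = 3L * nchar(prot), protein = prot, stop_codon = "TGA")
  ann2 <- annotate_precursor(orf2, c(38L, 69L),
                             paste0(strrep("ACG", nchar(prot)), "TGA"))
  expect_false(ann2$flags[["junction_is_Ala"]])

  # core overlapping the signal is malformed
  expect_error(annotate_precursor(orf2, c(10L, 41L), "ACGT"), "malformed")
})

test_that("dedupe_candidates collapses identical cores deterministically", {
  mk <- function(core, tid) {
    a <- list(core = core, orf = list(transcript_id = tid),
              flags = c(junction_is_Ala = TRUE, stop_is_TGA = TRUE))
    class(a) <- "precursor_annotation"
    a
  }
  two <- dedupe_candidates(list(mk("ACDC", "t1"), mk("ACDC", "t2")))
  expect_equal(nrow(two), 1L)
  expect_equal(two$n_support, 2L)
  expect_equal(two$transcripts, "t1,t2")
  expect_equal(two$name, "cand1")

  diff <- dedupe_candidates(list(mk("ACDC", "t1"), mk("ACDA", "t2")))
  expect_equal(nrow(diff), 2L)
  expect_equal(diff$name, c("cand1", "cand2"))

  expect_equal(nrow(dedupe_candidates(list())), 0L)
})

test_that("deduped candidates equal planted cores; broken decoys never pass", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(tiny_sim(302), out_dir = dir)
  res <- run_sim_pipeline(ds, dir, peaks = FALSE)
  planted <- unique(vapply(ds$manifest$records, `[[`, "", "core_seq"))
  expect_setequal(res$candidates$core_seq, planted)

  # framework-broken decoy precursors are rejected by the framework filter
  fw <- framework_of(barrettide_c())
  cfgb <- sim_config(seed = 303, n_precursors = 4L, n_decoys = 0L,
                     n_samples = 1L, force_cys_break = TRUE)
  set.seed(303)
  for (i in 1:4) {
    broken <- make_precursor(cfgb, i)
    expect_false(matches_framework(broken$core, fw))
  }
})
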