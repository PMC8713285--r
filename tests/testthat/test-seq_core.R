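test_that("read_fasta normalizes and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "acgt"), f)
  r <- read_fasta(f)
  expect_equal(r$id, "t1")
  expect_equal(r$sequence, "ACGT")

  writeLines(c(">t1", "ACGU"), f)
  expect_equal(read_fasta(f)$sequence, "ACGT")

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  writeLines(c(">t1", "ACGT", ">empty", ">t2", "AA"), f)
  expect_error(read_fasta(f), "line 3")

  writeLines(c(">t1", "ACQT"), f)
  expect_error(read_fasta(f), "invalid nucleotide")
})

test_that("fasta round-trips through write_fasta at 60 columns", {
  f <- withr::local_tempfile(fileext = ".fasta")
  recs <- data.frame(id = c("a", "b"),
                     sequence = c(strrep("ACGT", 40), "TTT"),
                     stringsAsFactors = FALSE)
  write_fasta(recs, f)
  expect_true(all(nchar(readLines(f)) <= 60L))
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("six_frame_translate matches the standard code and maps coords", {
  f <- six_frame_translate("ATGAAA")
  expect_equal(f[["+1"]]$protein, "MK")
  expect_equal(f[["+1"]]$codon_starts, c(0L, 3L))
  expect_equal(six_frame_translate("TTTCAT")[["-1"]]$protein, "MK")
  expect_equal(six_frame_translate("TGA")[["+1"]]$protein, "*")
  # N translates to X
  expect_equal(six_frame_translate("ATGANA")[["+1"]]$protein, "MX")
  expect_warning(six_frame_translate("AT"), "shorter")
})

test_that("six-frame translation agrees with Biostrings on random records", {
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1), TRUE),
               collapse = "")
    fr <- six_frame_translate(s)
    for (off in 0:2) {
      ref <- as.character(Biostrings::translate(
        Biostrings::subseq(Biostrings::DNAString(s), start = off + 1,
                           width = ((nchar(s) - off) %/% 3) * 3),
        no.init.codon = TRUE))
      expect_equal(fr[[off + 1]]$protein, ref)
    }
  }
})

test_that("reverse-complementing the input permutes frames", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:60, 1), TRUE),
               collapse = "")
    a <- six_frame_translate(s)
    b <- six_frame_translate(revcomp(s))
    prot <- function(x) sort(unname(vapply(x, `[[`, "", "protein")))
    expect_equal(prot(a[1:3]), prot(b[4:6]))
    expect_equal(prot(a[4:6]), prot(b[1:3]))
  }
})

test_that("extract_orfs finds maximal M..stop segments", {
  o <- extract_orfs("ATGAAATGA", min_protein_len = 1L)
  o1 <- o[o$frame == 1L, ]
  expect_equal(o1$protein, "MK")
  expect_equal(o1$stop_codon, "TGA")
  expect_equal(c(o1$nt_start, o1$nt_end), c(0L, 6L))

  expect_equal(nrow(extract_orfs("AAACCCGGG", min_protein_len = 1L)), 0L)

  # nested starts: longest by default, all when configured
  s <- "ATGGCCATGAAATAA"
  expect_equal(extract_orfs(s, min_protein_len = 1L)$protein[1], "MAMK")
  all_o <- extract_orfs(s, min_protein_len = 1L, all_starts = TRUE)
  expect_setequal(all_o$protein[all_o$frame == 1L], c("MAMK", "MK"))
})

test_that("every ORF nucleotide interval retranslates to its protein", {
  set.seed(11)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE),
               collapse = "")
    orfs <- extract_orfs(s, min_protein_len = 2L)
    for (k in seq_len(nrow(orfs))) {
      sub <- substr(s, orfs$nt_start[k] + 1L, orfs$nt_end[k])
      expect_equal((orfs$nt_end[k] - orfs$nt_start[k]) %% 3L, 0)
      if (orfs$frame[k] < 0L) sub <- revcomp(sub)
      expect_equal(translate_nt(sub), orfs$protein[k])
      expect_equal(substr(orfs$protein[k], 1, 1), "M")
    }
  }
})

test_that("stop-terminated ORFs are invariant under appended tails", {
  set.seed(13)
  s <- "ATGAAACCCGGGTTTACACATTGA"
  base <- extract_orfs(s, min_protein_len = 1L)
  base <- base[base$frame == 1L & base$stop_codon != "", ]
  ext <- extract_orfs(paste0(s, "GCAGCAGCA"), min_protein_len = 1L)
  ext <- ext[ext$frame == 1L & ext$stop_codon != "", ]
  expect_equal(base$protein, ext$protein[seq_len(nrow(base))])
  expect_equal(base$nt_start, ext$nt_start[seq_len(nrow(base))])
})

test_that("simulator precursor transcripts contain the planted ORF", {
  ds <- simulate_dataset(tiny_sim(301))
  for (tru in ds$manifest$records) {
    rec <- ds$transcripts$S01[ds$transcripts$S01$id == tru$transcript_id, ]
    orfs <- extract_orfs(rec, min_protein_len = 50L)
    hit <- orfs[grepl(tru$core_seq, orfs$protein, fixed = TRUE), ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$frame, tru$frame)
    expect_equal(hit$nt_start, tru$orf_nt_start)
    expect_equal(hit$nt_end, tru$orf_nt_end)
  }
})
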