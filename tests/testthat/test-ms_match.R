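test_that("read_peak_list parses CSV and MGF, sorts, and reports errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("1619.681,1000", f)
  pl <- read_peak_list(f)
  expect_equal(nrow(pl$peaks), 1L)
  expect_equal(pl$peaks$mz, 1619.681)

  writeLines(c("mz,intensity", "900.5,10", "300.1,5"), f)
  pl <- read_peak_list(f)
  expect_equal(pl$peaks$mz, c(300.1, 900.5))

  writeLines(c("100,1", "oops,2"), f)
  expect_error(read_peak_list(f), "line 2")

  g <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500", "810.34 123",
               "1080.12 456", "END IONS"), g)
  plm <- read_peak_list(g)
  expect_equal(plm$peaks$mz, c(810.34, 1080.12))
  expect_equal(plm$peaks$intensity, c(123, 456))
})

test_that("match_ions matches within tolerance to the nearest peak", {
  bc <- theoretical_ions(barrettide_c())
  pl <- structure(list(sample = "s", peaks = data.frame(
    mz = c(100, 1619.681, 1620.5), intensity = c(1, 2, 3))),
    class = "peak_list")
  m <- match_ions(list(bc), pl, tolerance = 0.05)
  expect_equal(nrow(m), 1L)
  expect_equal(m$charge, 2L)
  expect_equal(m$error_da, 1619.681 - bc$mz_by_charge[["z2"]],
               tolerance = 1e-9)

  # out of tolerance -> nothing
  pl$peaks <- data.frame(mz = 1620.5, intensity = 1)
  expect_equal(nrow(match_ions(list(bc), pl, tolerance = 0.05)), 0L)

  # equidistant peaks: lower m/z wins
  pl$peaks <- data.frame(mz = c(999.99, 1000.01), intensity = c(1, 2))
  one <- theoretical_ions(mature_peptide("x", "G"), charges = 1)
  one$mz_by_charge <- c(z1 = 1000)
  m2 <- match_ions(list(one), pl, tolerance = 0.05)
  expect_equal(m2$observed_mz, 999.99)
})

test_that("matching equals a brute-force all-pairs scan in both modes", {
  set.seed(50)
  theo <- runif(12, 100, 1500)
  obs <- sort(c(theo[1:6] + rnorm(6, 0, 0.02), runif(20, 100, 1500)))
  pl <- structure(list(sample = "s", peaks = data.frame(
    mz = obs, intensity = 1)), class = "peak_list")
  sets <- lapply(seq_along(theo), function(i) {
    structure(list(peptide_name = paste0("p", i), sequence = "G",
                   neutral_mass_oxidized = theo[i] - MASS_PROTON,
                   mz_by_charge = c(z1 = theo[i]), n_disulfides = 0L),
              class = "theoretical_ions")
  })
  for (mode in c("da", "ppm")) {
    tol <- if (mode == "da") 0.05 else 30
    m <- match_ions(sets, pl, tolerance = tol, mode = mode)
    brute <- vapply(theo, function(t) {
      d <- if (mode == "da") abs(t - obs) else abs(t - obs) / t * 1e6
      any(d <= tol)
    }, logical(1))
    expect_setequal(m$peptide_name, paste0("p", which(brute)))
  }
})

test_that("isobaric peptides share peaks and ambiguity symmetrically", {
  a <- mature_peptide("pepB", "NLVPCFCVEDETSGAKTCIPDNCDASRGTNP",
                      list(c(5, 23), c(7, 18)))
  b <- mature_peptide("pepG", "NIVPCFCVEDETSGAKTCIPDNCDASRGTNP",
                      list(c(5, 23), c(7, 18)))
  sets <- list(theoretical_ions(a), theoretical_ions(b))
  pl <- structure(list(sample = "s", peaks = data.frame(
    mz = sets[[1]]$mz_by_charge[["z2"]], intensity = 1)),
    class = "peak_list")
  m <- match_ions(sets, pl, tolerance = 0.05)
  expect_equal(nrow(m), 2L)
  expect_equal(m$ambiguous_with[m$peptide_name == "pepB"], "pepG")
  expect_equal(m$ambiguous_with[m$peptide_name == "pepG"], "pepB")

  calls <- presence_call(m, sets)
  expect_true(all(calls$present))
  expect_true(all(calls$ambiguous))
})

test_that("presence_call counts distinct charge states", {
  m <- data.frame(peptide_name = c("p", "p"), charge = c(2L, 3L),
                  theoretical_mz = c(1, 1), observed_mz = c(1, 1),
                  intensity = 1, error_da = 0, error_ppm = 0,
                  ambiguous_with = c("", ""), stringsAsFactors = FALSE)
  expect_true(presence_call(m, min_charges = 2L)$present)
  expect_false(presence_call(m, min_charges = 3L)$present)
  single_amb <- m[1, ]; single_amb$ambiguous_with <- "q"
  call <- presence_call(single_amb, min_charges = 1L)
  expect_true(call$present)
  expect_true(call$ambiguous)
  none <- presence_call(m[0, ], list(theoretical_ions(barrettide_c())))
  expect_false(none$present)
})

test_that("build_presence_matrix merges evidence and validates samples", {
  seq_ev <- data.frame(sample = c("Gb01", "Gb01"),
                       peptide = c("pepA", "pepE"),
                       source = c("transcriptome", "genome"),
                       stringsAsFactors = FALSE)
  ms <- data.frame(sample = "Gb01", peptide_name = "pepA", present = TRUE,
                   ambiguous = FALSE, stringsAsFactors = FALSE)
  pm <- build_presence_matrix(seq_ev, ms)
  a <- pm[pm$peptide == "pepA", ]
  expect_true(a$sequence_evidence && a$ms_evidence && !a$ms_ambiguous)
  # genome-only evidence is tagged separately
  e <- pm[pm$peptide == "pepE", ]
  expect_true(e$genome_evidence && !e$sequence_evidence && !e$ms_evidence)

  expect_error(build_presence_matrix(seq_ev, ms, samples = "Gb02"),
               "unknown sample")
  empty <- build_presence_matrix(seq_ev[0, ], NULL)
  expect_equal(nrow(empty), 0L)
  expect_s3_class(pm, "presence_matrix")
  expect_true(nzchar(format(pm)))
})

test_that("simulated peak lists recover exactly the planted set at zero noise", {
  cfg <- tiny_sim(501, peak_noise_count = 0L, mz_jitter_sd = 0)
  ds <- simulate_dataset(cfg)
  sets <- lapply(ds$peptides, theoretical_ions)
  m <- match_ions(sets, ds$peak_lists$S01, tolerance = 0.05)
  calls <- presence_call(m, sets)
  expect_true(all(calls$present))
  expect_equal(sort(unique(m$peptide_name)), sort(names(ds$peptides)))
  # with jitter 0 observed m/z equal theoretical values exactly
  expect_true(all(abs(m$error_da) < 1e-9))
})
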