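# Independent oracles and small fixtures used across tests.

# Local alignment score by recursive enumeration over all alignments of all
# substring pairs (affine gaps: a gap of length k costs open + k * ext).
# Memoised recursion over (i, j, gap-state); written independently of the
# DP-with-traceback implementation it checks.
oracle_local_score <- function(q, s, submat = BLOSUM62_MAT,
                               open = 11, ext = 1) {
  A <- strsplit(q, "")[[1L]]
  B <- strsplit(s, "")[[1L]]
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) return(0)
  global_score <- function(ai, bi) {
    a <- A[ai]; b <- B[bi]
    na <- length(a); nb <- length(b)
    memo <- array(NA_real_, dim = c(na + 1L, nb + 1L, 3L))
    rec <- function(i, j, st) {  # st: 1 = none/match, 2 = gap-in-b, 3 = gap-in-a
      if (i > na && j > nb) return(0)
      if (!is.na(memo[i, j, st])) return(memo[i, j, st])
      best <- -Inf
      if (i <= na && j <= nb) {
        best <- max(best, submat[a[i], b[j]] + rec(i + 1L, j + 1L, 1L))
      }
      if (i <= na) {
        cost <- if (st == 2L) ext else open + ext
        best <- max(best, -cost + rec(i + 1L, j, 2L))
      }
      if (j <= nb) {
        cost <- if (st == 3L) ext else open + ext
        best <- max(best, -cost + rec(i, j + 1L, 3L))
      }
      memo[i, j, st] <<- best
      best
    }
    rec(1L, 1L, 1L)
  }
  best <- 0
  for (qs in seq_len(n)) for (qe in qs:n) {
    for (ss in seq_len(m)) for (se in ss:m) {
      best <- max(best, global_score(qs:qe, ss:se))
    }
  }
  best
}

# all strings of a given length over an alphabet
all_strings <- function(len, alphabet) {
  if (len == 0L) return("")
  grids <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grids, 1L, paste, collapse = "")
}

random_peptide <- function(len) {
  paste(sample(names(AA_MONO), len, replace = TRUE), collapse = "")
}

# compact simulator config for fast tests (defaults overridable via ...)
tiny_sim <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_precursors = 2L, n_decoys = 5L, n_samples = 1L,
         peak_noise_count = 20L),
    list(...))
  do.call(sim_config, args)
}

# run the full discovery pipeline on a simulated dataset written to disk
run_sim_pipeline <- function(ds, dir, peaks = TRUE, ...) {
  qf <- file.path(dir, "queries.fasta")
  writeLines(c(">barrettide_C", BARRETTIDE_C_SEQ), qf)
  asm <- file.path(dir, paste0("transcripts_", ds$samples, ".fasta"))
  pk <- if (peaks) file.path(dir, paste0("peaks_", ds$samples, ".csv")) else NULL
  run_pipeline(pipeline_config(queries = qf, assemblies = asm, peaks = pk,
                               out_dir = file.path(dir, "out"), ...))
}
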