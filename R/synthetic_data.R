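# Ground-truthed synthetic data: precursor transcripts with the family's
# architecture (signal 19 aa + leader 19/105/112 aa ending in Ala + 31-aa
# core + TGA stop + conserved 33-nt 3'UTR + optional poly-A), genomic
# copies with GT..AG introns, GC-structured decoy transcripts, and MS peak
# lists carrying planted charge-state ions plus uniform noise.
#
# All randomness flows from a single seed through fixed per-stage
# substreams, so identical configs yield byte-identical outputs and stages
# can be regenerated independently.

AA20 <- names(AA_MONO)

# derived substream seeds; kept far below 2^31 for 32-bit R integers
.stream_seed <- function(seed, stream) {
  offsets <- c(precursor = 11L, codon = 23L, decoy = 37L, genomic = 53L,
               peaks = 71L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

#' Simulator configuration
#'
#' Defaults state the world the analysis assumes: five planted precursors
#' (one family of five newly discoverable members), the printed barrettide
#' C core as template, mixed leader lengths (19/105/112), short geometric
#' poly-A tails, one ~300-nt intron per genomic copy, decoys drawn from two
#' GC modes (0.38 / 0.62) to emulate mixed eukaryote/prokaryote
#' assemblies, and Q-Tof-scale m/z jitter well inside the 0.05 Da matching
#' tolerance.
#'
#' @param seed Mandatory integer seed.
#' @param n_precursors Number of planted precursor transcripts (default 5).
#' @param n_decoys Number of decoy transcripts (default 100).
#' @param leader_mode `"short"`, `"long105"`, `"long112"`, or `"mixed"`.
#' @param core_template A [mature_peptide()] (default [barrettide_c()]).
#' @param core_mutation_rate Per-residue substitution probability
#'   (default 0).
#' @param preserve_framework Never mutate Cys and never introduce new Cys
#'   (default TRUE).
#' @param force_cys_break Force one core Cys to a non-Cys residue
#'   (framework-broken decoy precursors; default FALSE).
#' @param intron_lengths Intron lengths planted in genomic copies
#'   (default 300).
#' @param polya_geometric_mean Mean of the geometric poly-A tail-length
#'   excess over the 8-nt minimum (default 12).
#' @param polya_prob Probability a precursor transcript carries a poly-A
#'   tail (default 1).
#' @param peak_noise_count Uniform decoy peaks per peak list (default 200).
#' @param mz_jitter_sd Gaussian m/z jitter sd in Th (default 0.01).
#' @param charges Planted charge states (default 1:4).
#' @param scan_range Instrument scan range constraining noise peaks
#'   (default c(50, 1500)).
#' @param gc_decoy_modes List of `c(mean_gc, fraction)` pairs
#'   (default 0.38/0.62 at 50% each).
#' @param n_samples Number of synthetic samples (default 3).
#' @param anchor_k Minimum exon anchor size the genomic simulator must
#'   respect (default 21; exons are kept >= 2*anchor_k).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_precursors = 5L,
                       n_decoys = 100L,
                       leader_mode = c("mixed", "short", "long105", "long112"),
                       core_template = barrettide_c(),
                       core_mutation_rate = 0,
                       preserve_framework = TRUE,
                       force_cys_break = FALSE,
                       intron_lengths = 300L,
                       polya_geometric_mean = 12,
                       polya_prob = 1,
                       peak_noise_count = 200L,
                       mz_jitter_sd = 0.01,
                       charges = 1:4,
                       scan_range = c(50, 1500),
                       gc_decoy_modes = list(c(0.38, 0.5), c(0.62, 0.5)),
                       n_samples = 3L,
                       anchor_k = 21L) {
  if (missing(seed)) stop("seed is mandatory: no unseeded simulations")
  leader_mode <- match.arg(leader_mode)
  stopifnot(core_mutation_rate >= 0, core_mutation_rate <= 1,
            polya_prob >= 0, polya_prob <= 1,
            inherits(core_template, "mature_peptide"))
  structure(list(seed = as.integer(seed), n_precursors = as.integer(n_precursors),
                 n_decoys = as.integer(n_decoys), leader_mode = leader_mode,
                 core_template = core_template,
                 core_mutation_rate = core_mutation_rate,
                 preserve_framework = preserve_framework,
                 force_cys_break = force_cys_break,
                 intron_lengths = as.integer(intron_lengths),
                 polya_geometric_mean = polya_geometric_mean,
                 polya_prob = polya_prob,
                 peak_noise_count = as.integer(peak_noise_count),
                 mz_jitter_sd = mz_jitter_sd, charges = as.integer(charges),
                 scan_range = scan_range, gc_decoy_modes = gc_decoy_modes,
                 n_samples = as.integer(n_samples),
                 anchor_k = as.integer(anchor_k)),
            class = "sim_config")
}

.rand_aa <- function(n, exclude = character(0)) {
  pool <- setdiff(AA20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.rand_nt <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate one precursor protein
#'
#' Signal (one of the two printed motifs) + leader of the configured
#' length ending in Ala + core mutated from the template at
#' `core_mutation_rate`. With `preserve_framework`, substitutions never
#' touch a Cys and never introduce one, so the cysteine framework of the
#' core is invariant. The RNG state is the caller's.
#'
#' @param config A [sim_config()].
#' @param index Precursor index (names cores `synpepA`, `synpepB`, ...).
#' @return List: `name`, `protein`, `signal`, `leader`, `core`,
#'   `mutations` (data frame pos/from/to).
#' @export
make_precursor <- function(config, index = 1L) {
  signal <- sample(SIGNAL_MOTIFS, 1L)
  llen <- switch(config$leader_mode,
                 short = 19L, long105 = 105L, long112 = 112L,
                 mixed = sample(c(19L, 105L, 112L), 1L))
  leader <- if (llen > 1L)
    paste0(.rand_aa(llen - 1L, exclude = "C"), "A") else "A"
  core_ch <- strsplit(config$core_template$sequence, "")[[1L]]
  cys <- which(core_ch == "C")
  mut_pos <- which(rbinom(length(core_ch), 1L, config$core_mutation_rate) == 1L)
  if (config$preserve_framework) mut_pos <- setdiff(mut_pos, cys)
  muts <- list()
  for (p in mut_pos) {
    excl <- if (config$preserve_framework) c(core_ch[p], "C") else core_ch[p]
    new <- sample(setdiff(AA20, excl), 1L)
    muts[[length(muts) + 1L]] <- data.frame(pos = p, from = core_ch[p],
                                            to = new)
    core_ch[p] <- new
  }
  if (config$force_cys_break && length(cys) > 0L) {
    p <- sample(cys, 1L)
    new <- sample(setdiff(AA20, "C"), 1L)
    muts[[length(muts) + 1L]] <- data.frame(pos = p, from = "C", to = new)
    core_ch[p] <- new
  }
  core <- paste(core_ch, collapse = "")
  nm <- paste0("synpep", LETTERS[(index - 1L) %% 26L + 1L])
  list(name = nm, protein = paste0(signal, leader, core), signal = signal,
       leader = leader, core = core,
       mutations = if (length(muts)) do.call(rbind, muts) else
         data.frame(pos = integer(), from = character(), to = character()))
}

#' Encode a precursor protein as a transcript
#'
#' Codons are drawn uniformly from the synonymous set, the ORF ends in a
#' TGA stop, the fixed conserved 33-nt 3'UTR follows, then (with
#' probability `polya_prob`) a geometric poly-A tail of at least 8 nt.
#' A random 5'UTR precedes the ORF and the whole record is
#' reverse-complemented with probability 1/2 (strand recorded as truth).
#' The RNG state is the caller's.
#'
#' @param precursor Output of [make_precursor()].
#' @param config A [sim_config()].
#' @param id Transcript id.
#' @return List: `record` (one-row data frame id/sequence) and `truth`
#'   (list: transcript id, peptide name, core sequence, strand, frame,
#'   `orf_nt_start`/`orf_nt_end` forward-strand 0-based half-open coords of
#'   the coding region excluding the stop, `core_aa_span` within the ORF
#'   protein, `polya_len`).
#' @export
encode_transcript <- function(precursor, config, id = "tx1") {
  aa <- strsplit(precursor$protein, "")[[1L]]
  codons <- vapply(aa, function(a) sample(SYNONYMOUS_CODONS[[a]], 1L), "")
  orf <- paste(codons, collapse = "")
  utr5 <- .rand_nt(sample(20:80, 1L), gc = 0.45)
  polya_len <- 0L
  tail <- ""
  if (runif(1L) < config$polya_prob) {
    polya_len <- POLYA_MIN_RUN +
      rgeom(1L, 1 / (1 + config$polya_geometric_mean))
    tail <- strrep("A", polya_len)
  }
  fwd <- paste0(utr5, orf, "TGA", CONSERVED_UTR3, tail)
  orf_start <- nchar(utr5)
  orf_end <- orf_start + nchar(orf)      # excludes the stop codon
  L <- nchar(fwd)
  minus <- runif(1L) < 0.5
  seq <- if (minus) revcomp(fwd) else fwd
  if (minus) {
    s <- L - orf_end; e <- L - orf_start
    frame <- -(((L - e) %% 3L) + 1L)
  } else {
    s <- orf_start; e <- orf_end
    frame <- (s %% 3L) + 1L
  }
  sig_lead <- nchar(precursor$signal) + nchar(precursor$leader)
  list(record = data.frame(id = id, sequence = seq, stringsAsFactors = FALSE),
       truth = list(transcript_id = id, peptide = precursor$name,
                    core_seq = precursor$core,
                    strand = if (minus) "-" else "+", frame = frame,
                    orf_nt_start = s, orf_nt_end = e,
                    core_aa_span = c(sig_lead, sig_lead + nchar(precursor$core)),
                    polya_len = polya_len))
}

#' Insert introns into a transcript to make a genomic copy
#'
#' Introns (`GT` + random interior + `AG`, totalling the configured
#' lengths) are inserted at positions inside the ORF at least 30 nt from
#' either ORF end, spaced so every exon retains at least `2 * anchor_k` nt
#' of unique anchor sequence. Works on the plus-strand orientation of the
#' transcript. The RNG state is the caller's.
#'
#' @param transcript_truth The `truth` entry from [encode_transcript()]
#'   together with its record; pass the list returned by
#'   [encode_transcript()].
#' @param config A [sim_config()].
#' @param id Genomic record id.
#' @return List: `record` (one-row data frame) and `introns` (data frame
#'   `g_start`, `g_end`, `length` — coordinates on the genomic record).
#' @export
make_genomic <- function(transcript_truth, config, id = NULL) {
  rec <- transcript_truth$record
  tru <- transcript_truth$truth
  if (is.null(id)) id <- paste0("g_", rec$id)
  seq <- rec$sequence
  if (tru$strand == "-") seq <- revcomp(seq)   # plus-strand orientation
  L <- nchar(seq)
  # recover plus-strand ORF coords
  if (tru$strand == "-") {
    os <- L - tru$orf_nt_end; oe <- L - tru$orf_nt_start
  } else {
    os <- tru$orf_nt_start; oe <- tru$orf_nt_end
  }
  k <- length(config$intron_lengths)
  introns <- data.frame(g_start = integer(), g_end = integer(),
                        length = integer(), stringsAsFactors = FALSE)
  if (k > 0L) {
    lo <- os + max(30L, 2L * config$anchor_k)
    hi <- oe - max(30L, 2L * config$anchor_k)
    gap <- 2L * config$anchor_k
    # pick k insertion points spaced >= gap apart; reject points whose
    # flanking exon bases are G, which would make a GT..AG junction
    # ambiguous by shifting (the intron terminus could slide into the exon)
    pts <- integer(0)
    tries <- 0L
    while (length(pts) < k && tries < 1000L) {
      cand <- sample(lo:hi, 1L)
      if (all(abs(cand - pts) >= gap) &&
          substr(seq, cand, cand) != "G" &&
          substr(seq, cand + 1L, cand + 1L) != "G") {
        pts <- c(pts, cand)
      }
      tries <- tries + 1L
    }
    pts <- sort(pts)
    out <- substr(seq, 1L, pts[1L])
    offset <- 0L
    for (i in seq_along(pts)) {
      len <- config$intron_lengths[i]
      interior <- if (len > 4L) .rand_nt(len - 4L, gc = 0.4) else ""
      intron <- paste0("GT", interior, "AG")
      g_start <- pts[i] + offset
      introns <- rbind(introns, data.frame(
        g_start = g_start, g_end = g_start + len, length = len))
      nxt <- if (i < length(pts)) pts[i + 1L] else L
      out <- paste0(out, intron, substr(seq, pts[i] + 1L, nxt))
      offset <- offset + len
    }
    seq <- out
  }
  list(record = data.frame(id = id, sequence = seq, stringsAsFactors = FALSE),
       introns = introns)
}

#' Simulate an MS peak list
#'
#' For every planted peptide, one peak per configured charge at the
#' theoretical oxidized m/z plus Gaussian jitter, with log-normal
#' intensity; plus `peak_noise_count` uniform noise peaks over the
#' instrument scan range. The RNG state is the caller's.
#'
#' @param peptides List of [mature_peptide()] objects to plant (may be
#'   empty).
#' @param config A [sim_config()].
#' @param sample Sample label.
#' @return List: `peak_list` (class `peak_list`) and `truth` (data frame
#'   `peptide`, `charge`, `true_mz`).
#' @export
make_peak_list <- function(peptides, config, sample = "S01") {
  mzv <- numeric(0); inty <- numeric(0)
  truth <- data.frame(peptide = character(), charge = integer(),
                      true_mz = numeric(), stringsAsFactors = FALSE)
  for (p in peptides) {
    ti <- theoretical_ions(p, charges = config$charges)
    for (i in seq_along(config$charges)) {
      true_mz <- ti$mz_by_charge[[i]]
      mzv <- c(mzv, true_mz + rnorm(1L, 0, config$mz_jitter_sd))
      inty <- c(inty, rlnorm(1L, meanlog = 8, sdlog = 1))
      truth <- rbind(truth, data.frame(peptide = p$name,
                                       charge = config$charges[i],
                                       true_mz = true_mz))
    }
  }
  if (config$peak_noise_count > 0L) {
    mzv <- c(mzv, runif(config$peak_noise_count,
                        config$scan_range[1L], config$scan_range[2L]))
    inty <- c(inty, rlnorm(config$peak_noise_count, meanlog = 5, sdlog = 1))
  }
  o <- order(mzv)
  pl <- structure(list(sample = sample,
                       peaks = data.frame(mz = mzv[o], intensity = inty[o])),
                  class = "peak_list")
  list(peak_list = pl, truth = truth)
}

#' Simulate a full ground-truthed dataset
#'
#' Generates, per sample: precursor transcripts, decoy transcripts, and a
#' peak list carrying the planted peptides' ions; plus one genomic copy
#' (with introns) per precursor of the first sample. Identical configs
#' yield byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes
#'   `transcripts_<sample>.fasta`, `genomic.fasta`,
#'   `peaks_<sample>.csv`, and `manifest.json`.
#' @return List of class `sim_dataset`: `config`, `samples`, `peptides`
#'   (list of [mature_peptide()]), `transcripts` (named list of record
#'   data frames per sample), `genomic` (record data frame),
#'   `peak_lists` (named list), `manifest` (list with `records`,
#'   `introns`, `peaks`).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  # precursor proteins (shared across samples: same biological peptides)
  set.seed(.stream_seed(config$seed, "precursor"))
  precursors <- lapply(seq_len(config$n_precursors), make_precursor,
                       config = config)
  peptides <- lapply(precursors, function(p) {
    mp <- config$core_template
    # carry the template connectivity when the framework is intact
    pairs <- tryCatch({
      fw_ok <- matches_framework(p$core, framework_of(config$core_template))
      if (fw_ok) {
        cys_new <- which(strsplit(p$core, "")[[1L]] == "C")
        cys_old <- mp$cys_positions
        lapply(mp$disulfide_pairs, function(pr)
          cys_new[match(pr, cys_old)])
      } else list()
    }, error = function(e) list())
    mature_peptide(p$name, p$core, pairs)
  })
  names(peptides) <- vapply(peptides, `[[`, "", "name")

  # transcripts per sample (isoform-like: same protein, fresh codons)
  set.seed(.stream_seed(config$seed, "codon"))
  transcripts <- list(); rec_truth <- list()
  enc_first <- list()
  for (s in seq_along(samples)) {
    recs <- list()
    for (i in seq_along(precursors)) {
      enc <- encode_transcript(precursors[[i]], config,
                               id = sprintf("%s_tx%02d", samples[s], i))
      recs[[i]] <- enc$record
      enc$truth$sample <- samples[s]
      rec_truth[[length(rec_truth) + 1L]] <- enc$truth
      if (s == 1L) enc_first[[i]] <- enc
    }
    transcripts[[samples[s]]] <- do.call(rbind, recs)
  }

  # decoys appended to every sample's transcriptome
  set.seed(.stream_seed(config$seed, "decoy"))
  modes <- config$gc_decoy_modes
  fracs <- vapply(modes, `[`, numeric(1L), 2L)
  fracs <- fracs / sum(fracs)
  for (s in seq_along(samples)) {
    n <- config$n_decoys
    if (n == 0L) next
    counts <- round(n * fracs)
    counts[1L] <- n - sum(counts[-1L])
    recs <- list()
    d <- 0L
    for (m in seq_along(modes)) {
      gc_mean <- modes[[m]][1L]
      for (j in seq_len(counts[m])) {
        d <- d + 1L
        gc <- min(max(rnorm(1L, gc_mean, 0.02), 0.05), 0.95)
        recs[[d]] <- data.frame(
          id = sprintf("%s_decoy%03d", samples[s], d),
          sequence = .rand_nt(sample(300:1500, 1L), gc = gc),
          stringsAsFactors = FALSE)
      }
    }
    transcripts[[samples[s]]] <- rbind(transcripts[[samples[s]]],
                                       do.call(rbind, recs))
  }

  # genomic copies with introns, from sample 1's precursor transcripts
  set.seed(.stream_seed(config$seed, "genomic"))
  genomic <- list(); intron_truth <- list()
  for (i in seq_along(enc_first)) {
    g <- make_genomic(enc_first[[i]], config)
    genomic[[i]] <- g$record
    if (nrow(g$introns) > 0L) {
      g$introns$genomic_id <- g$record$id
      g$introns$transcript_id <- enc_first[[i]]$record$id
      intron_truth[[length(intron_truth) + 1L]] <- g$introns
    }
  }
  genomic <- do.call(rbind, genomic)

  # peak lists per sample
  set.seed(.stream_seed(config$seed, "peaks"))
  peak_lists <- list(); peak_truth <- list()
  for (s in samples) {
    mk <- make_peak_list(peptides, config, sample = s)
    peak_lists[[s]] <- mk$peak_list
    if (nrow(mk$truth) > 0L) {
      mk$truth$sample <- s
      peak_truth[[length(peak_truth) + 1L]] <- mk$truth
    }
  }

  manifest <- list(
    seed = config$seed,
    records = rec_truth,
    introns = if (length(intron_truth)) do.call(rbind, intron_truth) else
      data.frame(),
    peaks = if (length(peak_truth)) do.call(rbind, peak_truth) else
      data.frame())

  out <- structure(list(config = config, samples = samples,
                        peptides = peptides, transcripts = transcripts,
                        genomic = genomic, peak_lists = peak_lists,
                        manifest = manifest),
                   class = "sim_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in samples) {
      write_fasta(transcripts[[s]],
                  file.path(out_dir, paste0("transcripts_", s, ".fasta")))
      write_peak_list(peak_lists[[s]],
                      file.path(out_dir, paste0("peaks_", s, ".csv")))
    }
    write_fasta(genomic, file.path(out_dir, "genomic.fasta"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
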