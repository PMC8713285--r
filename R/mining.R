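# Candidate mining: hit cleanup, cysteine-framework filtering, core
# localization within ORFs, precursor architecture annotation, and
# candidate deduplication.
#
# The precursor model follows the RiPP-like architecture of barrettide
# precursors: a 19-residue signal peptide, a leader of 19, 105 or 112
# residues ending in Ala, the 31-residue core, a TGA stop immediately
# after the core, and a conserved ~33-nt 3'UTR.

#' Construct a mature peptide
#'
#' @param name Peptide name.
#' @param sequence Amino-acid sequence (20 standard residues).
#' @param disulfide_pairs List of 1-based Cys position pairs, e.g.
#'   `list(c(5, 23), c(7, 18))`. May be empty.
#' @return Object of class `mature_peptide` with fields `name`, `sequence`,
#'   `cys_positions`, `disulfide_pairs`, `n_disulfides`.
#' @export
mature_peptide <- function(name, sequence, disulfide_pairs = list()) {
  sequence <- toupper(sequence)
  cys <- which(strsplit(sequence, "")[[1L]] == "C")
  for (p in disulfide_pairs) {
    if (!all(p %in% cys)) {
      stop("disulfide pair (", paste(p, collapse = ","),
           ") does not index Cys residues")
    }
  }
  used <- unlist(disulfide_pairs)
  if (anyDuplicated(used)) stop("a Cys cannot join two disulfide bonds")
  structure(list(name = name, sequence = sequence, cys_positions = cys,
                 disulfide_pairs = disulfide_pairs,
                 n_disulfides = length(disulfide_pairs)),
            class = "mature_peptide")
}

#' @export
print.mature_peptide <- function(x, ...) {
  cat("mature_peptide:", x$name, "\n  ", x$sequence, "\n  Cys at ",
      paste(x$cys_positions, collapse = ","), "; ", x$n_disulfides,
      " disulfide bond(s)\n", sep = "")
  invisible(x)
}

#' The barrettide C mature peptide
#'
#' Convenience constructor for the printed barrettide C sequence with its
#' I-IV, II-III disulfide connectivity (Cys5-Cys23, Cys7-Cys18).
#'
#' @return A [mature_peptide()].
#' @export
barrettide_c <- function() {
  mature_peptide("barrettide_C", BARRETTIDE_C_SEQ,
                 list(c(5L, 23L), c(7L, 18L)))
}

#' Remove alignment artifacts from a hit sequence
#'
#' Deletes every `*` (translated stop) and `-` (alignment gap) from a raw
#' hit string, preserving all other characters in order. Idempotent.
#'
#' @param raw Character vector of raw hit strings.
#' @return Cleaned character vector.
#' @export
clean_hit_sequence <- function(raw) {
  gsub("[*-]", "", raw)
}

#' Cysteine framework of a peptide
#'
#' The framework is the vector of inter-cysteine spacings (number of
#' non-Cys residues between consecutive Cys). Barrettides have framework
#' C-x1-C-x10-C-x4-C, i.e. gaps (1, 10, 4) over 4 cysteines.
#'
#' @param peptide A [mature_peptide()] or plain AA string with >= 2 Cys.
#' @return Object of class `cys_framework`: list with `gap_lengths`
#'   (integer vector) and `n_cys`.
#' @export
framework_of <- function(peptide) {
  seq <- if (inherits(peptide, "mature_peptide")) peptide$sequence else
    toupper(peptide)
  cys <- which(strsplit(seq, "")[[1L]] == "C")
  if (length(cys) < 2L) stop("fewer than 2 Cys: no framework")
  structure(list(gap_lengths = as.integer(diff(cys) - 1L),
                 n_cys = length(cys)),
            class = "cys_framework")
}

#' @export
print.cys_framework <- function(x, ...) {
  cat("cysteine framework: C-",
      paste0("x", x$gap_lengths, "-C", collapse = "-"),
      " (", x$n_cys, " Cys)\n", sep = "")
  invisible(x)
}

#' Does a candidate fit a cysteine framework?
#'
#' TRUE iff the candidate contains `n_cys` cysteines whose consecutive
#' spacings match the framework's gap lengths (within `slack` per gap;
#' default exact). The framework is searched at every offset, so leading or
#' trailing residues and additional cysteines elsewhere do not disqualify a
#' candidate.
#'
#' @param candidate_seq Cleaned candidate AA string.
#' @param framework A `cys_framework` from [framework_of()].
#' @param slack Per-gap tolerance in residues (default 0 = exact spacing).
#' @return Logical.
#' @export
matches_framework <- function(candidate_seq, framework, slack = 0L) {
  stopifnot(inherits(framework, "cys_framework"))
  ch <- strsplit(toupper(candidate_seq), "")[[1L]]
  cys <- which(ch == "C")
  k <- framework$n_cys
  if (length(cys) < k) return(FALSE)
  gaps <- framework$gap_lengths
  if (slack == 0L) {
    for (p in cys) {
      pos <- p
      ok <- TRUE
      for (g in gaps) {
        nxt <- pos + g + 1L
        if (nxt > length(ch) || ch[nxt] != "C") { ok <- FALSE; break }
        pos <- nxt
      }
      if (ok) return(TRUE)
    }
    return(FALSE)
  }
  # slack > 0: depth-first search over Cys positions
  rec <- function(pos, gi) {
    if (gi > length(gaps)) return(TRUE)
    lo <- pos + gaps[gi] + 1L - slack
    hi <- pos + gaps[gi] + 1L + slack
    for (nxt in cys[cys >= lo & cys <= hi & cys > pos]) {
      if (rec(nxt, gi + 1L)) return(TRUE)
    }
    FALSE
  }
  any(vapply(cys, rec, logical(1L), gi = 1L))
}

#' Locate the core peptide within an ORF protein
#'
#' Anchors the query's best local alignment within `orf_protein` and
#' returns the core span (0-based half-open), of the query's length,
#' adjusted by up to `max_shift` residues so that the spanned substring
#' carries cysteines at exactly the query's cysteine positions.
#'
#' @param orf_protein ORF protein string.
#' @param query A [mature_peptide()].
#' @param min_score Minimum alignment score to accept (default 50).
#' @param max_shift Maximum anchor adjustment in residues (default 5).
#' @return Integer vector `c(start, end)` or `NULL` when no alignment
#'   reaches `min_score` or no framework-consistent placement exists.
#' @export
locate_core <- function(orf_protein, query, min_score = 50, max_shift = 5L) {
  stopifnot(inherits(query, "mature_peptide"))
  al <- align_local(query$sequence, orf_protein)
  if (al$score < min_score) return(NULL)
  L <- nchar(query$sequence)
  n <- nchar(orf_protein)
  anchor <- al$subject_span[1] - al$query_span[1]
  ch <- strsplit(orf_protein, "")[[1L]]
  fits <- function(s) {
    if (s < 0L || s + L > n) return(FALSE)
    all(ch[s + query$cys_positions] == "C")
  }
  for (d in c(0L, as.vector(rbind(seq_len(max_shift), -seq_len(max_shift))))) {
    s <- anchor + d
    if (fits(s)) return(c(s, s + L))
  }
  NULL
}

#' Annotate precursor architecture
#'
#' Segments an ORF protein into signal / leader / core given the core span,
#' and inspects the transcript for the stop codon and 3'UTR. The junction
#' residue is the last leader residue (expected Ala); the stop codon is
#' expected to be TGA; the 3'UTR runs from just after the stop codon to
#' the poly-A tail (trailing run of >= 8 A) or the transcript end. These
#' expectations are recorded as validation flags, not filters.
#'
#' @param orf One-row data frame (or list) from [extract_orfs()].
#' @param core_span Integer `c(start, end)`, 0-based half-open within the
#'   ORF protein.
#' @param transcript Transcript DNA string, or one-row data frame from
#'   [read_fasta()].
#' @param signal_len Signal peptide length (default 19).
#' @param check_motif Also test the signal against the two-variant
#'   consensus motif (default TRUE; result recorded as a flag).
#' @return Object of class `precursor_annotation`: list with `orf`,
#'   `signal`, `leader`, `core`, `junction_residue`, `stop_codon`, `utr3`,
#'   `polya_len`, and `flags` (named logical vector: `junction_is_Ala`,
#'   `stop_is_TGA`, `leader_len_known`, `signal_motif`,
#'   `trailing_residues`), plus `leader_len_class` ("short", "long",
#'   "other").
#' @export
annotate_precursor <- function(orf, core_span, transcript,
                               signal_len = 19L, check_motif = TRUE) {
  if (is.data.frame(orf)) orf <- as.list(orf[1L, ])
  seq <- if (is.character(transcript)) transcript[[1L]] else
    transcript$sequence[[1L]]
  prot <- orf$protein
  n <- nchar(prot)
  cs <- core_span[1L]; ce <- core_span[2L]
  if (cs < signal_len) stop("malformed precursor: core overlaps signal")
  if (ce > n) stop("core span exceeds ORF protein")
  signal <- substr(prot, 1L, signal_len)
  leader <- substr(prot, signal_len + 1L, cs)
  core <- substr(prot, cs + 1L, ce)
  junction <- if (nchar(leader) > 0L) substr(leader, nchar(leader), nchar(leader)) else ""
  leader_len <- nchar(leader)
  leader_class <- if (leader_len == 19L) "short" else
    if (leader_len %in% c(105L, 112L)) "long" else "other"

  # orient the transcript to the ORF's strand for stop/UTR inspection
  L <- nchar(seq)
  if (orf$frame < 0L) {
    oseq <- revcomp(seq)
    oend <- L - orf$nt_start
  } else {
    oseq <- seq
    oend <- orf$nt_end
  }
  core_ends_orf <- (ce == n)
  stop_codon <- orf$stop_codon
  utr3 <- ""
  polya_len <- 0L
  if (nzchar(stop_codon)) {
    tail_seq <- substr(oseq, oend + 4L, L)  # after the stop codon
    polya_len <- detect_polya(tail_seq, min_run = POLYA_MIN_RUN)
    utr3 <- if (polya_len > 0L)
      substr(tail_seq, 1L, nchar(tail_seq) - polya_len) else tail_seq
  }
  flags <- c(
    junction_is_Ala = identical(junction, "A"),
    stop_is_TGA = identical(stop_codon, "TGA"),
    leader_len_known = leader_len %in% c(19L, 105L, 112L),
    signal_motif = if (check_motif) grepl(SIGNAL_MOTIF_REGEX, prot) else NA,
    trailing_residues = !core_ends_orf
  )
  structure(list(orf = orf, signal = signal, leader = leader, core = core,
                 junction_residue = junction, stop_codon = stop_codon,
                 utr3 = utr3, polya_len = polya_len,
                 leader_len_class = leader_class, flags = flags),
            class = "precursor_annotation")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("precursor: signal(", nchar(x$signal), ") + leader(", nchar(x$leader),
      ", ", x$leader_len_class, ") + core(", nchar(x$core), ")\n",
      "  core: ", x$core, "\n  stop: ", x$stop_codon,
      "  3'UTR: ", nchar(x$utr3), " nt  poly-A: ", x$polya_len, " nt\n",
      "  flags: ",
      paste(names(x$flags)[which(x$flags)], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Collapse candidate annotations by identical core sequence
#'
#' Candidates sharing a core amino-acid sequence (e.g. transcript isoforms)
#' collapse into one named entry listing supporting transcripts. Names are
#' assigned deterministically in first-seen order.
#'
#' @param annotations List of `precursor_annotation` objects (optionally
#'   each carrying a `sample` and `source` attribute).
#' @param prefix Name prefix (default "cand").
#' @return Data frame: `name`, `core_seq`, `n_support`, `transcripts`
#'   (comma-separated), `samples` (comma-separated), `junction_is_Ala`,
#'   `stop_is_TGA` (all() over supports).
#' @export
dedupe_candidates <- function(annotations, prefix = "cand") {
  if (length(annotations) == 0L) {
    return(data.frame(name = character(), core_seq = character(),
                      n_support = integer(), transcripts = character(),
                      samples = character(), junction_is_Ala = logical(),
                      stop_is_TGA = logical(), stringsAsFactors = FALSE))
  }
  cores <- vapply(annotations, function(a) a$core, "")
  uniq <- unique(cores)
  rows <- lapply(seq_along(uniq), function(i) {
    idx <- which(cores == uniq[i])
    tx <- vapply(annotations[idx], function(a) a$orf$transcript_id, "")
    smp <- vapply(annotations[idx], function(a) {
      s <- attr(a, "sample"); if (is.null(s)) NA_character_ else s
    }, "")
    data.frame(
      name = paste0(prefix, i), core_seq = uniq[i], n_support = length(idx),
      transcripts = paste(unique(tx), collapse = ","),
      samples = paste(unique(smp[!is.na(smp)]), collapse = ","),
      junction_is_Ala = all(vapply(annotations[idx],
                                   function(a) isTRUE(a$flags[["junction_is_Ala"]]),
                                   logical(1L))),
      stop_is_TGA = all(vapply(annotations[idx],
                               function(a) isTRUE(a$flags[["stop_is_TGA"]]),
                               logical(1L))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
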