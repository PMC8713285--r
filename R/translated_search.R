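# Translated homology search: Smith-Waterman local alignment of a mature
# peptide query against six-frame translations of nucleotide records. This
# is the deterministic, exhaustive stand-in for a tblastn search at desk
# scale: no seeding heuristics and no E-value model, just the optimal local
# alignment per (transcript, frame) with a raw-score cutoff.

.encode_aa <- function(x, alphabet) {
  if (nchar(x) == 0L) return(integer(0))
  ch <- strsplit(x, "")[[1L]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)  # unknown residues score as X
  idx - 1L
}

#' Optimal local alignment of two protein strings
#'
#' Smith-Waterman with affine gaps (a gap of length k costs
#' `gap_open + k * gap_ext`). Traceback is deterministic: ties prefer
#' diagonal, then up (gap in subject), then left; among equal-scoring end
#' cells the alignment with the smallest subject start, then smallest query
#' start, is returned. Residues outside the 20 standard amino acids,
#' `X` and `*` are scored as `X`; `*` scores -4 against everything.
#'
#' @param query,subject Protein strings.
#' @param submat Substitution matrix with AA dimnames
#'   (default [BLOSUM62_MAT]).
#' @param gap_open,gap_ext Affine gap penalties (defaults 11 and 1, the
#'   tblastn defaults for BLOSUM62).
#' @return List with `score`, `query_span`, `subject_span` (0-based
#'   half-open), `aligned_query`, `aligned_subject` (gapped strings with
#'   `-`), and `identity_fraction`. A pair with no positive-scoring
#'   alignment returns score 0 and empty spans.
#' @export
align_local <- function(query, subject, submat = BLOSUM62_MAT,
                        gap_open = 11, gap_ext = 1) {
  alphabet <- rownames(submat)
  qi <- .encode_aa(query, alphabet)
  si <- .encode_aa(subject, alphabet)
  r <- .sw_align_cpp(qi, si, submat, gap_open, gap_ext)
  decode <- function(v) {
    if (length(v) == 0L) return("")
    ch <- ifelse(v < 0L, "-", alphabet[v + 1L])
    paste(ch, collapse = "")
  }
  aq <- decode(r$q_gapped)
  as_ <- decode(r$s_gapped)
  ident <- 0
  if (nchar(aq) > 0L) {
    a <- strsplit(aq, "")[[1L]]
    b <- strsplit(as_, "")[[1L]]
    ident <- sum(a == b & a != "-") / length(a)
  }
  list(score = r$score,
       query_span = c(r$q_start, r$q_end),
       subject_span = c(r$s_start, r$s_end),
       aligned_query = aq, aligned_subject = as_,
       identity_fraction = ident)
}

#' Search nucleotide records with a mature-peptide query
#'
#' Aligns `query` against all six translated frames of every record and
#' reports the best local alignment per (transcript, frame) scoring at
#' least `min_score`. The nucleotide span of each hit is recovered from the
#' frame's codon coordinate map (forward-strand, 0-based half-open).
#'
#' @param query A [mature_peptide()] object or a plain protein string.
#' @param records Data frame of nucleotide records ([read_fasta()]).
#' @param min_score Minimum raw alignment score (default 50).
#' @param submat,gap_open,gap_ext Passed to [align_local()].
#' @return Data frame of hits sorted by score (descending), then
#'   `transcript_id`, then `frame`; columns `query_id`, `transcript_id`,
#'   `frame`, `score`, `identity_fraction`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (protein coords), `nt_start`, `nt_end`, `aligned_query`,
#'   `aligned_subject`.
#' @export
search_transcripts <- function(query, records, min_score = 50,
                               submat = BLOSUM62_MAT,
                               gap_open = 11, gap_ext = 1) {
  stopifnot(nrow(records) > 0L)
  qname <- if (inherits(query, "mature_peptide")) query$name else "query"
  qseq <- if (inherits(query, "mature_peptide")) query$sequence else query
  hits <- list()
  for (i in seq_len(nrow(records))) {
    frames <- six_frame_translate(records$sequence[i])
    for (fr in frames) {
      if (nchar(fr$protein) == 0L) next
      al <- align_local(qseq, fr$protein, submat, gap_open, gap_ext)
      if (al$score < min_score) next
      cs <- fr$codon_starts[(al$subject_span[1] + 1L):al$subject_span[2]]
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = qname, transcript_id = records$id[i], frame = fr$frame,
        score = al$score, identity_fraction = al$identity_fraction,
        q_start = al$query_span[1], q_end = al$query_span[2],
        s_start = al$subject_span[1], s_end = al$subject_span[2],
        nt_start = min(cs), nt_end = max(cs) + 3L,
        aligned_query = al$aligned_query,
        aligned_subject = al$aligned_subject,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(query_id = character(), transcript_id = character(),
                      frame = integer(), score = numeric(),
                      identity_fraction = numeric(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), nt_start = integer(),
                      nt_end = integer(), aligned_query = character(),
                      aligned_subject = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(-out$score, out$transcript_id, out$frame), , drop = FALSE]
}

#' Write a hit table as TSV (tabular-BLAST-like columns)
#'
#' @param hits Data frame from [search_transcripts()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  tab <- data.frame(qid = hits$query_id, tid = hits$transcript_id,
                    frame = hits$frame,
                    pident = round(100 * hits$identity_fraction, 2),
                    score = hits$score,
                    qstart = hits$q_start, qend = hits$q_end,
                    tstart = hits$s_start, tend = hits$s_end,
                    nt_start = hits$nt_start, nt_end = hits$nt_end,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
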