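# Sequence I/O, six-frame translation and ORF extraction.
#
# Conventions used throughout the package:
#  * nucleotide coordinates are 0-based half-open on the FORWARD strand of
#    the stored sequence, for plus and minus frames alike;
#  * frames are +1/+2/+3 (forward, offsets 0/1/2) and -1/-2/-3 (reverse
#    complement, offsets 0/1/2);
#  * the standard genetic code only; codons containing N (or any non-ACGT
#    letter) translate to 'X'.

#' Read a nucleotide FASTA file
#'
#' Parses a FASTA file into a data frame of nucleotide records. Sequences
#' are normalized to uppercase DNA (`U` becomes `T`); characters outside
#' `A,C,G,T,N` raise an error.
#'
#' @param path Path to a FASTA file.
#' @param source_sample Optional sample label attached to every record
#'   (e.g. `"Gb01"`). Defaults to `NA`.
#' @return A data frame with columns `id`, `sequence`, `source_sample`.
#' @export
read_fasta <- function(path, source_sample = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines) | grepl("^>", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      source_sample = character(), stringsAsFactors = FALSE))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA: sequence before first header at line ", line_no[1L])
  }
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_seq <- character(0); cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_id)) return()
    if (length(cur_seq) == 0L) {
      stop("malformed FASTA: header without sequence at line ", cur_line)
    }
    ids <<- c(ids, cur_id)
    seqs <<- c(seqs, paste(cur_seq, collapse = ""))
  }
  for (i in seq_along(lines)) {
    if (is_hdr[i]) {
      flush()
      cur_id <- sub("^>\\s*", "", lines[i])
      cur_id <- sub("\\s.*$", "", cur_id)
      cur_seq <- character(0)
      cur_line <- line_no[i]
    } else {
      cur_seq <- c(cur_seq, gsub("\\s", "", lines[i]))
    }
  }
  flush()
  seqs <- normalize_dna(seqs)
  data.frame(id = ids, sequence = seqs,
             source_sample = rep(source_sample, length(ids)),
             stringsAsFactors = FALSE)
}

#' Normalize a DNA string
#'
#' Uppercases, converts RNA `U` to `T`, and validates the `A,C,G,T,N`
#' alphabet.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Normalized character vector.
#' @export
normalize_dna <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1L], regexpr("[^ACGTN]", x[bad][1L]))
    stop("invalid nucleotide character '", ch, "' in sequence")
  }
  x
}

#' Write sequences to FASTA
#'
#' @param records Data frame with `id` and `sequence` columns (or a named
#'   character vector).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' @param seq DNA string(s) over `A,C,G,T,N`.
#' @return Reverse complement string(s).
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Translate a DNA string in a single frame
#'
#' Translates from the first position of `seq`, dropping a trailing partial
#' codon. Stops render as `*`; codons containing `N` render as `X`.
#'
#' @param seq DNA string.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_STD[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide record in all six frames. Each frame carries a
#' coordinate map giving, for every protein position, the 0-based half-open
#' start of its 3-nt codon interval on the forward strand.
#'
#' @param record A one-row data frame from [read_fasta()], or a single DNA
#'   string.
#' @return A list of six entries named `"+1" ... "-3"`, each a list with
#'   `frame` (integer in ±1..3), `protein` (AA string, stops as `*`), and
#'   `codon_starts` (integer vector, forward-strand start of each codon).
#' @export
six_frame_translate <- function(record) {
  seq <- if (is.character(record)) record[[1L]] else record$sequence[[1L]]
  L <- nchar(seq)
  out <- vector("list", 6L)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (L < 3L) {
    warning("sequence shorter than 3 nt; all frames empty")
    for (k in 1:6) {
      f <- if (k <= 3) k else -(k - 3L)
      out[[k]] <- list(frame = f, protein = "", codon_starts = integer(0))
    }
    return(out)
  }
  rc <- revcomp(seq)
  for (off in 0:2) {
    n <- (L - off) %/% 3L
    prot <- translate_nt(substr(seq, off + 1L, L))
    out[[off + 1L]] <- list(
      frame = off + 1L, protein = prot,
      codon_starts = off + 3L * (seq_len(n) - 1L)
    )
    nr <- (L - off) %/% 3L
    protr <- translate_nt(substr(rc, off + 1L, L))
    # codon i (0-based) on the rc covers rc[off+3i, off+3i+3) which maps to
    # forward-strand interval [L - off - 3i - 3, L - off - 3i)
    out[[off + 4L]] <- list(
      frame = -(off + 1L), protein = protr,
      codon_starts = L - off - 3L * seq_len(nr)
    )
  }
  out
}

#' Extract open reading frames
#'
#' Finds, in all six frames, maximal `M...(stop|end)` segments. By default,
#' ORFs sharing a stop codon report only the longest (leftmost start
#' methionine); with `all_starts = TRUE` every internal M yields an ORF.
#' Coordinates cover the coding region excluding the stop codon and are
#' 0-based half-open on the forward strand.
#'
#' @param record One-row data frame from [read_fasta()] or a DNA string.
#' @param min_protein_len Minimum protein length to report (default 50).
#' @param all_starts Report every start methionine per stop (default FALSE).
#' @return Data frame with columns `transcript_id`, `frame`, `nt_start`,
#'   `nt_end`, `protein`, `stop_codon` (empty string when the ORF runs off
#'   the end of the sequence).
#' @export
extract_orfs <- function(record, min_protein_len = 50L, all_starts = FALSE) {
  if (is.character(record)) {
    record <- data.frame(id = "seq1", sequence = record,
                         stringsAsFactors = FALSE)
  }
  id <- record$id[[1L]]
  seq <- record$sequence[[1L]]
  empty <- data.frame(transcript_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      protein = character(), stop_codon = character(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 3L) return(empty)
  frames <- six_frame_translate(seq)
  res <- list()
  for (fr in frames) {
    prot <- fr$protein
    if (nchar(prot) == 0L) next
    aa <- strsplit(prot, "")[[1L]]
    n <- length(aa)
    stop_idx <- c(which(aa == "*"), n + 1L)  # n+1 marks run-off-the-end
    seg_start <- 1L
    for (sp in stop_idx) {
      if (sp > seg_start) {
        ms <- which(aa[seg_start:(sp - 1L)] == "M") + seg_start - 1L
        if (length(ms) > 0L) {
          starts <- if (all_starts) ms else ms[1L]
          for (m in starts) {
            plen <- sp - m
            if (plen >= min_protein_len) {
              cs <- fr$codon_starts
              ints <- cs[m:(sp - 1L)]
              stop_cod <- ""
              if (sp <= n) {
                sc_start <- cs[sp]
                stop_cod <- substr(seq, sc_start + 1L, sc_start + 3L)
                if (fr$frame < 0L) stop_cod <- revcomp(stop_cod)
              }
              res[[length(res) + 1L]] <- data.frame(
                transcript_id = id, frame = fr$frame,
                nt_start = min(ints), nt_end = max(ints) + 3L,
                protein = paste(aa[m:(sp - 1L)], collapse = ""),
                stop_codon = stop_cod, stringsAsFactors = FALSE)
            }
          }
        }
      }
      seg_start <- sp + 1L
    }
  }
  if (length(res) == 0L) return(empty)
  do.call(rbind, res)
}

#' Write an ORF table as TSV
#'
#' @param orfs Data frame from [extract_orfs()].
#' @param path Output path.
#' @export
write_orf_table <- function(orfs, path) {
  cols <- c("transcript_id", "frame", "nt_start", "nt_end", "stop_codon",
            "protein")
  utils::write.table(orfs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
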