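# MS peak-list loading, theoretical-ion matching, presence calling, and
# the samples x peptides evidence matrix.
#
# Presence reasoning is m/z-based only: a peptide is called present in a
# sample when at least `min_charges` distinct charge states of its
# theoretical ions each match an observed peak within tolerance. Isobaric
# peptides (e.g. Leu/Ile variants) match the same peaks and are flagged
# mutually ambiguous; intensity is carried through but never used.

#' Read an MS peak list
#'
#' Supports two-column CSV (`mz,intensity`, header optional) and MGF
#' (peaks of all `BEGIN IONS`/`END IONS` blocks pooled). Peaks are sorted
#' ascending by m/z.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"csv"`, or `"mgf"`.
#' @param sample Sample label; defaults to the file name stem (a leading
#'   `peaks_` prefix is stripped).
#' @return Object of class `peak_list`: list with `sample` and `peaks`
#'   (data frame `mz`, `intensity`).
#' @export
read_peak_list <- function(path, format = c("auto", "csv", "mgf"),
                           sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak list not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  }
  if (is.null(sample)) {
    sample <- sub("^peaks[_-]", "", tools::file_path_sans_ext(basename(path)))
  }
  lines <- readLines(path, warn = FALSE)
  mzv <- numeric(0); inty <- numeric(0)
  if (format == "csv") {
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) next
      parts <- trimws(strsplit(ln, ",")[[1L]])
      v <- suppressWarnings(as.numeric(parts[1L]))
      if (is.na(v)) {
        if (i == 1L) next  # header row
        stop("non-numeric m/z at line ", i, " of ", path)
      }
      mzv <- c(mzv, v)
      inty <- c(inty, if (length(parts) > 1L)
        suppressWarnings(as.numeric(parts[2L])) else NA_real_)
    }
  } else {
    in_block <- FALSE
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) next
      if (ln == "BEGIN IONS") { in_block <- TRUE; next }
      if (ln == "END IONS") { in_block <- FALSE; next }
      if (!in_block || grepl("=", ln, fixed = TRUE)) next
      parts <- strsplit(ln, "[ \t]+")[[1L]]
      v <- suppressWarnings(as.numeric(parts[1L]))
      if (is.na(v)) stop("non-numeric m/z at line ", i, " of ", path)
      mzv <- c(mzv, v)
      inty <- c(inty, if (length(parts) > 1L)
        suppressWarnings(as.numeric(parts[2L])) else NA_real_)
    }
  }
  if (any(mzv <= 0)) stop("non-positive m/z in ", path)
  o <- order(mzv)
  structure(list(sample = sample,
                 peaks = data.frame(mz = mzv[o], intensity = inty[o])),
            class = "peak_list")
}

#' Write a peak list as CSV
#'
#' @param peak_list A `peak_list`.
#' @param path Output path.
#' @export
write_peak_list <- function(peak_list, path) {
  utils::write.csv(peak_list$peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match theoretical ions against a peak list
#'
#' For every (peptide, charge) whose theoretical m/z lies within tolerance
#' of at least one observed peak, reports a match against the nearest such
#' peak (ties: lower m/z wins). `ambiguous_with` lists all other peptides
#' with a theoretical m/z at any charge within tolerance of the same
#' observed peak.
#'
#' @param ion_sets List of `theoretical_ions` objects.
#' @param peak_list A `peak_list`.
#' @param tolerance Matching tolerance (default 0.05).
#' @param mode `"da"` (absolute Th, default) or `"ppm"` (relative to the
#'   theoretical m/z).
#' @return Data frame: `peptide_name`, `charge`, `theoretical_mz`,
#'   `observed_mz`, `intensity`, `error_da`, `error_ppm`, `ambiguous_with`
#'   (comma-separated, empty when unambiguous).
#' @export
match_ions <- function(ion_sets, peak_list, tolerance = 0.05,
                       mode = c("da", "ppm")) {
  mode <- match.arg(mode)
  if (inherits(ion_sets, "theoretical_ions")) ion_sets <- list(ion_sets)
  peaks <- peak_list$peaks
  within_tol <- function(theo, obs) {
    if (mode == "da") abs(theo - obs) <= tolerance
    else abs(theo - obs) / theo * 1e6 <= tolerance
  }
  rows <- list()
  for (is_ in ion_sets) {
    for (k in seq_along(is_$mz_by_charge)) {
      theo <- is_$mz_by_charge[[k]]
      z <- as.integer(sub("z", "", names(is_$mz_by_charge)[k]))
      if (nrow(peaks) == 0L) next
      ok <- within_tol(theo, peaks$mz)
      if (!any(ok)) next
      cand <- which(ok)
      d <- abs(peaks$mz[cand] - theo)
      best <- cand[which(d == min(d))]
      best <- best[which.min(peaks$mz[best])]  # equidistant: lower m/z wins
      obs <- peaks$mz[best]
      # other peptides with any-charge theoretical m/z within tol of obs
      amb <- character(0)
      for (other in ion_sets) {
        if (identical(other$peptide_name, is_$peptide_name)) next
        if (any(within_tol(other$mz_by_charge, obs))) {
          amb <- c(amb, other$peptide_name)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_name = is_$peptide_name, charge = z, theoretical_mz = theo,
        observed_mz = obs, intensity = peaks$intensity[best],
        error_da = obs - theo, error_ppm = (obs - theo) / theo * 1e6,
        ambiguous_with = paste(sort(unique(amb)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peptide_name = character(), charge = integer(),
                      theoretical_mz = numeric(), observed_mz = numeric(),
                      intensity = numeric(), error_da = numeric(),
                      error_ppm = numeric(), ambiguous_with = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Call peptide presence from ion matches
#'
#' A peptide is present when it matches at >= `min_charges` distinct charge
#' states; it is additionally flagged ambiguous when every supporting match
#' is shared with an isobaric peptide.
#'
#' @param matches Data frame from [match_ions()].
#' @param ion_sets The ion sets that were matched (used to enumerate
#'   peptides with zero matches).
#' @param min_charges Minimum distinct charge states (default 1).
#' @return Data frame: `peptide_name`, `present`, `ambiguous`, `n_charges`.
#' @export
presence_call <- function(matches, ion_sets = NULL, min_charges = 1L) {
  stopifnot(min_charges >= 1L)
  peptides <- unique(matches$peptide_name)
  if (!is.null(ion_sets)) {
    if (inherits(ion_sets, "theoretical_ions")) ion_sets <- list(ion_sets)
    peptides <- unique(c(vapply(ion_sets, `[[`, "", "peptide_name"),
                         peptides))
  }
  rows <- lapply(peptides, function(p) {
    sub <- matches[matches$peptide_name == p, , drop = FALSE]
    nz <- length(unique(sub$charge))
    present <- nz >= min_charges
    ambiguous <- present && nrow(sub) > 0L && all(nzchar(sub$ambiguous_with))
    data.frame(peptide_name = p, present = present, ambiguous = ambiguous,
               n_charges = nz, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(peptide_name = character(), present = logical(),
                      ambiguous = logical(), n_charges = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build the samples x peptides presence matrix
#'
#' Merges sequence-level evidence (candidates found in transcriptome or
#' genome assemblies) with MS-level evidence (presence calls per sample)
#' into one long-format evidence table.
#'
#' @param sequence_evidence Data frame with columns `sample`, `peptide`,
#'   `source` (`"transcriptome"` or `"genome"`). May have zero rows.
#' @param ms_calls Data frame with columns `sample`, `peptide_name`,
#'   `present`, `ambiguous` (e.g. [presence_call()] output with a `sample`
#'   column added). May be NULL (sequence-only mode).
#' @param samples Optional explicit sample universe; labels outside it
#'   raise an error.
#' @return Data frame of class `presence_matrix`: `sample`, `peptide`,
#'   `sequence_evidence`, `genome_evidence`, `ms_evidence`, `ms_ambiguous`.
#' @export
build_presence_matrix <- function(sequence_evidence, ms_calls = NULL,
                                  samples = NULL) {
  seen <- unique(c(sequence_evidence$sample,
                   if (!is.null(ms_calls)) ms_calls$sample))
  if (is.null(samples)) samples <- sort(seen)
  unknown <- setdiff(seen, samples)
  if (length(unknown) > 0L) {
    stop("unknown sample label(s): ", paste(unknown, collapse = ", "))
  }
  peptides <- unique(c(sequence_evidence$peptide,
                       if (!is.null(ms_calls)) ms_calls$peptide_name))
  if (length(samples) == 0L || length(peptides) == 0L) {
    out <- data.frame(sample = character(), peptide = character(),
                      sequence_evidence = logical(),
                      genome_evidence = logical(), ms_evidence = logical(),
                      ms_ambiguous = logical(), stringsAsFactors = FALSE)
    class(out) <- c("presence_matrix", class(out))
    return(out)
  }
  grid <- expand.grid(sample = samples, peptide = peptides,
                      stringsAsFactors = FALSE)
  grid$sequence_evidence <- FALSE
  grid$genome_evidence <- FALSE
  grid$ms_evidence <- FALSE
  grid$ms_ambiguous <- FALSE
  for (i in seq_len(nrow(sequence_evidence))) {
    r <- sequence_evidence[i, ]
    j <- grid$sample == r$sample & grid$peptide == r$peptide
    if (identical(r$source, "genome")) grid$genome_evidence[j] <- TRUE
    else grid$sequence_evidence[j] <- TRUE
  }
  if (!is.null(ms_calls)) {
    for (i in seq_len(nrow(ms_calls))) {
      r <- ms_calls[i, ]
      j <- grid$sample == r$sample & grid$peptide == r$peptide_name
      if (isTRUE(r$present)) grid$ms_evidence[j] <- TRUE
      if (isTRUE(r$ambiguous)) grid$ms_ambiguous[j] <- TRUE
    }
  }
  class(grid) <- c("presence_matrix", class(grid))
  grid
}

#' Render a presence matrix as a glyph grid
#'
#' Glyph legend: `#` sequence evidence (transcriptome), `G` genome-only
#' sequence evidence, `o` MS evidence, `?` MS evidence that is isobarically
#' ambiguous, `.` absent. Multiple flags concatenate.
#'
#' @param x A `presence_matrix`.
#' @param ... Unused.
#' @export
format.presence_matrix <- function(x, ...) {
  samples <- unique(x$sample); peptides <- unique(x$peptide)
  lines <- c(paste(c(format("", width = 10),
                     format(peptides, width = 10)), collapse = " "))
  for (s in samples) {
    cells <- vapply(peptides, function(p) {
      r <- x[x$sample == s & x$peptide == p, , drop = FALSE]
      if (nrow(r) == 0L) return(".")
      g <- c(if (r$sequence_evidence) "#", if (r$genome_evidence) "G",
             if (r$ms_evidence && !r$ms_ambiguous) "o",
             if (r$ms_ambiguous) "?")
      if (length(g) == 0L) "." else paste(g, collapse = "")
    }, "")
    lines <- c(lines, paste(c(format(s, width = 10),
                              format(cells, width = 10)), collapse = " "))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a presence matrix as TSV
#'
#' @param x A `presence_matrix`.
#' @param path Output path.
#' @export
write_presence_matrix <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
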