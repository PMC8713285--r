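# End-to-end orchestration: translated search -> framework mining ->
# precursor annotation -> candidate dedup -> ion table -> MS matching ->
# presence matrix. All intermediates are plain TSV/CSV/JSON so any stage
# can be inspected or replaced; a run log captures config and seed.

#' Pipeline configuration
#'
#' @param queries Path to a protein FASTA of mature-peptide queries, or a
#'   list of [mature_peptide()] objects.
#' @param assemblies Named character vector of transcriptome FASTA paths
#'   (names = sample labels; unnamed paths use the file stem, with a
#'   leading `transcripts_` stripped).
#' @param genome_assemblies Optional named vector of genome FASTA paths.
#' @param peaks Optional named character vector of peak-list paths
#'   (CSV or MGF; names = sample labels).
#' @param out_dir Output directory (created on run).
#' @param min_score Alignment score cutoff (default 50).
#' @param tolerance,tolerance_mode MS matching tolerance (default 0.05 Da).
#' @param signal_len Signal peptide length (default 19).
#' @param framework_slack Per-gap framework slack (default 0).
#' @param min_charges Charge states required for an MS presence call
#'   (default 1).
#' @param seed Seed recorded in the run log (the discovery pipeline itself
#'   is deterministic; the seed matters when the config is used to
#'   regenerate synthetic inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(queries, assemblies, genome_assemblies = NULL,
                            peaks = NULL, out_dir = tempfile("bdr_run_"),
                            min_score = 50, tolerance = 0.05,
                            tolerance_mode = c("da", "ppm"),
                            signal_len = 19L, framework_slack = 0L,
                            min_charges = 1L, seed = NA_integer_) {
  tolerance_mode <- match.arg(tolerance_mode)
  label <- function(paths, strip) {
    if (is.null(paths)) return(NULL)
    nm <- names(paths)
    if (is.null(nm)) nm <- rep("", length(paths))
    auto <- sub(paste0("^", strip, "[_-]"), "",
                tools::file_path_sans_ext(basename(paths)))
    nm[nm == ""] <- auto[nm == ""]
    names(paths) <- nm
    paths
  }
  if (is.character(queries) && !file.exists(queries)) {
    stop("queries file not found: ", queries)
  }
  for (p in c(assemblies, genome_assemblies, peaks)) {
    if (!file.exists(p)) stop("input path not found: ", p)
  }
  structure(list(queries = queries,
                 assemblies = label(assemblies, "transcripts"),
                 genome_assemblies = label(genome_assemblies, "genome"),
                 peaks = label(peaks, "peaks"),
                 out_dir = out_dir, min_score = min_score,
                 tolerance = tolerance, tolerance_mode = tolerance_mode,
                 signal_len = as.integer(signal_len),
                 framework_slack = as.integer(framework_slack),
                 min_charges = as.integer(min_charges),
                 seed = seed),
            class = "pipeline_config")
}

.read_queries <- function(queries) {
  if (!is.character(queries)) {
    if (inherits(queries, "mature_peptide")) return(list(queries))
    return(queries)
  }
  lines <- readLines(queries, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers in query file")
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    id <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr[i]]))
    seq <- toupper(gsub("\\s", "", paste(
      lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)], collapse = "")))
    # assume the family connectivity when the query fits the barrettide
    # framework, otherwise no disulfide annotation
    mp <- tryCatch({
      bc <- barrettide_c()
      if (matches_framework(seq, framework_of(bc))) {
        cys <- which(strsplit(seq, "")[[1L]] == "C")
        mature_peptide(id, seq, list(cys[c(1L, 4L)], cys[c(2L, 3L)]))
      } else mature_peptide(id, seq)
    }, error = function(e) mature_peptide(id, seq))
    out[[length(out) + 1L]] <- mp
  }
  out
}

# mine one assembly with one query; returns list of annotated precursors
.mine_assembly <- function(query, records, sample, source, cfg) {
  hits <- search_transcripts(query, records, min_score = cfg$min_score)
  anns <- list()
  fw <- framework_of(query)
  for (tid in unique(hits$transcript_id)) {
    rec <- records[records$id == tid, , drop = FALSE]
    cleaned <- clean_hit_sequence(
      hits$aligned_subject[hits$transcript_id == tid][1L])
    if (!matches_framework(cleaned, fw, slack = cfg$framework_slack)) next
    orfs <- extract_orfs(rec, min_protein_len = cfg$signal_len + 1L + nchar(query$sequence))
    for (k in seq_len(nrow(orfs))) {
      span <- locate_core(orfs$protein[k], query, min_score = cfg$min_score)
      if (is.null(span)) next
      ann <- tryCatch(
        annotate_precursor(orfs[k, ], span, rec,
                           signal_len = cfg$signal_len),
        error = function(e) NULL)
      if (is.null(ann)) next
      if (!matches_framework(ann$core, fw, slack = cfg$framework_slack)) next
      attr(ann, "sample") <- sample
      attr(ann, "source") <- source
      anns[[length(anns) + 1L]] <- ann
    }
  }
  anns
}

#' Run the discovery pipeline
#'
#' Executes search, mining, annotation, dedup, ion-table computation, MS
#' matching and presence-matrix assembly, writing all artifacts to
#' `config$out_dir`: `candidates.tsv`, `ions.tsv`, `matches.tsv`,
#' `presence_matrix.tsv`, and `run_log.json`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `candidates`, `annotations`,
#'   `ion_table`, `matches`, `presence`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  queries <- .read_queries(cfg$queries)

  anns <- list()
  read_all <- function(paths, source) {
    for (s in names(paths)) {
      records <- read_fasta(paths[[s]], source_sample = s)
      for (q in queries) {
        anns <<- c(anns, .mine_assembly(q, records, s, source, cfg))
      }
    }
  }
  read_all(cfg$assemblies, "transcriptome")
  if (!is.null(cfg$genome_assemblies)) read_all(cfg$genome_assemblies, "genome")

  candidates <- dedupe_candidates(anns)

  # sequence evidence table
  seq_ev <- if (length(anns) > 0L) {
    do.call(rbind, lapply(seq_along(anns), function(i) {
      core <- anns[[i]]$core
      data.frame(sample = attr(anns[[i]], "sample"),
                 peptide = candidates$name[candidates$core_seq == core][1L],
                 source = attr(anns[[i]], "source"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(sample = character(), peptide = character(),
               source = character(), stringsAsFactors = FALSE)
  }

  # theoretical ions: candidate cores inherit the query family's disulfide
  # count when their framework is intact
  cand_peps <- lapply(seq_len(nrow(candidates)), function(i) {
    seq <- candidates$core_seq[i]
    cys <- which(strsplit(seq, "")[[1L]] == "C")
    pairs <- if (length(cys) == 4L)
      list(cys[c(1L, 4L)], cys[c(2L, 3L)]) else list()
    mature_peptide(candidates$name[i], seq, pairs)
  })
  itab <- ion_table(cand_peps)
  ion_sets <- lapply(cand_peps, theoretical_ions)

  matches <- NULL; ms_calls <- NULL
  if (!is.null(cfg$peaks) && length(ion_sets) > 0L) {
    all_matches <- list(); all_calls <- list()
    for (s in names(cfg$peaks)) {
      pl <- read_peak_list(cfg$peaks[[s]], sample = s)
      m <- match_ions(ion_sets, pl, tolerance = cfg$tolerance,
                      mode = cfg$tolerance_mode)
      calls <- presence_call(m, ion_sets, min_charges = cfg$min_charges)
      if (nrow(m) > 0L) { m$sample <- s; all_matches[[s]] <- m }
      calls$sample <- s
      all_calls[[s]] <- calls
    }
    matches <- if (length(all_matches)) do.call(rbind, all_matches) else
      data.frame()
    ms_calls <- do.call(rbind, all_calls)
  }

  presence <- build_presence_matrix(seq_ev, ms_calls)

  utils::write.table(candidates, file.path(cfg$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ion_table(itab, file.path(cfg$out_dir, "ions.tsv"))
  if (!is.null(matches)) {
    utils::write.table(matches, file.path(cfg$out_dir, "matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_presence_matrix(presence, file.path(cfg$out_dir,
                                            "presence_matrix.tsv"))
  log <- list(package_version = as.character(utils::packageVersion("barrettideR")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = cfg[setdiff(names(cfg), "queries")],
              n_queries = length(queries),
              n_candidates = nrow(candidates))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  structure(list(candidates = candidates, annotations = anns,
                 ion_table = itab, matches = matches, presence = presence,
                 out_dir = cfg$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run:", nrow(x$candidates), "candidate peptide(s)\n")
  if (nrow(x$candidates) > 0L) {
    print(x$candidates[, c("name", "core_seq", "n_support")])
  }
  cat("\npresence matrix:\n")
  print(x$presence)
  invisible(x)
}

# ---------------------------------------------------------------------------
# command-line interface ----------------------------------------------------

.cli_opts <- function(args) {
  opts <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        opts[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `search` (hit
#' table for a query vs an assembly), `mine` (candidate table), `ions`
#' (charge-state table for peptide FASTA), `match` (ion matches vs a peak
#' list), `run` (full pipeline). Designed for
#' `Rscript -e 'barrettideR::bdr_cli()' <subcommand> ...`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result object.
#' @export
bdr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: bdr_cli <simulate|search|mine|ions|match|run> [--flags]\n")
    return(invisible(NULL))
  }
  cmd <- args[1L]
  parsed <- .cli_opts(args[-1L])
  o <- parsed$opts
  res <- switch(
    cmd,
    simulate = {
      if (is.null(o$seed)) stop("simulate requires --seed")
      cfg <- sim_config(seed = as.integer(o$seed),
                        n_precursors = .cli_num(o, "n-precursors", 5),
                        n_decoys = .cli_num(o, "n-decoys", 100),
                        core_mutation_rate = .cli_num(o, "mutation-rate", 0),
                        peak_noise_count = .cli_num(o, "noise", 200),
                        mz_jitter_sd = .cli_num(o, "jitter", 0.01),
                        n_samples = .cli_num(o, "n-samples", 3))
      simulate_dataset(cfg, out_dir = o$out %||% "sim_out")
    },
    search = {
      recs <- read_fasta(o$assembly)
      q <- .read_queries(o$queries)[[1L]]
      hits <- search_transcripts(q, recs,
                                 min_score = .cli_num(o, "min-score", 50))
      if (!is.null(o$out)) write_hit_table(hits, o$out)
      hits
    },
    mine = {
      cfg <- pipeline_config(queries = o$queries, assemblies = o$assembly,
                             out_dir = o$out %||% tempfile("bdr_mine_"),
                             min_score = .cli_num(o, "min-score", 50))
      run_pipeline(cfg)$candidates
    },
    ions = {
      qs <- .read_queries(o$queries)
      tab <- ion_table(qs)
      if (!is.null(o$out)) write_ion_table(tab, o$out)
      tab
    },
    match = {
      qs <- .read_queries(o$queries)
      pl <- read_peak_list(o$peaks)
      m <- match_ions(lapply(qs, theoretical_ions), pl,
                      tolerance = .cli_num(o, "tol-da", 0.05))
      if (!is.null(o$out)) {
        utils::write.table(m, o$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      m
    },
    run = {
      asm <- strsplit(o$assemblies, ",")[[1L]]
      pk <- if (!is.null(o$peaks)) strsplit(o$peaks, ",")[[1L]] else NULL
      gn <- if (!is.null(o$genome)) strsplit(o$genome, ",")[[1L]] else NULL
      cfg <- pipeline_config(
        queries = o$queries, assemblies = asm, genome_assemblies = gn,
        peaks = pk, out_dir = o$out %||% "bdr_out",
        min_score = .cli_num(o, "min-score", 50),
        tolerance = .cli_num(o, "tol-da", 0.05),
        signal_len = .cli_num(o, "signal-len", 19),
        min_charges = .cli_num(o, "min-charges", 1),
        seed = as.integer(.cli_num(o, "seed", NA)))
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
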