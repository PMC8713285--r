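# Monoisotopic masses and charge-state m/z for disulfide-oxidized peptides.
#
# neutral M = sum(residue masses) + water - 2 * n_disulfides * H
# m/z(z)    = (M + z * m_proton) / z
#
# Constants (see constants.R) are the standard monoisotopic values; table
# rendering rounds half-to-even at 4 decimals, internal values stay at full
# double precision.

#' Monoisotopic neutral mass of a peptide
#'
#' @param sequence AA string over the 20 standard residues.
#' @param n_disulfides Number of disulfide bonds formed (each removes two
#'   hydrogen atoms). Default 0 (fully reduced).
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(sequence, n_disulfides = 0L) {
  ch <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!(ch %in% names(AA_MONO)))
  if (length(bad) > 0L) {
    stop("nonstandard residue '", ch[bad[1L]], "' at position ", bad[1L])
  }
  n_cys <- sum(ch == "C")
  if (2L * n_disulfides > n_cys) {
    stop("too many disulfides: ", n_disulfides, " bonds need ",
         2L * n_disulfides, " Cys, sequence has ", n_cys)
  }
  sum(AA_MONO[ch]) + MASS_WATER - 2 * n_disulfides * MASS_H
}

#' m/z of a protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z Positive integer charge.
#' @return m/z in Th: `(M + z * m_proton) / z`.
#' @export
mz <- function(neutral_mass, z) {
  if (any(z <= 0)) stop("charge must be >= 1")
  (neutral_mass + z * MASS_PROTON) / z
}

#' Theoretical ion set for one peptide
#'
#' @param peptide A [mature_peptide()] (its `n_disulfides` is used) or an
#'   AA string.
#' @param n_disulfides Overrides/sets the disulfide count for plain strings.
#' @param charges Charge states (default 1:4).
#' @return Object of class `theoretical_ions`: list with `peptide_name`,
#'   `sequence`, `neutral_mass_oxidized`, `mz_by_charge` (named numeric),
#'   `n_disulfides`.
#' @export
theoretical_ions <- function(peptide, n_disulfides = NULL, charges = 1:4) {
  if (inherits(peptide, "mature_peptide")) {
    nm <- peptide$name; sq <- peptide$sequence
    nd <- if (is.null(n_disulfides)) peptide$n_disulfides else n_disulfides
  } else {
    nm <- "peptide"; sq <- toupper(peptide)
    nd <- if (is.null(n_disulfides)) 0L else n_disulfides
  }
  M <- monoisotopic_mass(sq, nd)
  mzs <- mz(M, charges)
  names(mzs) <- paste0("z", charges)
  structure(list(peptide_name = nm, sequence = sq,
                 neutral_mass_oxidized = M, mz_by_charge = mzs,
                 n_disulfides = nd),
            class = "theoretical_ions")
}

#' @export
print.theoretical_ions <- function(x, ...) {
  cat("theoretical ions:", x$peptide_name, "\n  neutral (oxidized):",
      format(round(x$neutral_mass_oxidized, 4), nsmall = 4), "Da\n")
  for (z in names(x$mz_by_charge)) {
    cat("  [M+", sub("z", "", z), "H]", sub("z", "", z), "+ : ",
        format(round(x$mz_by_charge[[z]], 4), nsmall = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Ion table for a set of peptides
#'
#' Computes, for every peptide, the oxidized monoisotopic mass and m/z at
#' charges 1-4 (the layout of a standard charge-state table).
#'
#' @param peptides List of [mature_peptide()] objects.
#' @param charges Charge states (default 1:4).
#' @return Data frame with columns `peptide`, `MH1`, `MH2`, `MH3`, `MH4`
#'   (full precision; round at rendering), `n_disulfides`.
#' @export
ion_table <- function(peptides, charges = 1:4) {
  if (inherits(peptides, "mature_peptide")) peptides <- list(peptides)
  if (length(peptides) == 0L) {
    out <- data.frame(peptide = character(), stringsAsFactors = FALSE)
    for (z in charges) out[[paste0("MH", z)]] <- numeric(0)
    out$n_disulfides <- integer(0)
    return(out)
  }
  rows <- lapply(peptides, function(p) {
    ti <- theoretical_ions(p, charges = charges)
    row <- data.frame(peptide = ti$peptide_name, stringsAsFactors = FALSE)
    for (i in seq_along(charges)) {
      row[[paste0("MH", charges[i])]] <- ti$mz_by_charge[[i]]
    }
    row$n_disulfides <- ti$n_disulfides
    row
  })
  do.call(rbind, rows)
}

#' Write an ion table as TSV, rounded to 4 decimals
#'
#' @param tab Data frame from [ion_table()].
#' @param path Output path.
#' @export
write_ion_table <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1L)) & names(tab) != "n_disulfides"
  tab[num] <- lapply(tab[num], function(v) formatC(round(v, 4), format = "f",
                                                   digits = 4))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Isobaric canonical key
#'
#' Replaces every Ile with Leu (identical elemental composition, hence
#' identical monoisotopic mass), so MS-indistinguishable sequences share a
#' key.
#'
#' @param sequence AA string.
#' @return Canonical key string.
#' @export
isobaric_key <- function(sequence) {
  gsub("I", "L", toupper(sequence))
}

#' Are two peptides isobaric?
#'
#' TRUE iff the monoisotopic masses of the Leu/Ile-canonicalized sequences
#' agree to within 1e-9 Da.
#'
#' @param a,b AA strings or [mature_peptide()] objects.
#' @return Logical.
#' @export
are_isobaric <- function(a, b) {
  sa <- if (inherits(a, "mature_peptide")) a$sequence else a
  sb <- if (inherits(b, "mature_peptide")) b$sequence else b
  abs(monoisotopic_mass(isobaric_key(sa)) -
        monoisotopic_mass(isobaric_key(sb))) <= 1e-9
}
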