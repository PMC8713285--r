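# Physical constants and reference tables.
#
# The monoisotopic residue masses are the standard values (Unimod/IUPAC
# elemental compositions evaluated with CODATA atomic masses). Together with
# the proton, hydrogen and water constants below they reproduce published
# charge-state m/z tables for oxidized cystine-containing peptides to four
# printed decimals.

#' Monoisotopic residue masses
#'
#' Named numeric vector of the 20 standard amino-acid residue masses in Da
#' (monoisotopic, residue = amino acid minus water).
#'
#' @format Named numeric vector of length 20.
#' @export
AA_MONO <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' Mass constants (Da)
#'
#' `MASS_PROTON`: proton; `MASS_H`: hydrogen atom; `MASS_WATER`: water.
#' Each disulfide bond removes two hydrogen atoms from the reduced peptide.
#'
#' @name mass-constants
#' @export
MASS_PROTON <- 1.007276466

#' @rdname mass-constants
#' @export
MASS_H <- 1.0078250319

#' @rdname mass-constants
#' @export
MASS_WATER <- 18.0105646863

# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# aa -> synonymous codons (stops excluded)
SYNONYMOUS_CODONS <- split(
  names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"],
  GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]
)

# BLOSUM62, standard 24-letter version (A..V plus B, J, Z, X, *), with the
# stop row/column overridden to -4 everywhere so local alignments never
# extend through a translated stop codon.
.blosum62_build <- function() {
  letters24 <- strsplit("ARNDCQEGHILKMFPSTWYVBJZX*", "")[[1]]
  vals <- c(
    4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,-2,-1,-1,-1,-4,
    -1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,-1,-2,0,-1,-4,
    -2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,4,-3,0,-1,-4,
    -2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,4,-3,1,-1,-4,
    0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-1,-3,-1,-4,
    -1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,0,-2,4,-1,-4,
    -1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,1,-3,4,-1,-4,
    0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,-1,-4,-2,-1,-4,
    -2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,0,-3,0,-1,-4,
    -1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,-3,3,-3,-1,-4,
    -1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,-4,3,-3,-1,-4,
    -1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,0,-3,1,-1,-4,
    -1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,-3,2,-1,-1,-4,
    -2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,-3,0,-3,-1,-4,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,-2,-3,-1,-1,-4,
    1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,0,-2,0,-1,-4,
    0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,-1,-1,-1,-1,-4,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,-4,-2,-2,-1,-4,
    -2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,-3,-1,-2,-1,-4,
    0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4,-3,2,-2,-1,-4,
    -2,-1,4,4,-3,0,1,-1,0,-3,-4,0,-3,-3,-2,0,-1,-4,-3,-3,4,-3,0,-1,-4,
    -1,-2,-3,-3,-1,-2,-3,-4,-3,3,3,-3,2,0,-3,-2,-1,-2,-1,2,-3,3,-3,-1,-4,
    -1,0,0,1,-3,4,4,-2,0,-3,-3,1,-1,-3,-1,0,-1,-2,-2,-2,0,-3,4,-1,-4,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-4,
    -4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4
  )
  m <- matrix(as.integer(vals), nrow = 25, ncol = 25, byrow = TRUE,
              dimnames = list(letters24, letters24))
  m
}

#' BLOSUM62 substitution matrix
#'
#' Standard BLOSUM62 (24-letter alphabet plus stop), with the `*` row and
#' column set to -4 against everything so that translated stop codons
#' terminate rather than extend local alignments.
#'
#' @format Integer matrix with amino-acid row/column names.
#' @export
BLOSUM62_MAT <- .blosum62_build()

#' Printed barrettide C mature sequence
#'
#' The 31-residue mature barrettide C peptide (disulfide connectivity
#' I-IV, II-III, i.e. Cys5-Cys23 and Cys7-Cys18).
#'
#' @export
BARRETTIDE_C_SEQ <- "NVVPCFCVEDETSGAKTCIPDNCDASRGTNP"

#' Barrettide precursor signal-peptide motifs
#'
#' The two observed 19-residue signal peptide variants of barrettide
#' precursors.
#'
#' @export
SIGNAL_MOTIFS <- c("MATKVALLVVSALIAVAAA", "MAIKVALLAVSALIAVAAA")

# Regular expression form of the signal motif (two-variant consensus).
SIGNAL_MOTIF_REGEX <- "^MA[TI]KVALL[VA]VSALIAVAAA"

# Fixed 33-nt conserved 3'UTR used by the simulator for every precursor
# transcript (the family shares a conserved ~33-nt 3'UTR; the actual
# sequence is arbitrary but constant so conservation is emulated).
CONSERVED_UTR3 <- "TTGCACTAGGTAACCTTGAGCATCACGTGGATT"

# Trailing run of >= POLYA_MIN_RUN adenines counts as a poly-A tail;
# shared between precursor annotation and origin evidence.
POLYA_MIN_RUN <- 8L
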